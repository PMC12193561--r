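#' Patient-level survival records
#'
#' A `patient_records` object is a data frame with columns `diagnosis_year`,
#' `death_year` and `count`, one row per observed (diagnosis year, death year)
#' pair. `count` aggregates identical pairs, so a SEER-style case listing and
#' a pre-tabulated frequency table are interchangeable inputs. Records of
#' patients lost to follow-up or still alive carry no death year and must not
#' appear: the methods in this package address the right censoring that comes
#' from incomplete follow-up *windows*, not from incomplete records.
#'
#' Years are calendar years. They are integer-valued in registry extracts,
#' but real-valued years are accepted (e.g. from the synthetic generator with
#' rounding disabled), in which case survival is the real difference.
#'
#' @param diagnosis_year numeric vector of diagnosis years.
#' @param death_year numeric vector of death years, `death_year >= diagnosis_year`.
#' @param count positive integer vector of patients per pair (recycled; default 1).
#' @return A `patient_records` data frame.
#' @examples
#' patient_records(c(1992, 1992), c(1994, 2000))
#' @export
patient_records <- function(diagnosis_year, death_year, count = 1L) {
  if (length(diagnosis_year) != length(death_year)) {
    stop("`diagnosis_year` and `death_year` must have equal length", call. = FALSE)
  }
  count <- rep_len(count, length(diagnosis_year))
  df <- data.frame(
    diagnosis_year = as.numeric(diagnosis_year),
    death_year = as.numeric(death_year),
    count = as.numeric(count)
  )
  as_patient_records(df)
}

#' Coerce a data frame to patient records
#'
#' @param x data frame with columns `diagnosis_year`, `death_year` and
#'   optionally `count` (defaulted to 1).
#' @return A validated `patient_records` data frame.
#' @export
as_patient_records <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("diagnosis_year", "death_year")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$count)) x$count <- 1
  x <- x[, c("diagnosis_year", "death_year", "count")]
  bad <- which(is.na(x$diagnosis_year) | is.na(x$death_year) |
                 x$death_year < x$diagnosis_year)
  if (length(bad)) {
    stop("death_year earlier than diagnosis_year (or missing) in row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x$count) | x$count <= 0)) {
    stop("`count` must be positive", call. = FALSE)
  }
  class(x) <- c("patient_records", "data.frame")
  x
}

#' Survival time of each record
#'
#' Survival is the calendar-year difference `death_year - diagnosis_year`;
#' a same-year death has survival 0 years.
#'
#' @param records a `patient_records` object (or compatible data frame).
#' @return Numeric vector of survival times in years, one per row.
#' @examples
#' survival_years(patient_records(1992, 1995)) # 3
#' @export
survival_years <- function(records) {
  records <- as_patient_records(records)
  records$death_year - records$diagnosis_year
}

#' Read patient records from CSV
#'
#' Expects a UTF-8 CSV with header `diagnosis_year,death_year[,count]`; the
#' `count` column is optional and defaults to 1. Rows violating
#' `death_year >= diagnosis_year` are rejected with their file line numbers.
#'
#' @param path path to the CSV file.
#' @return A `patient_records` data frame.
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("diagnosis_year", "death_year")
  if (!all(needed %in% names(df))) {
    stop("malformed header in ", path, ": need columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$count)) df$count <- rep(1, nrow(df))
  dy <- suppressWarnings(as.numeric(df$diagnosis_year))
  ey <- suppressWarnings(as.numeric(df$death_year))
  ct <- suppressWarnings(as.numeric(df$count))
  # +1 for the header line
  bad <- which(is.na(dy) | is.na(ey) | ey < dy | is.na(ct) | ct <= 0) + 1L
  if (length(bad)) {
    stop("invalid record(s) in ", path, " at line(s): ",
         paste(head(bad, 10L), collapse = ", "),
         " (need numeric years with death_year >= diagnosis_year and count > 0)",
         call. = FALSE)
  }
  patient_records(dy, ey, ct)
}

#' Write patient records to CSV
#'
#' @param records a `patient_records` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  records <- as_patient_records(records)
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.patient_records <- function(x, ...) {
  cat(sprintf("Patient records: %d rows, %g patients, diagnosis years %g-%g\n",
              nrow(x), sum(x$count), min(x$diagnosis_year), max(x$diagnosis_year)))
  NextMethod()
}
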