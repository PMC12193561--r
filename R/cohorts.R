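#' Declared data range of a registry extract
#'
#' The inclusive span of calendar years over which the extract's records are
#' complete and reliable. Cohort eligibility is defined relative to this span,
#' not to the years that happen to appear in the data.
#'
#' @param year_min,year_max integer calendar years, `year_min <= year_max`.
#' @return A `data_range` object.
#' @examples
#' data_range(1992, 2020)
#' @export
data_range <- function(year_min, year_max) {
  stopifnot(length(year_min) == 1L, length(year_max) == 1L)
  if (is.na(year_min) || is.na(year_max) || year_min > year_max) {
    stop("need year_min <= year_max", call. = FALSE)
  }
  structure(list(year_min = as.numeric(year_min), year_max = as.numeric(year_max)),
            class = "data_range")
}

#' @export
print.data_range <- function(x, ...) {
  cat(sprintf("Data range: %g-%g\n", x$year_min, x$year_max))
  invisible(x)
}

as_data_range <- function(x) {
  if (inherits(x, "data_range")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(data_range(x[1], x[2]))
  stop("cannot interpret as a data range", call. = FALSE)
}

#' Diagnosis-year cohorts with complete N-year follow-up
#'
#' A diagnosis-year (start) cohort's N-year average survival time only exists
#' once N further years of death data are available, so year `y` is eligible
#' iff `y + N <= year_max`. With data for 1992--2020 and N = 20 the eligible
#' diagnosis cohorts are 1992--2000.
#'
#' @param range a [data_range()] (or length-2 numeric).
#' @param N observation window in years (e.g. 5, 10 or 20).
#' @return Ascending integer vector of eligible cohort years (possibly empty).
#' @seealso [eligible_end_cohorts()]
#' @export
eligible_start_cohorts <- function(range, N) {
  range <- as_data_range(range)
  stopifnot(N >= 1)
  ys <- seq(range$year_min, range$year_max)
  ys[ys + N <= range$year_max]
}

#' Death-year cohorts with complete N-year look-back
#'
#' A death-year (end) cohort at year `y` needs diagnosis data for the full N
#' preceding years, so `y` is eligible iff `y - N >= year_min`. Death-year
#' cohorts contain no within-window right censoring: every member's survival
#' time is fully observed.
#'
#' @inheritParams eligible_start_cohorts
#' @return Ascending integer vector of eligible cohort years (possibly empty).
#' @export
eligible_end_cohorts <- function(range, N) {
  range <- as_data_range(range)
  stopifnot(N >= 1)
  ys <- seq(range$year_min, range$year_max)
  ys[ys - N >= range$year_min]
}

#' Construct a cohort table
#'
#' Internal-facing constructor; most users build tables with
#' [build_cohort_table()].
#'
#' @param cohort_year numeric vector of cohort years (ascending).
#' @param mean_survival numeric vector of mean survival times in years.
#' @param n numeric vector of patient counts per cohort.
#' @param kind `"start"` (diagnosis-year) or `"end"` (death-year).
#' @param window_N observation window in years.
#' @param omitted_years eligible years omitted for lack of qualifying records.
#' @return A `cohort_table` data frame with attributes `kind` and `window_N`.
#' @export
cohort_table <- function(cohort_year, mean_survival, n, kind, window_N,
                         omitted_years = numeric(0)) {
  kind <- match.arg(kind, c("start", "end"))
  if (any(mean_survival < 0 | mean_survival > window_N)) {
    stop("cohort means must lie in [0, window_N]", call. = FALSE)
  }
  ord <- order(cohort_year)
  out <- data.frame(cohort_year = cohort_year[ord],
                    mean_survival = mean_survival[ord],
                    n = n[ord])
  structure(out, kind = kind, window_N = window_N, omitted_years = omitted_years,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("%s-year cohort table (N = %g): %d cohorts\n",
              if (attr(x, "kind") == "start") "Diagnosis" else "Death",
              attr(x, "window_N"), nrow(x)))
  om <- attr(x, "omitted_years")
  if (length(om)) {
    cat("Eligible years without qualifying records: ", paste(om, collapse = ", "), "\n")
  }
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Build an N-year cohort table from patient records
#'
#' For `kind = "start"`, each eligible diagnosis year's entry is the mean
#' survival time over patients diagnosed that year who did not survive more
#' than N calendar years (survival in `[0, N]`). For `kind = "end"`, each
#' eligible death year's entry is the mean survival over patients who died
#' that year and were diagnosed at most N calendar years before. Means are
#' weighted by the record `count`. Eligible cohort years without any
#' qualifying record are omitted from the table and reported in its
#' `omitted_years` attribute.
#'
#' Cohort years are taken from the years present in the data; eligibility is
#' tested against `range` by the inequalities `y + N <= year_max` (start) and
#' `y - N >= year_min` (end), which also apply unchanged to real-valued years.
#'
#' @param records a `patient_records` object (or compatible data frame).
#' @param range a [data_range()] declaring the reliable span.
#' @param N observation window in years.
#' @param kind `"start"` or `"end"`.
#' @return A [cohort_table()].
#' @examples
#' rec <- patient_records(c(1992, 1992), c(1994, 2000))
#' build_cohort_table(rec, data_range(1992, 2020), 20, "start")
#' @export
build_cohort_table <- function(records, range, N, kind = c("start", "end")) {
  records <- as_patient_records(records)
  range <- as_data_range(range)
  kind <- match.arg(kind)
  surv <- survival_years(records)
  in_window <- surv >= 0 & surv <= N
  if (kind == "start") {
    key <- records$diagnosis_year
    eligible <- key >= range$year_min & key + N <= range$year_max
  } else {
    key <- records$death_year
    eligible <- key <= range$year_max & key - N >= range$year_min
  }
  keep <- in_window & eligible
  if (!any(keep)) {
    stop("no eligible ", kind, " cohorts have qualifying records for N = ", N,
         " within ", range$year_min, "-", range$year_max, call. = FALSE)
  }
  key <- key[keep]
  surv <- surv[keep]
  wt <- records$count[keep]
  grp <- factor(key)
  wsum <- rowsum(surv * wt, grp)
  ns <- rowsum(wt, grp)[, 1]
  yrs <- as.numeric(levels(grp))
  means <- wsum[, 1] / ns
  # integer-year eligible cohorts that received no data
  omitted <- if (kind == "start") {
    setdiff(eligible_start_cohorts(range, N), yrs)
  } else {
    setdiff(eligible_end_cohorts(range, N), yrs)
  }
  cohort_table(yrs, means, ns, kind, N, omitted_years = omitted)
}

#' Classify a (diagnosis year, death year) cell
#'
#' Partitions the in-range grid of integer (diagnosis year, death year) pairs
#' into six classes describing which analysis, if any, uses records in that
#' cell for an N-year window:
#' \describe{
#'   \item{`invalid`}{above the diagonal — death before diagnosis.}
#'   \item{`out_of_window`}{survival exceeds N years.}
#'   \item{`both`}{in an eligible diagnosis cohort and an eligible death
#'     cohort (used by the base method and by the death-year regression).}
#'   \item{`start_only`}{only the diagnosis cohort is eligible (base method).}
#'   \item{`end_only`}{only the death cohort is eligible — the recent data
#'     that the base method cannot use.}
#'   \item{`unused_v`}{valid data in neither eligible cohort (the white "V"
#'     between the two regions); unused by either method.}
#' }
#'
#' @param diagnosis_year,death_year integer calendar years (vectorized).
#' @param range a [data_range()].
#' @param N observation window in years.
#' @return Character vector of cell classes.
#' @export
classify_cell <- function(diagnosis_year, death_year, range, N) {
  range <- as_data_range(range)
  if (any(diagnosis_year < range$year_min | diagnosis_year > range$year_max |
          death_year < range$year_min | death_year > range$year_max)) {
    stop("years outside the declared data range", call. = FALSE)
  }
  surv <- death_year - diagnosis_year
  start_ok <- diagnosis_year + N <= range$year_max
  end_ok <- death_year - N >= range$year_min
  out <- ifelse(surv < 0, "invalid",
         ifelse(surv > N, "out_of_window",
         ifelse(start_ok & end_ok, "both",
         ifelse(start_ok, "start_only",
         ifelse(end_ok, "end_only", "unused_v")))))
  out
}

#' Paired sign test between start and end cohort tables
#'
#' Pairs the i-th eligible diagnosis-year cohort with the i-th eligible
#' death-year cohort (positional pairing over the equal-length year lists)
#' and tests whether death-year cohorts tend to have the higher mean survival
#' time — the signature of an improving treatment trend, since each death-year
#' cohort contains more recent diagnoses than its paired diagnosis-year
#' cohort. The one-sided p-value is the exact binomial tail
#' `P(X >= n_end_higher)` with `X ~ Binomial(n_pairs, 1/2)`.
#'
#' @param start_table,end_table [cohort_table()]s with equally many entries.
#' @param ties how to treat exactly tied pairs: `"drop"` (default, the
#'   standard sign-test convention) removes them from `n_pairs`;
#'   `"keep"` counts them as not end-higher.
#' @return List with `n_pairs`, `n_end_higher` and `p_value`.
#' @export
paired_sign_test <- function(start_table, end_table, ties = c("drop", "keep")) {
  ties <- match.arg(ties)
  if (nrow(start_table) != nrow(end_table)) {
    stop("tables must have equally many entries to be paired", call. = FALSE)
  }
  d <- end_table$mean_survival - start_table$mean_survival
  if (ties == "drop") d <- d[d != 0]
  n <- length(d)
  k <- sum(d > 0)
  p <- if (n == 0) NA_real_ else pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  list(n_pairs = n, n_end_higher = k, p_value = p)
}

#' Write a cohort table to CSV
#'
#' Columns: `cohort_kind,window_N,cohort_year,mean_survival,n`.
#'
#' @param table a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  df <- data.frame(cohort_kind = attr(table, "kind"),
                   window_N = attr(table, "window_N"),
                   cohort_year = table$cohort_year,
                   mean_survival = table$mean_survival,
                   n = table$n)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Inverse of [write_cohort_csv()].
#'
#' @param path path to a cohort-table CSV.
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cohort_kind", "window_N", "cohort_year", "mean_survival", "n")
  if (!all(needed %in% names(df))) {
    stop("malformed cohort-table CSV: ", path, call. = FALSE)
  }
  kind <- unique(df$cohort_kind)
  N <- unique(df$window_N)
  if (length(kind) != 1L || length(N) != 1L) {
    stop("cohort-table CSV must hold a single kind and window", call. = FALSE)
  }
  cohort_table(df$cohort_year, df$mean_survival, df$n, kind, N)
}
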