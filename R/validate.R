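#' Score predictions against held-out cohort means
#'
#' RMSE and AIC are computed on the *held-out* residuals (prediction error),
#' not on the training fit: `AIC = n_heldout * ln(RSS/n_heldout) + 2k` with
#' the same RSS floor as [goodness_of_fit()].
#'
#' @param predictions data frame (or list) with columns/elements `year` and
#'   `predicted`.
#' @param observed a [cohort_table()] containing every prediction year.
#' @param k number of free parameters of the predicting model.
#' @return List with `RMSE`, `AIC`, `RSS`, `n` and `residuals`.
#' @export
prediction_metrics <- function(predictions, observed, k) {
  predictions <- as.data.frame(predictions)
  idx <- match(predictions$year, observed$cohort_year)
  if (anyNA(idx)) {
    stop("prediction year(s) missing from the observed table: ",
         paste(predictions$year[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  res <- observed$mean_survival[idx] - predictions$predicted
  residuals_from(res, k)
}

#' Retrospective hold-out experiment
#'
#' Truncates the data range at `cutoff_year`, fits the base model (when at
#' least two completed diagnosis-year cohorts exist in the truncated range)
#' and the steepness regression on the truncated range's death-year cohorts,
#' then scores both models' predictions against the diagnosis-year cohort
#' means that only the full range can supply. This mimics standing at
#' `cutoff_year` and asking how well each method would have predicted the
#' since-completed cohorts.
#'
#' With a single completed diagnosis cohort the base method cannot fit a
#' slope at all (`base` is absent, with a recorded reason); the steepness
#' regression still runs, anchored at that single cohort's mean — the
#' method's characteristic degenerate case.
#'
#' @param records a `patient_records` object.
#' @param full_range the [data_range()] of the complete data.
#' @param cutoff_year last year of the training range
#'   (`< full_range$year_max`).
#' @param N observation window in years.
#' @param family trend family.
#' @param weighted passed to [fit_steti_steepness()].
#' @return A `steti_holdout` list: `cutoff_year`, `base` (a `steti_fit` or
#'   `NULL` with `base_absent_reason`), `steti` (a `steti_fit`), `anchor`,
#'   `heldout_years`, `heldout` (the held-out cohort table), and
#'   `prediction_rmse_base` / `prediction_aic_base` (NA when base is absent),
#'   `prediction_rmse_steti` / `prediction_aic_steti`.
#' @export
holdout_experiment <- function(records, full_range, cutoff_year, N,
                               family = c("linear", "exponential", "logistic"),
                               weighted = FALSE) {
  family <- match.arg(family)
  full_range <- as_data_range(full_range)
  if (cutoff_year >= full_range$year_max) {
    stop("cutoff_year must precede the full range's last year", call. = FALSE)
  }
  train_range <- data_range(full_range$year_min, cutoff_year)
  train_start <- build_cohort_table(records, train_range, N, "start")
  train_end <- build_cohort_table(records, train_range, N, "end")

  base <- NULL
  base_reason <- NULL
  min_pts <- if (family == "logistic") 3L else 2L
  if (nrow(train_start) >= min_pts) {
    base <- fit_base(train_start, family)
    anchor <- anchor_from_base(base, train_start)
  } else {
    base_reason <- sprintf(
      "%d diagnosis cohort(s) cannot support a %s fit (need %d)",
      nrow(train_start), family, min_pts)
    # anchor directly at the single cohort's observed mean
    t_r <- max(train_start$cohort_year)
    anchor <- list(t_r = t_r,
                   S_r = train_start$mean_survival[train_start$cohort_year == t_r])
  }
  steti <- fit_steti_steepness(anchor, family, train_end, weighted = weighted)

  full_start <- build_cohort_table(records, full_range, N, "start")
  heldout_years <- setdiff(full_start$cohort_year, train_start$cohort_year)
  if (!length(heldout_years)) {
    stop("no held-out diagnosis cohorts beyond the cutoff", call. = FALSE)
  }
  heldout <- full_start[full_start$cohort_year %in% heldout_years, ]
  class(heldout) <- class(full_start)
  attributes(heldout)[c("kind", "window_N")] <-
    attributes(full_start)[c("kind", "window_N")]

  steti_pred <- data.frame(year = heldout_years,
                           predicted = eval_start(steti$model, heldout_years))
  m_steti <- prediction_metrics(steti_pred, heldout, k = 1L)
  m_base <- if (!is.null(base)) {
    base_pred <- data.frame(year = heldout_years,
                            predicted = eval_start(base$model, heldout_years))
    prediction_metrics(base_pred, heldout, k = base$k)
  }

  structure(list(
    cutoff_year = cutoff_year,
    family = family,
    base = base,
    base_absent_reason = base_reason,
    steti = steti,
    anchor = anchor,
    train_start = train_start,
    train_end = train_end,
    heldout_years = heldout_years,
    heldout = heldout,
    prediction_rmse_base = if (is.null(m_base)) NA_real_ else m_base$RMSE,
    prediction_aic_base = if (is.null(m_base)) NA_real_ else m_base$AIC,
    prediction_rmse_steti = m_steti$RMSE,
    prediction_aic_steti = m_steti$AIC
  ), class = "steti_holdout")
}

#' @export
print.steti_holdout <- function(x, ...) {
  cat(sprintf("Hold-out at %g (%s family): %d training diagnosis cohorts, %d death cohorts\n",
              x$cutoff_year, x$family, nrow(x$train_start), nrow(x$train_end)))
  cat(sprintf("Held-out diagnosis cohorts: %s\n",
              paste(x$heldout_years, collapse = ", ")))
  if (is.null(x$base)) {
    cat("Base fit absent:", x$base_absent_reason, "\n")
  } else {
    cat(sprintf("Base prediction RMSE = %.4g, AIC = %.4g\n",
                x$prediction_rmse_base, x$prediction_aic_base))
  }
  cat(sprintf("STETI prediction RMSE = %.4g, AIC = %.4g\n",
              x$prediction_rmse_steti, x$prediction_aic_steti))
  invisible(x)
}
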