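#' Full trend analysis and projection
#'
#' Runs the whole estimation pipeline for one observation window: builds the
#' diagnosis-year and death-year cohort tables, fits the base model per
#' family, extracts the anchor, regresses the steepness on the death-year
#' cohorts, projects the updated curve to `target_year` with a
#' relative-likelihood uncertainty band, and — when both linear and
#' exponential families are fitted — combines the two projections into a
#' headline estimate using the base fits' AIC relative likelihood (the base
#' fits use the larger diagnosis-cohort dataset, so they carry the model
#' comparison).
#'
#' @param records a `patient_records` object; alternatively supply
#'   `start_table` and `end_table` directly and leave `records` `NULL`.
#' @param range a [data_range()] (required with `records`).
#' @param N observation window in years (required with `records`).
#' @param families subset of `c("linear", "exponential", "logistic")`.
#' @param target_year diagnosis year to project to.
#' @param start_table,end_table pre-built [cohort_table()]s (optional).
#' @param band_threshold relative-likelihood cutoff for the uncertainty
#'   band; default 0.5.
#' @param combine_threshold no-preference cutoff for combining projections;
#'   default 0.5.
#' @param weighted weight the steepness regression by cohort size.
#' @param anchor optional fixed `list(t_r, S_r)` overriding the
#'   from-base-fit anchor policy.
#' @return A `steti_analysis` list with one entry per family (each holding
#'   `base`, `anchor`, `steti`, `projection`, `band`), plus `comparison`
#'   (`rel_lik`, `preferred`) and `combined` when linear and exponential are
#'   both present.
#' @export
steti_analysis <- function(records = NULL, range = NULL, N = NULL,
                           families = c("linear", "exponential"),
                           target_year,
                           start_table = NULL, end_table = NULL,
                           band_threshold = 0.5, combine_threshold = 0.5,
                           weighted = FALSE, anchor = NULL) {
  families <- match.arg(families, c("linear", "exponential", "logistic"),
                        several.ok = TRUE)
  if (is.null(start_table) || is.null(end_table)) {
    if (is.null(records) || is.null(range) || is.null(N)) {
      stop("supply either records + range + N or both cohort tables",
           call. = FALSE)
    }
    start_table <- build_cohort_table(records, range, N, "start")
    end_table <- build_cohort_table(records, range, N, "end")
  }
  fits <- lapply(families, function(fam) {
    base <- fit_base(start_table, fam)
    anc <- if (is.null(anchor)) anchor_from_base(base, start_table) else as_anchor(anchor)
    steti <- fit_steti_steepness(anc, fam, end_table, weighted = weighted)
    band <- uncertainty_band(anc, fam, end_table, target_year,
                             threshold = band_threshold, weighted = weighted)
    list(base = base, anchor = anc, steti = steti,
         projection = eval_start(steti$model, target_year), band = band)
  })
  names(fits) <- families
  out <- list(families = fits, target_year = target_year,
              start_table = start_table, end_table = end_table)
  if (all(c("linear", "exponential") %in% families)) {
    rl <- relative_likelihood(fits$linear$base$AIC, fits$exponential$base$AIC)
    preferred <- if (fits$linear$base$AIC <= fits$exponential$base$AIC)
      "linear" else "exponential"
    out$comparison <- list(rel_lik = rl, preferred = preferred,
                           threshold = combine_threshold)
    out$combined <- combine_projections(
      fits$linear$projection, fits$exponential$projection, rl,
      preferred = if (preferred == "linear") "a" else "b",
      threshold = combine_threshold)
  }
  structure(out, class = "steti_analysis")
}

#' @export
print.steti_analysis <- function(x, ...) {
  N <- attr(x$start_table, "window_N")
  cat(sprintf("%g-year average survival trend analysis\n", N))
  cat(sprintf("Diagnosis cohorts: %s; death cohorts: %s\n",
              paste(range(x$start_table$cohort_year), collapse = "-"),
              paste(range(x$end_table$cohort_year), collapse = "-")))
  for (fam in names(x$families)) {
    f <- x$families[[fam]]
    cat(sprintf(
      "  %s: base AIC %.4g, %s = %.6g; projection at %g = %.3f years, band [%.3f, %.3f]\n",
      fam, f$base$AIC, theta_label(fam), f$steti$model$theta,
      x$target_year, f$projection, f$band$lo, f$band$hi))
  }
  if (!is.null(x$combined)) {
    cat(sprintf(
      "Relative likelihood (linear vs exponential) = %.3g -> %s\n",
      x$comparison$rel_lik,
      if (x$comparison$rel_lik >= x$comparison$threshold) "no preference, projections averaged"
      else paste("prefer", x$comparison$preferred)))
    cat(sprintf("Headline estimate for %g: %.2f years (rounded)\n",
                x$target_year, x$combined))
  }
  invisible(x)
}

#' Plot an analysis: cohort points, base and updated curves, band
#'
#' Diagnosis-cohort means are drawn as points, the base fit as a solid curve,
#' the steepness-updated curve (from the anchor onward) dashed, and the
#' uncertainty band as a shaded cone widening with extrapolation distance.
#'
#' @param x a [steti_analysis()] result.
#' @param family which fitted family to draw; default the first.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.steti_analysis <- function(x, family = names(x$families)[1], ...) {
  f <- x$families[[family]]
  st <- x$start_table
  xs <- seq(min(st$cohort_year), x$target_year, length.out = 200)
  base_curve <- eval_start(f$base$model, xs)
  upd <- xs >= f$anchor$t_r
  upd_curve <- eval_start(f$steti$model, xs[upd])
  ylim <- range(st$mean_survival, base_curve, upd_curve, f$band$lo, f$band$hi)
  plot(st$cohort_year, st$mean_survival, xlim = range(xs), ylim = ylim,
       xlab = "Diagnosis year", ylab = "Average survival time (years)",
       pch = 16, ...)
  lines(xs, base_curve, lwd = 1.5)
  lines(xs[upd], upd_curve, lty = 2, lwd = 2)
  # cone of uncertainty at the target year
  polygon(c(f$anchor$t_r, x$target_year, x$target_year),
          c(f$anchor$S_r, f$band$lo, f$band$hi),
          col = adjustcolor("grey", 0.4), border = NA)
  points(x$target_year, f$projection, pch = 4, cex = 1.2)
  legend("topleft", bty = "n", lty = c(1, 2, NA), pch = c(NA, NA, 16),
         legend = c("base fit", "updated (death-year regressed)", "cohort means"))
  invisible(x)
}

#' Serialize a fit report to JSON
#'
#' Machine-readable report with unrounded numbers: model parameters, anchor,
#' sample sizes, RSS/RMSE/AIC per stage, projections, bands and the combined
#' headline estimate.
#'
#' @param analysis a [steti_analysis()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_analysis_json <- function(analysis, path) {
  fam_report <- lapply(analysis$families, function(f) {
    list(
      base = list(model = model_to_config(f$base$model), n = f$base$n,
                  k = f$base$k, RSS = f$base$RSS, RMSE = f$base$RMSE,
                  AIC = f$base$AIC),
      anchor = f$anchor,
      steti = list(model = model_to_config(f$steti$model), n = f$steti$n,
                   k = f$steti$k, RSS = f$steti$RSS, RMSE = f$steti$RMSE,
                   AIC = f$steti$AIC),
      projection = f$projection,
      band = list(target_year = f$band$target_year, point = f$band$point,
                  lo = f$band$lo, hi = f$band$hi,
                  threshold = f$band$threshold))
  })
  report <- list(target_year = analysis$target_year, families = fam_report,
                 comparison = analysis$comparison,
                 combined = analysis$combined)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
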