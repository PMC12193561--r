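# RSS floor keeping the least-squares AIC finite on perfect fits
RSS_FLOOR <- 1e-12

new_steti_fit <- function(model, gof, k, stage, data) {
  structure(list(model = model, n = gof$n, k = k, residuals = gof$residuals,
                 RSS = gof$RSS, RMSE = gof$RMSE, AIC = gof$AIC,
                 stage = stage, data = data),
            class = "steti_fit")
}

#' @export
print.steti_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s family): n = %d, k = %d, RMSE = %.4g, AIC = %.4g\n",
              x$stage, x$model$family, x$n, x$k, x$RMSE, x$AIC))
  print(x$model)
  invisible(x)
}

#' Goodness of fit of a trend model against a cohort table
#'
#' Residuals are observed cohort means minus the model's value at the cohort
#' year, evaluated on the start-time scale (`evaluator = "start"`) or through
#' the end-time transform (`evaluator = "end"`). The AIC is the Gaussian
#' least-squares form `n * ln(RSS/n) + 2k`; only AIC *differences* are
#' meaningful, and the RSS is floored at 1e-12 before the logarithm so that
#' perfect fits stay finite.
#'
#' @param observed a [cohort_table()].
#' @param model a [trend_model()].
#' @param evaluator `"start"` or `"end"` — which cohort-year axis the table
#'   uses.
#' @param k number of free parameters charged to the model.
#' @return List with `RSS`, `RMSE`, `AIC`, `n` and `residuals`.
#' @export
goodness_of_fit <- function(observed, model, evaluator = c("start", "end"), k) {
  evaluator <- match.arg(evaluator)
  pred <- if (evaluator == "start") {
    eval_start(model, observed$cohort_year)
  } else {
    eval_end(model, observed$cohort_year)
  }
  residuals_from(observed$mean_survival - pred, k)
}

# Shared RSS/RMSE/AIC arithmetic from a residual vector.
residuals_from <- function(res, k) {
  n <- length(res)
  rss <- sum(res^2)
  list(RSS = rss, RMSE = sqrt(rss / n),
       AIC = n * log(max(rss, RSS_FLOOR) / n) + 2 * k,
       n = n, residuals = res)
}

#' Fit the base trend model to diagnosis-year cohorts
#'
#' The "base" method regresses a trend family on the completed diagnosis-year
#' cohort means only — the conventional analysis that must wait N years for
#' each cohort. Linear fits use ordinary least squares. Exponential fits use
#' log-linear least squares (regressing `ln(mean)` on year, as spreadsheet
#' exponential trendlines do) by default, with exact nonlinear least squares
#' on the original scale available via `exp_method = "nls"`. Logistic fits
#' minimize the residual sum of squares over anchor value, rate and ceiling.
#'
#' Goodness of fit (RSS, RMSE, AIC) is always reported on the original
#' survival-time scale, whatever the fitting scale.
#'
#' @param start_table a `"start"`-kind [cohort_table()] with at least 2
#'   points (3 for logistic).
#' @param family trend family to fit.
#' @param t0 anchor year of the returned model; defaults to the earliest
#'   cohort year (a pure reparameterization — the fitted curve is identical).
#' @param L logistic ceiling. If `NULL` (default) the ceiling is estimated as
#'   a third free parameter, initialized at the table's observation window;
#'   if supplied it is held fixed.
#' @param exp_method `"loglinear"` (default) or `"nls"` for the exponential
#'   family.
#' @return A `steti_fit` with `k = 2` (`3` for logistic with free ceiling).
#' @export
fit_base <- function(start_table, family = c("linear", "exponential", "logistic"),
                     t0 = NULL, L = NULL,
                     exp_method = c("loglinear", "nls")) {
  family <- match.arg(family)
  exp_method <- match.arg(exp_method)
  yrs <- start_table$cohort_year
  y <- start_table$mean_survival
  min_pts <- if (family == "logistic") 3L else 2L
  if (length(yrs) < min_pts) {
    stop("fit_base needs at least ", min_pts, " ", family,
         " cohort points, got ", length(yrs), call. = FALSE)
  }
  if (is.null(t0)) t0 <- min(yrs)
  x <- yrs - t0

  if (family == "linear") {
    co <- coef(lm(y ~ x))
    model <- trend_model("linear", t0, co[[1]], co[[2]])
    k <- 2L
  } else if (family == "exponential") {
    if (any(y <= 0)) stop("exponential fit requires positive means", call. = FALSE)
    co <- coef(lm(log(y) ~ x))
    S0 <- exp(co[[1]])
    d <- log(2) / co[[2]]            # slope in log space is ln(2)/d
    if (exp_method == "nls") {
      obj <- function(p) sum((y - exp(p[1]) * 2^(x / p[2]))^2)
      opt <- optim(c(log(S0), d), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))
      S0 <- exp(opt$par[1]); d <- opt$par[2]
    }
    model <- trend_model("exponential", t0, S0, d)
    k <- 2L
  } else {
    N <- attr(start_table, "window_N")
    L_init <- if (!is.null(L)) L else max(N, 1.1 * max(y))
    free_L <- is.null(L)
    if (L_init <= max(y)) L_init <- 1.1 * max(y)
    # initial rate from the linearized logit of y/L
    z <- log(pmax(L_init - y, 1e-8) / y)
    k_init <- -coef(lm(z ~ x))[[2]]
    obj <- function(p) {
      S0 <- exp(p[1]); kk <- p[2]
      LL <- if (free_L) max(y) + exp(p[3]) else L
      if (S0 >= LL) return(1e12)
      pred <- LL / (1 + ((LL - S0) / S0) * exp(-kk * x))
      sum((y - pred)^2)
    }
    par0 <- c(log(y[1]), k_init)
    if (free_L) par0 <- c(par0, log(max(L_init - max(y), 1e-3)))
    opt <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 10000))
    S0 <- exp(opt$par[1]); kk <- opt$par[2]
    LL <- if (free_L) max(y) + exp(opt$par[3]) else L
    model <- trend_model("logistic", t0, S0, kk, L = LL)
    k <- if (free_L) 3L else 2L
  }
  gof <- goodness_of_fit(start_table, model, "start", k)
  new_steti_fit(model, gof, k, "base", start_table)
}

#' Anchor for the steepness regression
#'
#' The updated curve is constrained to pass through the most recent point the
#' base analysis can speak to: `t_r` is the latest diagnosis-cohort year in
#' the fitted table and `S_r` the *fitted* curve's height there (not the raw
#' cohort mean, which carries sampling noise).
#'
#' @param base a `steti_fit` from [fit_base()].
#' @param start_table the fitted cohort table; defaults to the one stored in
#'   `base`.
#' @return List with `t_r` (year) and `S_r` (years of survival).
#' @export
anchor_from_base <- function(base, start_table = NULL) {
  stopifnot(inherits(base, "steti_fit"))
  if (is.null(start_table)) start_table <- base$data
  t_r <- max(start_table$cohort_year)
  list(t_r = t_r, S_r = eval_start(base$model, t_r))
}

as_anchor <- function(anchor) {
  if (is.list(anchor)) {
    stopifnot(!is.null(anchor$t_r), !is.null(anchor$S_r))
    return(list(t_r = as.numeric(anchor$t_r), S_r = as.numeric(anchor$S_r)))
  }
  if (is.numeric(anchor) && length(anchor) == 2L) {
    return(list(t_r = anchor[[1]], S_r = anchor[[2]]))
  }
  stop("anchor must be a list(t_r, S_r) or a length-2 numeric", call. = FALSE)
}

# Default steepness search bounds per family (theta space).
steepness_bounds <- function(family) {
  switch(family,
    linear = c(-0.99, 0.99),        # in u = M/(M+1) space
    exponential = c(1, 10000),      # |d| range, sign chosen by the data
    logistic = c(-5, 5)
  )
}

#' Regress the steepness parameter on death-year cohorts
#'
#' The centrepiece of the method: with the anchor `(t_r, S_r)` held fixed,
#' the single steepness parameter of the chosen family is chosen to minimize
#' the sum of squared differences between the death-year cohort means and the
#' model's end-time transform at those death years. Death-year cohorts are
#' complete — no within-window right censoring — so this regression can use
#' years far more recent than any completed diagnosis cohort.
#'
#' For the linear family the end-time transform is linear in `u = M/(M+1)`,
#' so the optimum is closed-form least squares in `u`, then `M = u/(1-u)`
#' (`method = "closed"`, the default). All families support bounded 1-D
#' numeric minimization (`method = "numeric"`); for the exponential family
#' both orientations of the doubling time are searched and the flatter
#' optimum wins ties. With a single death-year point the steepness is an
#' exact solve (zero residual).
#'
#' @param anchor `list(t_r, S_r)` from [anchor_from_base()] (or a length-2
#'   numeric `(year, value)`).
#' @param family trend family.
#' @param end_table an `"end"`-kind [cohort_table()] with at least 1 point.
#' @param L logistic ceiling; defaults to the table's observation window.
#' @param weighted if `TRUE`, weight squared residuals by cohort size `n`
#'   during optimization (reported goodness of fit stays unweighted).
#' @param method `"auto"` (closed form for linear, numeric otherwise),
#'   `"closed"`, or `"numeric"`.
#' @return A `steti_fit` with `k = 1` (the anchor is fixed, not estimated
#'   from this data), goodness of fit evaluated through the end-time
#'   transform.
#' @export
fit_steti_steepness <- function(anchor, family = c("linear", "exponential", "logistic"),
                                end_table, L = NULL, weighted = FALSE,
                                method = c("auto", "closed", "numeric")) {
  family <- match.arg(family)
  method <- match.arg(method)
  anchor <- as_anchor(anchor)
  if (is.null(end_table) || nrow(end_table) < 1L) {
    stop("steepness regression needs at least one death-year cohort point",
         call. = FALSE)
  }
  if (family == "logistic" && is.null(L)) L <- attr(end_table, "window_N")
  te <- end_table$cohort_year
  yv <- end_table$mean_survival
  w <- if (weighted) end_table$n else rep(1, length(te))

  make_model <- function(theta) trend_model(family, anchor$t_r, anchor$S_r, theta, L = L)
  wrss <- function(theta) {
    pred <- eval_end(make_model(theta), te)
    sum(w * (yv - pred)^2)
  }

  if (family == "linear" && method != "numeric") {
    # S_end(te) = S_r + u * (te - S_r - t_r): ordinary LS through the origin in u
    xs <- te - anchor$S_r - anchor$t_r
    ys <- yv - anchor$S_r
    u <- if (sum(w * xs^2) == 0) 0 else sum(w * xs * ys) / sum(w * xs^2)
    if (u >= 1) {
      stop(sprintf("end-time slope u = %.4g >= 1 implies an infinite start-time slope", u),
           call. = FALSE)
    }
    theta <- u / (1 - u)
  } else {
    if (method == "closed") {
      stop("closed-form steepness exists only for the linear family", call. = FALSE)
    }
    bounds <- steepness_bounds(family)
    if (family == "linear") {
      opt <- optimize(function(u) wrss(u / (1 - u)), bounds, tol = 1e-10)
      theta <- opt$minimum / (1 - opt$minimum)
    } else if (family == "exponential") {
      pos <- optimize(wrss, bounds, tol = 1e-10)
      neg <- optimize(wrss, rev(-bounds), tol = 1e-10)
      # prefer the flatter (larger |d|) orientation only on an exact RSS tie
      theta <- if (neg$objective < pos$objective ||
                   (neg$objective == pos$objective &&
                    abs(neg$minimum) < abs(pos$minimum))) neg$minimum else pos$minimum
    } else {
      theta <- optimize(wrss, bounds, tol = 1e-10)$minimum
    }
  }
  model <- make_model(theta)
  gof <- goodness_of_fit(end_table, model, "end", k = 1L)
  new_steti_fit(model, gof, 1L, "steti", end_table)
}

#' Relative likelihood of two models from their AIC values
#'
#' `exp(Delta/2)` with `Delta = AIC_min - AIC_other`: the likelihood of the
#' worse model relative to the better one. Symmetric in argument order,
#' always in (0, 1], and 1 exactly when the AICs are equal. Values near 1
#' mean the data do not prefer either model.
#'
#' @param aic_a,aic_b AIC values.
#' @return Relative likelihood in (0, 1].
#' @examples
#' relative_likelihood(-86.1, -96.7) # ~0.005: strong preference
#' @export
relative_likelihood <- function(aic_a, aic_b) {
  exp(-abs(aic_a - aic_b) / 2)
}

#' Projection interval from likelihood-plausible steepness variations
#'
#' Scans a dense grid of steepness values around the regression optimum,
#' scores each variation's AIC against the death-year cohort table (anchor
#' fixed, `k = 1`), retains variations whose relative likelihood against the
#' best fit is at least `threshold`, and returns the range of the retained
#' start-time curves' values at the target year — a cone-of-uncertainty style
#' interval. The grid is laid out in the parameter in which the family is
#' closest to linear (`u = M/(M+1)` for linear, inverse doubling time for
#' exponential, the rate for logistic) and widened adaptively until both ends
#' fall below the threshold.
#'
#' When the optimum's RSS is at the floor (a perfect fit) the band collapses
#' to the point estimate.
#'
#' @inheritParams fit_steti_steepness
#' @param target_year diagnosis year to project to.
#' @param threshold relative-likelihood cutoff in (0, 1]; default 0.5.
#' @param grid_points number of grid points per scan.
#' @return A `projection_band`: list with `target_year`, `point`, `lo`, `hi`,
#'   `threshold` and the best `steti_fit` as `fit`.
#' @export
uncertainty_band <- function(anchor, family = c("linear", "exponential", "logistic"),
                             end_table, target_year, threshold = 0.5,
                             L = NULL, weighted = FALSE, grid_points = 2001L) {
  family <- match.arg(family)
  stopifnot(threshold > 0, threshold <= 1)
  anchor <- as_anchor(anchor)
  best <- fit_steti_steepness(anchor, family, end_table, L = L, weighted = weighted)
  if (family == "logistic" && is.null(L)) L <- attr(end_table, "window_N")
  point <- eval_start(best$model, target_year)

  band <- structure(list(target_year = target_year, point = point,
                         lo = point, hi = point, threshold = threshold,
                         fit = best),
                    class = "projection_band")
  if (best$RSS <= 1.5 * RSS_FLOOR || threshold == 1) {
    return(band)  # degenerate: nothing can tie a (near-)perfect fit
  }

  # grid parameterization: p -> theta
  to_theta <- switch(family,
    linear = function(p) p / (1 - p),
    exponential = function(p) 1 / p,   # p is the inverse doubling time (1/yr)
    logistic = identity)
  p_best <- switch(family,
    linear = best$model$theta / (1 + best$model$theta),
    exponential = 1 / best$model$theta,
    logistic = best$model$theta)

  aic_of <- function(p) {
    # out-of-domain parameters (e.g. linear u >= 1) count as infinitely bad
    tryCatch({
      m <- trend_model(family, anchor$t_r, anchor$S_r, to_theta(p), L = L)
      goodness_of_fit(end_table, m, "end", k = 1L)$AIC
    }, error = function(e) Inf)
  }
  rel_of <- function(p) relative_likelihood(best$AIC, aic_of(p))

  h <- max(abs(p_best), 0.01) * 0.25
  iter <- 0L
  while ((rel_of(p_best - h) >= threshold || rel_of(p_best + h) >= threshold) &&
         iter < 60L) {
    h <- h * 2
    iter <- iter + 1L
  }
  grid <- unique(c(seq(p_best - h, p_best + h, length.out = grid_points), p_best))
  ok <- vapply(grid, function(p) rel_of(p) >= threshold, logical(1))
  vals <- vapply(grid[ok], function(p) {
    eval_start(trend_model(family, anchor$t_r, anchor$S_r, to_theta(p), L = L),
               target_year)
  }, numeric(1))
  vals <- c(vals, point)
  band$lo <- min(vals)
  band$hi <- max(vals)
  band
}

#' @export
print.projection_band <- function(x, ...) {
  cat(sprintf(
    "Projection at %g: %.4g years, band [%.4g, %.4g] at relative likelihood > %g\n",
    x$target_year, x$point, x$lo, x$hi, x$threshold))
  invisible(x)
}

# Round half away from zero (spreadsheet-style), unlike R's banker's rounding.
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Combine two model projections into a headline estimate
#'
#' If the relative likelihood between the two models is at least `threshold`
#' neither is preferred and their projections are averaged; otherwise the
#' preferred (lower-AIC) model's projection is used alone. The result is
#' rounded half-up to `digits` decimals, as a headline figure.
#'
#' @param proj_a,proj_b point projections in years (conventionally linear and
#'   exponential).
#' @param rel_lik relative likelihood between the two models, in (0, 1].
#' @param preferred which projection wins when `rel_lik < threshold`:
#'   `"a"`/`"b"` or the value itself must be recoverable; required only in
#'   that case.
#' @param threshold no-preference cutoff, default 0.5.
#' @param digits decimals of the headline estimate, default 2.
#' @return The combined estimate in years (rounded).
#' @examples
#' combine_projections(3.806, 3.842, 0.86)            # average: 3.82
#' combine_projections(3.253, 3.168, 0.005, "b")      # select: 3.17
#' @export
combine_projections <- function(proj_a, proj_b, rel_lik, preferred = NULL,
                                threshold = 0.5, digits = 2L) {
  stopifnot(rel_lik > 0, rel_lik <= 1)
  est <- if (rel_lik >= threshold) {
    (proj_a + proj_b) / 2
  } else {
    if (is.null(preferred)) {
      stop("rel_lik below threshold: `preferred` must name the lower-AIC model",
           call. = FALSE)
    }
    switch(match.arg(preferred, c("a", "b")), a = proj_a, b = proj_b)
  }
  round_half_up(est, digits)
}
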