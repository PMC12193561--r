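#' Start-time (diagnosis-year) trend model
#'
#' A parametric model of how the N-year average survival time improves with
#' the diagnosis year. All families use an *anchored* parameterization: the
#' curve passes through the anchor `(t0, S0)` and has one steepness parameter
#' `theta` whose meaning depends on the family:
#'
#' * `linear`: slope `M` in years of survival per calendar year;
#'   `S(t) = S0 + M * (t - t0)`.
#' * `exponential`: doubling time `d` in years;
#'   `S(t) = S0 * 2^((t - t0) / d)`.
#' * `logistic`: maximum steepness (rate) `k` per year with ceiling `L`;
#'   `S(t) = L / (1 + ((L - S0)/S0) * exp(-k * (t - t0)))`.
#'
#' The anchored form is an exact reparameterization of the usual
#' year-intercept forms; it makes the fixed-intercept steepness regression
#' (see [fit_steti_steepness()]) explicit. The logistic ceiling `L` is the
#' attainable maximum of an N-year average and therefore defaults to the
#' observation window when fitted through the higher-level functions.
#'
#' @param family `"linear"`, `"exponential"` or `"logistic"`.
#' @param t0 anchor calendar year.
#' @param S0 survival time (years) at `t0`; must be positive.
#' @param theta steepness: slope `M` (> -1), doubling time `d` (non-zero),
#'   or logistic rate `k`.
#' @param L logistic ceiling in years (required for `family = "logistic"`,
#'   with `0 < S0 < L`); ignored otherwise.
#' @return A `trend_model` object.
#' @examples
#' m <- trend_model("exponential", t0 = 2000, S0 = 3.26232411, theta = 106)
#' eval_start(m, 2025)
#' @export
trend_model <- function(family = c("linear", "exponential", "logistic"),
                        t0, S0, theta, L = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(t0), is.numeric(S0), is.numeric(theta))
  if (S0 <= 0) stop("anchor value S0 must be positive", call. = FALSE)
  if (family == "linear" && theta <= -1) {
    stop("linear slope M must exceed -1 (end times must increase with start times)",
         call. = FALSE)
  }
  if (family == "exponential" && theta == 0) {
    stop("exponential doubling time d must be non-zero", call. = FALSE)
  }
  if (family == "logistic") {
    if (is.null(L)) stop("logistic family requires a ceiling L", call. = FALSE)
    if (!(S0 < L)) stop("logistic family requires 0 < S0 < L", call. = FALSE)
  } else {
    L <- NULL
  }
  structure(list(family = family, t0 = as.numeric(t0), S0 = as.numeric(S0),
                 theta = as.numeric(theta),
                 L = if (is.null(L)) NULL else as.numeric(L)),
            class = "trend_model")
}

theta_label <- function(family) {
  switch(family, linear = "slope M", exponential = "doubling time d",
         logistic = "max steepness k")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("%s trend model: anchor (%g, %.6g yr), %s = %.6g%s\n",
              x$family, x$t0, x$S0, theta_label(x$family), x$theta,
              if (!is.null(x$L)) sprintf(", ceiling L = %g yr", x$L) else ""))
  invisible(x)
}

#' Evaluate a start-time model at a diagnosis year
#'
#' @param model a [trend_model()].
#' @param tb diagnosis year(s), real-valued.
#' @return Average survival time(s) in years.
#' @export
eval_start <- function(model, tb) {
  stopifnot(inherits(model, "trend_model"))
  switch(model$family,
    linear = model$S0 + model$theta * (tb - model$t0),
    exponential = model$S0 * 2^((tb - model$t0) / model$theta),
    logistic = model$L / (1 + ((model$L - model$S0) / model$S0) *
                            exp(-model$theta * (tb - model$t0)))
  )
}

#' Death year implied by a diagnosis year
#'
#' A patient diagnosed at `tb` with the model's average survival dies at
#' `te = tb + S(tb)`. Under the model invariants this map is strictly
#' increasing, which makes the start-time and end-time views of one trend
#' interconvertible.
#'
#' @inheritParams eval_start
#' @return Death year(s) `tb + eval_start(model, tb)`.
#' @export
end_time_of <- function(model, tb) {
  tb + eval_start(model, tb)
}

#' Evaluate the end-time (death-year) transform of a model
#'
#' Returns the average survival time as a function of the *death* year:
#' `S_end(te)` is the value `S(tb)` of the start-time model at the unique
#' `tb` with `tb + S(tb) = te`. For the linear family this has the closed
#' form `S_end(te) = S0 + M * (te - S0 - t0) / (M + 1)` — again a line, with
#' the flatter slope `M/(M+1)`. For the other families the defining equation
#' is solved by bracketed root-finding (monotonicity guarantees a unique
#' root), to a tolerance of 1e-10 years.
#'
#' @param model a [trend_model()].
#' @param te death year(s), real-valued.
#' @param method `"auto"` (closed form where available), `"closed"`
#'   (linear only) or `"numeric"` (always invert numerically).
#' @return Average survival time(s) in years at death year `te`.
#' @export
eval_end <- function(model, te, method = c("auto", "closed", "numeric")) {
  stopifnot(inherits(model, "trend_model"))
  method <- match.arg(method)
  if (method == "closed" && model$family != "linear") {
    stop("closed-form end-time evaluation exists only for the linear family",
         call. = FALSE)
  }
  if (model$family == "linear" && method != "numeric") {
    M <- model$theta
    return(model$S0 + M * (te - model$S0 - model$t0) / (M + 1))
  }
  invert_end_time_newton(model, te)
}

# derivative dS/dtb of the start-time curve
d_eval_start <- function(model, tb) {
  S <- eval_start(model, tb)
  switch(model$family,
    linear = rep(model$theta, length(tb)),
    exponential = S * log(2) / model$theta,
    logistic = model$theta * S * (1 - S / model$L)
  )
}

# Vectorized Newton iteration for tb + S(tb) = te; elements that fail to
# converge fall back to bracketed root-finding.
invert_end_time_newton <- function(model, te, tol = 1e-10, max_iter = 60L) {
  tb <- te - eval_start(model, te)   # start just below te
  for (i in seq_len(max_iter)) {
    f <- tb + eval_start(model, tb) - te
    if (all(is.finite(f)) && max(abs(f)) < tol) {
      return(eval_start(model, tb))
    }
    df <- 1 + d_eval_start(model, tb)
    step <- f / df
    step[!is.finite(step)] <- 0
    tb <- tb - step
  }
  vapply(te, function(t1) invert_end_time(model, t1), numeric(1))
}

# Solve tb + S(tb) = te for tb by bracketed root-finding (Brent).
invert_end_time <- function(model, te, tol = 1e-10) {
  f <- function(tb) end_time_of(model, tb) - te
  upper <- te               # S > 0 so the root lies strictly below te
  lower <- model$t0 - 200
  if (lower >= upper) lower <- upper - 200
  iter <- 0L
  while (f(lower) > 0) {
    lower <- upper - 2 * (upper - lower)
    iter <- iter + 1L
    if (iter > 60L) {
      stop(sprintf(
        "end-time inversion failed: no bracket below te = %g (last lower bound %g)",
        te, lower), call. = FALSE)
    }
  }
  if (f(upper) < 0) {
    stop(sprintf("te = %g is below the model's minimum end time", te),
         call. = FALSE)
  }
  root <- uniroot(f, c(lower, upper), tol = tol)$root
  eval_start(model, root)
}

#' Coefficients of the linear end-time transform
#'
#' The end-time transform of a linear start-time model is itself linear with
#' slope `M/(M+1)`: an improvement trend always looks *flatter* against the
#' death year than against the diagnosis year, because faster improvement
#' spreads a diagnosis cohort's deaths over more calendar years. The value at
#' `te = t0` is `S0 / (M + 1)`.
#'
#' @param model a linear [trend_model()].
#' @return List with `slope` (`M/(M+1)`) and `value_at_t0` (`S0/(M+1)`).
#' @export
linear_end_coefficients <- function(model) {
  stopifnot(inherits(model, "trend_model"))
  if (model$family != "linear") stop("model must be linear", call. = FALSE)
  M <- model$theta
  if (M == -1) stop("slope M = -1 has no end-time transform", call. = FALSE)
  list(slope = M / (M + 1), value_at_t0 = model$S0 / (M + 1))
}

#' Serialize a trend model to a plain configuration list
#'
#' @param model a [trend_model()].
#' @return Named list `(family, t0, S0, theta[, L])`.
#' @seealso [model_from_config()], [write_model_config()]
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "trend_model"))
  cfg <- list(family = model$family, t0 = model$t0, S0 = model$S0,
              theta = model$theta)
  if (!is.null(model$L)) cfg$L <- model$L
  cfg
}

#' Rebuild a trend model from a configuration list
#'
#' @param config named list as produced by [model_to_config()].
#' @return A [trend_model()].
#' @export
model_from_config <- function(config) {
  trend_model(config$family, config$t0, config$S0, config$theta,
              L = config$L)
}

#' Write / read a trend model as YAML or JSON
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param model a [trend_model()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `path` invisibly (write); a [trend_model()] (read).
#' @export
write_model_config <- function(model, path) {
  cfg <- model_to_config(model)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported model-config extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported model-config extension: .", ext, call. = FALSE)
  }
  model_from_config(cfg)
}
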