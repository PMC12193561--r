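test_that("base linear fit reproduces exact lines", {
  tab <- ct(c(2000, 2010), c(3.0, 4.0), "start", 20)
  fit <- fit_base(tab, "linear")
  expect_equal(fit$model$theta, 0.1)
  expect_equal(eval_start(fit$model, 2000), 3.0)
  expect_equal(fit$RSS, 0, tolerance = 1e-20)
  expect_equal(fit$k, 2)

  tab3 <- ct(2000:2002, c(3, 3.5, 4), "start", 20)
  expect_equal(fit_base(tab3, "linear")$RMSE, 0, tolerance = 1e-10)

  expect_error(fit_base(ct(2000, 3, "start", 20), "linear"), "at least 2")
})

test_that("base exponential fit recovers a noiseless doubling time", {
  true <- trend_model("exponential", 1992, 3.0748, 93)
  tab <- ct(1992:2000, eval_start(true, 1992:2000), "start", 20)
  fit <- fit_base(tab, "exponential")
  expect_equal(fit$model$theta, 93, tolerance = 1e-6)
  expect_equal(eval_start(fit$model, 1992), 3.0748, tolerance = 1e-8)
  # the exact nonlinear alternative agrees on noiseless data
  fit_nls <- fit_base(tab, "exponential", exp_method = "nls")
  expect_equal(fit_nls$model$theta, 93, tolerance = 1e-4)
})

test_that("base logistic fit recovers a noiseless S-curve", {
  true <- trend_model("logistic", 1992, 2.0, 0.12, L = 20)
  tab <- ct(1992:2005, eval_start(true, 1992:2005), "start", 20)
  fit <- fit_base(tab, "logistic", L = 20)
  expect_equal(fit$k, 2)
  expect_equal(fit$model$theta, 0.12, tolerance = 1e-4)
  expect_lt(fit$RMSE, 1e-5)
  fit_free <- fit_base(tab, "logistic")
  expect_equal(fit_free$k, 3)
  expect_lt(fit_free$RMSE, 1e-4)
  expect_error(fit_base(ct(1992:1993, c(2, 2.1), "start", 20), "logistic"),
               "at least 3")
})

test_that("the anchor is the fitted height at the latest complete cohort", {
  flat <- ct(1995:2000, rep(2.0, 6), "start", 20)
  fit <- fit_base(flat, "linear")
  anc <- anchor_from_base(fit)
  expect_equal(anc$t_r, 2000)
  expect_equal(anc$S_r, 2.0, tolerance = 1e-12)

  fit2 <- fit_base(ct(c(2000, 2010), c(3.0, 4.0), "start", 20), "linear")
  anc2 <- anchor_from_base(fit2)
  expect_equal(anc2, list(t_r = 2010, S_r = 4.0))
})

test_that("steepness regression inverts noiseless end-cohort data", {
  # linear: anchored at (2000, 2.0) with true M = 0.1
  truth <- trend_model("linear", 2000, 2.0, 0.1)
  et <- ct(2012:2015, eval_end(truth, 2012:2015), "end", 20)
  expect_equal(et$mean_survival[1], 2 + 0.1 * (2012 - 2 - 2000) / 1.1)
  fit <- fit_steti_steepness(list(t_r = 2000, S_r = 2.0), "linear", et)
  expect_equal(fit$model$theta, 0.1, tolerance = 1e-9)
  expect_equal(fit$k, 1)

  # flat end data pins the slope at zero
  flat <- ct(2012:2015, rep(2.0, 4), "end", 20)
  expect_equal(fit_steti_steepness(list(t_r = 2000, S_r = 2.0), "linear",
                                   flat)$model$theta, 0)

  # a single death-year cohort determines the line exactly (degenerate case)
  one <- ct(2012, 2.6, "end", 20)
  fit1 <- fit_steti_steepness(list(t_r = 1992, S_r = 2.2), "linear", one)
  expect_equal(eval_end(fit1$model, 2012), 2.6, tolerance = 1e-12)
  expect_equal(fit1$RSS, 0, tolerance = 1e-20)

  # exponential: recover the printed 106-year doubling time from its curve
  e_truth <- trend_model("exponential", 2000, 3.2623, 106)
  e_tab <- ct(2012:2020, eval_end(e_truth, 2012:2020), "end", 20)
  e_fit <- fit_steti_steepness(list(t_r = 2000, S_r = 3.2623), "exponential", e_tab)
  expect_equal(e_fit$model$theta, 106, tolerance = 1e-5)

  # implied infinite start-time slope is an error
  steep <- ct(2012, 14, "end", 20)
  expect_error(fit_steti_steepness(list(t_r = 2000, S_r = 2.0), "linear", steep),
               "infinite")
  expect_error(fit_steti_steepness(list(t_r = 2000, S_r = 2.0), "linear",
                                   et[0, ]), "at least one")
})

test_that("closed-form steepness equals 1-D numeric optimization", {
  set.seed(21)
  for (rep in 1:15) {
    anc <- list(t_r = 2000, S_r = runif(1, 1, 5))
    years <- 2010:2018
    truth <- trend_model("linear", anc$t_r, anc$S_r, runif(1, -0.3, 0.6))
    means <- pmax(0.05, eval_end(truth, years) + rnorm(9, 0, 0.15))
    et <- ct(years, pmin(means, 20), "end", 20)
    closed <- fit_steti_steepness(anc, "linear", et, method = "closed")
    numeric <- fit_steti_steepness(anc, "linear", et, method = "numeric")
    expect_equal(closed$model$theta, numeric$model$theta, tolerance = 1e-7)
  }
})

test_that("goodness of fit implements least-squares RMSE and AIC", {
  # residuals {1, -1}, k = 1
  obs <- ct(c(2000, 2001), c(4, 2), "start", 20)
  flat <- trend_model("linear", 2000, 3, 0)
  g <- goodness_of_fit(obs, flat, "start", k = 1)
  expect_equal(g$RMSE, 1)
  expect_equal(g$AIC, 2)

  # residuals {0.5 x 4}, k = 2
  obs4 <- ct(2000:2003, rep(3.5, 4), "start", 20)
  g4 <- goodness_of_fit(obs4, flat, "start", k = 2)
  expect_equal(g4$RSS, 1.0)
  expect_equal(g4$RMSE, 0.5)
  expect_equal(g4$AIC, 4 * log(0.25) + 4)

  # perfect fit: RMSE 0, AIC floored at the epsilon RSS
  obs0 <- ct(2000:2003, rep(3, 4), "start", 20)
  g0 <- goodness_of_fit(obs0, flat, "start", k = 2)
  expect_equal(g0$RMSE, 0)
  expect_equal(g0$AIC, 4 * log(1e-12 / 4) + 4)
})

test_that("relative likelihood reproduces printed evidence ratios", {
  expect_equal(signif(relative_likelihood(-86.1, -96.7), 1), 0.005)
  expect_equal(round(relative_likelihood(-54.5, -54.8), 2), 0.86)
  expect_equal(round(relative_likelihood(-14.71, -12.22), 2), 0.29)
  expect_equal(relative_likelihood(-3, -3), 1.0)
  # symmetric, bounded by 1, equal to 1 iff AICs are equal
  set.seed(5)
  a <- rnorm(20, 0, 30); b <- rnorm(20, 0, 30)
  expect_equal(relative_likelihood(a, b), relative_likelihood(b, a))
  expect_true(all(relative_likelihood(a, b) <= 1))
  expect_true(all((relative_likelihood(a, b) == 1) == (a == b)))
})

test_that("uncertainty bands widen with lower thresholds and collapse when exact", {
  anc <- list(t_r = 2000, S_r = 2.0)
  truth <- trend_model("linear", 2000, 2.0, 0.1)

  noiseless <- ct(2012:2015, eval_end(truth, 2012:2015), "end", 20)
  b0 <- uncertainty_band(anc, "linear", noiseless, 2025)
  expect_equal(b0$lo, b0$point)
  expect_equal(b0$hi, b0$point)

  set.seed(31)
  noisy <- ct(2012:2019, eval_end(truth, 2012:2019) + rnorm(8, 0, 0.1), "end", 20)
  b1 <- uncertainty_band(anc, "linear", noisy, 2025, threshold = 1.0)
  expect_equal(b1$lo, b1$point)

  b50 <- uncertainty_band(anc, "linear", noisy, 2025, threshold = 0.5)
  b05 <- uncertainty_band(anc, "linear", noisy, 2025, threshold = 0.05)
  expect_lte(b50$lo, b50$point); expect_gte(b50$hi, b50$point)
  expect_lte(b05$lo, b50$lo)
  expect_gte(b05$hi, b50$hi)
  expect_gt(b50$hi, b50$lo) # noisy data gives a genuine interval

  # exponential bands behave the same way
  e_anc <- list(t_r = 2000, S_r = 3.26)
  e_noisy <- ct(2012:2019,
                eval_end(trend_model("exponential", 2000, 3.26, 106), 2012:2019) +
                  rnorm(8, 0, 0.05), "end", 20)
  eb <- uncertainty_band(e_anc, "exponential", e_noisy, 2025, threshold = 0.5)
  expect_true(eb$lo <= eb$point && eb$point <= eb$hi)
})

test_that("projection combination averages or selects and rounds half-up", {
  expect_equal(combine_projections(1.553, 1.582, 0.75), 1.57)
  expect_equal(combine_projections(3.806, 3.842, 0.86), 3.82)
  expect_equal(combine_projections(3.253, 3.168, 0.005, preferred = "b"), 3.17)
  expect_equal(combine_projections(2.5, 2.5, 0.3, preferred = "a"), 2.5)
  expect_error(combine_projections(1, 2, 0.1), "preferred")
  # the half-up convention: 3.824 -> 3.82 but 3.825 -> 3.83
  expect_equal(combine_projections(3.82, 3.83, 0.9), 3.83)
  # result always inside the span of its inputs
  set.seed(41)
  for (i in 1:20) {
    p <- sort(runif(2, 1, 5)); rl <- runif(1)
    out <- combine_projections(p[1], p[2], rl, preferred = "a")
    expect_gte(out, p[1] - 0.005) # within the span up to headline rounding
    expect_lte(out, p[2] + 0.005)
  }
})

test_that("projections of improving models increase with the target year", {
  anc <- list(t_r = 2000, S_r = 3.0)
  et <- ct(2012:2016, eval_end(trend_model("linear", 2000, 3, 0.05), 2012:2016),
           "end", 20)
  fit <- fit_steti_steepness(anc, "linear", et)
  proj <- eval_start(fit$model, 2020:2030)
  expect_true(all(diff(proj) > 0))
})
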