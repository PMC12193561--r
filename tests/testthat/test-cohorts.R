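test_that("survival is the calendar-year difference", {
  rec <- patient_records(c(1992, 2000, 2000), c(1995, 2000, 2020))
  expect_equal(survival_years(rec), c(3, 0, 20))
  # a 20-year survivor still qualifies for a 20-year window
  tab <- build_cohort_table(rec[3, ], data_range(1992, 2020), 20, "end")
  expect_equal(tab$mean_survival, 20)
  expect_error(patient_records(1995, 1992), "death_year earlier")
})

test_that("cohort eligibility follows the follow-up and look-back rules", {
  r <- data_range(1992, 2020)
  expect_equal(eligible_start_cohorts(r, 20), 1992:2000)
  expect_equal(eligible_start_cohorts(r, 5), 1992:2015)
  expect_equal(eligible_start_cohorts(data_range(1992, 2015), 20), 1992:1995)
  expect_equal(eligible_end_cohorts(r, 20), 2012:2020)
  expect_equal(eligible_end_cohorts(data_range(1992, 2015), 20), 2012:2015)
  expect_length(eligible_end_cohorts(data_range(1992, 2010), 20), 0)
})

test_that("cohort tables average within-window survival, weighted by count", {
  rec <- patient_records(c(1992, 1992), c(1994, 2000))
  tab <- build_cohort_table(rec, data_range(1992, 2020), 20, "start")
  expect_equal(tab$mean_survival, mean(c(2, 8)))
  expect_equal(tab$n, 2)

  # diagnosis cohort not yet complete inside a shorter range
  expect_error(
    build_cohort_table(rec, data_range(1992, 2011), 20, "start"),
    "no eligible")

  rec2 <- patient_records(c(2000, 1995), c(2012, 2012), count = c(3, 1))
  tab2 <- build_cohort_table(rec2, data_range(1992, 2020), 20, "end")
  expect_equal(tab2$mean_survival, (3 * 12 + 1 * 17) / 4)
  expect_equal(tab2$n, 4)

  # records beyond the window are excluded, empty eligible years reported
  rec3 <- patient_records(c(1992, 1993), c(2015, 1995))
  tab3 <- build_cohort_table(rec3, data_range(1992, 2020), 20, "start")
  expect_equal(tab3$cohort_year, 1993)
  expect_true(1992 %in% attr(tab3, "omitted_years"))
})

test_that("records feed the start/end tables exactly when their cohort is eligible", {
  rng <- data_range(1992, 2020); N <- 20
  set.seed(42)
  dy <- sample(1992:2020, 200, replace = TRUE)
  s <- sample(0:25, 200, replace = TRUE)
  keep <- dy + s <= 2020
  rec <- patient_records(dy[keep], (dy + s)[keep])
  start_tab <- build_cohort_table(rec, rng, N, "start")
  end_tab <- build_cohort_table(rec, rng, N, "end")
  surv <- survival_years(rec)
  in_window <- surv >= 0 & surv <= N
  # every in-window record with an eligible diagnosis year appears in the
  # start table (and likewise for death years / the end table); purple-cell
  # records appear in both
  start_fed <- in_window & rec$diagnosis_year %in% eligible_start_cohorts(rng, N)
  end_fed <- in_window & rec$death_year %in% eligible_end_cohorts(rng, N)
  expect_true(all(rec$diagnosis_year[start_fed] %in% start_tab$cohort_year))
  expect_true(all(rec$death_year[end_fed] %in% end_tab$cohort_year))
  expect_equal(sum(start_tab$n), sum(rec$count[start_fed]))
  expect_equal(sum(end_tab$n), sum(rec$count[end_fed]))
  both <- classify_cell(rec$diagnosis_year, rec$death_year, rng, N) == "both"
  expect_equal(both, start_fed & end_fed)
  expect_true(all(start_tab$mean_survival >= 0 & start_tab$mean_survival <= N))
  expect_true(all(end_tab$mean_survival >= 0 & end_tab$mean_survival <= N))
})

test_that("cell classification matches the eligibility geometry", {
  rng <- data_range(1992, 2020)
  expect_equal(classify_cell(2005, 2003, rng, 20), "invalid")
  expect_equal(classify_cell(1995, 2005, rng, 20), "start_only")
  expect_equal(classify_cell(2005, 2018, rng, 20), "end_only")
  expect_equal(classify_cell(2002, 2008, rng, 20), "unused_v")
  expect_equal(classify_cell(1992, 2012, rng, 20), "both")
  expect_equal(classify_cell(1992, 2015, rng, 20), "out_of_window")
  expect_error(classify_cell(1980, 1990, rng, 20), "outside")
})

test_that("the six cell classes partition every in-range pair", {
  check_partition <- function(rng, N) {
    grid <- expand.grid(dy = rng$year_min:rng$year_max,
                        ey = rng$year_min:rng$year_max)
    cls <- classify_cell(grid$dy, grid$ey, rng, N)
    expect_true(all(cls %in% c("invalid", "out_of_window", "both",
                               "start_only", "end_only", "unused_v")))
    expect_length(cls, nrow(grid))
    # recompute each class membership independently and compare counts
    surv <- grid$ey - grid$dy
    s_ok <- grid$dy + N <= rng$year_max
    e_ok <- grid$ey - N >= rng$year_min
    expect_equal(sum(cls == "invalid"), sum(surv < 0))
    expect_equal(sum(cls == "out_of_window"), sum(surv >= 0 & surv > N))
    in_v <- surv >= 0 & surv <= N
    expect_equal(sum(cls == "both"), sum(in_v & s_ok & e_ok))
    expect_equal(sum(cls == "start_only"), sum(in_v & s_ok & !e_ok))
    expect_equal(sum(cls == "end_only"), sum(in_v & !s_ok & e_ok))
    expect_equal(sum(cls == "unused_v"), sum(in_v & !s_ok & !e_ok))
  }
  check_partition(data_range(1992, 2020), 20)
  check_partition(data_range(2000, 2010), 5)
  check_partition(data_range(2000, 2004), 2)
})

test_that("the paired sign test equals exact binomial enumeration", {
  # frozen values computed from the enumeration oracle
  expect_equal(sign_p_by_enumeration(9, 8), 10 / 512)
  expect_equal(sign_p_by_enumeration(9, 9), 1 / 512)
  expect_equal(sign_p_by_enumeration(4, 2), 11 / 16)

  make_pair <- function(d) {
    list(start = ct(seq_along(d), rep(2, length(d)), "start", 20),
         end = ct(seq_along(d) + 20, 2 + d, "end", 20))
  }
  # the improving-trend configuration reported as significant: 8 of 9 higher
  tabs <- make_pair(c(rep(0.5, 8), -0.1))
  res <- paired_sign_test(tabs$start, tabs$end)
  expect_equal(res$n_pairs, 9)
  expect_equal(res$n_end_higher, 8)
  expect_equal(res$p_value, 10 / 512)
  expect_lt(res$p_value, 0.02)

  set.seed(7)
  for (n in c(3, 5, 8, 12)) {
    d <- stats::runif(n, -1, 1)
    tabs <- make_pair(d)
    res <- paired_sign_test(tabs$start, tabs$end)
    expect_equal(res$p_value, sign_p_by_enumeration(n, sum(d > 0)))
  }

  # ties dropped by default
  tabs <- make_pair(c(0, 0.3, 0.4))
  res <- paired_sign_test(tabs$start, tabs$end)
  expect_equal(res$n_pairs, 2)
  expect_equal(res$p_value, sign_p_by_enumeration(2, 2))
  res_keep <- paired_sign_test(tabs$start, tabs$end, ties = "keep")
  expect_equal(res_keep$n_pairs, 3)

  expect_error(paired_sign_test(ct(1:3, rep(2, 3), "start", 20),
                                ct(1:2, rep(2, 2), "end", 20)),
               "equally many")
})
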