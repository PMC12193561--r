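# Shared fixtures and independent oracles, built in code.

# Exact binomial sign-test p-value by brute-force enumeration of all 2^n
# equally likely sign configurations (independent of the implementation).
sign_p_by_enumeration <- function(n, k) {
  outcomes <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  mean(rowSums(outcomes) >= k)
}

# Cohort table straight from (year, mean) vectors, n = 10 unless given.
ct <- function(years, means, kind, N, n = rep(10, length(years))) {
  cohort_table(years, means, n, kind, N)
}

# Noiseless records tracing an exact linear diagnosis-year trend, one
# patient per diagnosis year, real-valued survival (no rounding).
linear_truth_records <- function(range = data_range(1992, 2020), S0 = 2.5,
                                 M = 0.05, t0 = 1992, n_per_year = 5) {
  model <- trend_model("linear", t0, S0, M)
  cfg <- simulation_config(range = range, window_N = 20, true_model = model,
                           n_per_year = n_per_year, noise = "none",
                           rounding = "none")
  list(records = simulate_records(cfg), model = model, config = cfg)
}

# SEER-like noisy simulation (gamma individual survival, integer years).
noisy_sim_config <- function(seed, n_per_year = 300,
                             model = trend_model("linear", 1992, 2.6, 0.04),
                             rounding = "round") {
  simulation_config(range = data_range(1992, 2020), window_N = 20,
                    true_model = model, n_per_year = n_per_year,
                    noise = "gamma", noise_param = 2, rounding = rounding,
                    seed = seed)
}
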