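test_that("trace simulation is seed-deterministic and leaves the RNG alone", {
  mx <- default_plateau_mixture()
  acq <- acquisition_spec(n_bins = 200)
  t1 <- simulate_decay(mx, acq, seed = 11)
  t2 <- simulate_decay(mx, acq, seed = 11)
  expect_identical(t1$counts, t2$counts)
  expect_false(identical(t1$counts, simulate_decay(mx, acq, seed = 12)$counts))
  # caller RNG state untouched
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_decay(mx, acq, seed = 5))
  expect_identical(before, .Random.seed)
})

test_that("simulated totals match the closed-form expected counts", {
  mx <- lifetime_mixture(1, 28.7)
  acq <- acquisition_spec(n_bins = 500, background_rate = 0)
  t_end <- acq$n_bins * acq$bin_width
  expected_total <- acq$n_flashes * acq$counts_per_flash_scale *
    28.7 * (1 - exp(-t_end / 28.7))
  totals <- vapply(1:200, function(s)
    sum(simulate_decay(mx, acq, seed = s)$counts), numeric(1))
  se <- sqrt(expected_total / 200)
  expect_lt(abs(mean(totals) - expected_total), 3 * se)
})

test_that("per-bin empirical means track the analytic Poisson means", {
  mx <- lifetime_mixture(1, 2)
  acq <- acquisition_spec(n_bins = 150, background_rate = 0.5)
  mu <- expected_bin_counts(mx, acq)
  n_rep <- 120
  counts <- vapply(seq_len(n_rep), function(s)
    simulate_decay(mx, acq, seed = 1000 + s)$counts, numeric(acq$n_bins))
  emp <- rowMeans(counts)
  se <- sqrt(mu / n_rep)
  frac_ok <- mean(abs(emp - mu) <= 4 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("invalid simulation inputs are rejected by name", {
  acq <- acquisition_spec(n_bins = 100)
  expect_error(lifetime_mixture(c(0, 0), c(1, 2)), "all-zero amplitudes")
  expect_error(lifetime_mixture(1, 0), "nonpositive lifetime")
  expect_error(acquisition_spec(n_bins = 100, bin_width = 0), "bin_width")
  expect_error(acquisition_spec(n_bins = 5), "n_bins")
  p <- two_state_params(100, 450, 5)
  expect_error(series_design(p, noise_sd = -0.1), "noise_sd")
  expect_error(series_design(p, temperatures = numeric(0)), "empty")
  expect_error(series_design(p, temperatures = c(200, 190)), "increasing")
})

test_that("series generator reproduces the model in the noiseless limit", {
  df <- zn_hba_reference_params()
  p <- two_state_params(df$delta_E[1], df$delta_S[1], df$K_d[1],
                        tau0 = df$tau0[1])
  des <- series_design(p, noise_sd = 0)
  s <- simulate_series(des, seed = 1)
  # deep-frozen point is exactly at the plateau
  expect_equal(s$ratio[s$temperatures == 50], 1, tolerance = 1e-6)
  # tau_avg carried alongside on the unnormalized scale
  expect_equal(s$tau_avg, s$ratio * p$tau0, tolerance = 1e-12)
  # ground truth embedded in provenance
  expect_equal(s$provenance$true_params$delta_E, p$delta_E)
  # midpoint value by algebraic substitution of the closed form
  tmp <- midpoint_temperature(p)
  des2 <- series_design(p, temperatures = c(100, tmp), noise_sd = 0)
  s2 <- simulate_series(des2, seed = 1)
  expect_equal(s2$ratio[2], (1 + 1 / p$K_d) / 2, tolerance = 1e-9)
  # K_d = 1 gives a flat series
  des3 <- series_design(two_state_params(100, 450, 1), noise_sd = 0)
  expect_equal(simulate_series(des3, seed = 3)$ratio,
               rep(1, length(des3$temperatures)))
})

test_that("series noise is seed-deterministic with the stated sd", {
  p <- two_state_params(113.4, 526, 2.0)
  des <- series_design(p, noise_sd = 0.02)
  s1 <- simulate_series(des, seed = 21)
  s2 <- simulate_series(des, seed = 21)
  expect_identical(s1$ratio, s2$ratio)
  expect_equal(s1$sd, rep(0.02, length(s1$ratio)))
})

test_that("experiment simulation scales lifetimes by the model ratio", {
  p <- two_state_params(113.4, 526, 2.0, tau0 = 28.7)
  des <- series_design(p, temperatures = c(50, 200, 220), noise_sd = 0)
  acq <- acquisition_spec(n_bins = 100)
  traces <- simulate_experiment(des, acq, seed = 3)
  expect_length(traces, 3)
  expect_equal(vapply(traces, `[[`, numeric(1), "temperature"),
               c(50, 200, 220))
  # the embedded true average scales by exactly r(T)
  for (tr in traces) {
    r <- two_state_ratio(p, tr$temperature)
    expect_equal(tr$meta$true_tau_avg, r * 28.7, tolerance = 1e-12)
    expect_equal(tr$meta$true_ratio, r)
  }
  # determinism of the whole experiment
  traces2 <- simulate_experiment(des, acq, seed = 3)
  expect_identical(lapply(traces, `[[`, "counts"),
                   lapply(traces2, `[[`, "counts"))
})
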