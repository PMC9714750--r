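test_that("a noiseless single exponential is recovered exactly", {
  acq <- acquisition_spec(n_bins = 2000)
  tr <- noiseless_trace(lifetime_mixture(1, 28.7), acq)
  fit <- fit_multiexponential(tr)
  expect_equal(fit$mixture$n, 1L)
  expect_equal(fit$mixture$lifetimes, 28.7, tolerance = 1e-6)
  expect_lt(fit$background, 1e-6)
  expect_equal(fit$tau_avg, 28.7, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("two well-separated lifetimes are recovered from Poisson traces", {
  mx <- lifetime_mixture(c(1, 1), c(5, 50))
  # high-count acquisition; trace spans 10x the longest lifetime
  acq <- acquisition_spec(n_bins = 6250, counts_per_flash_scale = 0.3)
  errs <- vapply(1:20, function(s) {
    fit <- fit_multiexponential(simulate_decay(mx, acq, seed = s))
    expect_gte(fit$mixture$n, 2L)
    tau <- fit$mixture$lifetimes
    # match fitted components to truth by proximity
    c(abs(tau[which.min(abs(tau - 5))] - 5) / 5,
      abs(tau[which.min(abs(tau - 50))] - 50) / 50)
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 0.05)
  expect_lt(stats::median(errs[2, ]), 0.05)
})

test_that("degenerate traces are rejected by name", {
  acq <- acquisition_spec(n_bins = 50)
  tt <- (0:49) * 0.08
  expect_error(fit_multiexponential(decay_trace(tt, rep(0, 50))),
               "empty signal")
  expect_error(fit_multiexponential(decay_trace(tt, rep(7, 50))),
               "no signal above background")
  expect_error(
    fit_multiexponential(decay_trace(tt[1:8], exp(-(0:7)))),
    "too few bins")
  expect_error(decay_trace(c(0, 0.08, 0.2), c(1, 1, 1)), "non-uniform")
})

test_that("fitted lifetimes are invariant to count rescaling", {
  acq <- acquisition_spec(n_bins = 1500)
  tr <- simulate_decay(lifetime_mixture(c(1, 1), c(4, 30)), acq, seed = 8)
  fit1 <- fit_multiexponential(tr)
  k <- 3.7
  tr_k <- decay_trace(tr$times, tr$counts * k)
  fit2 <- fit_multiexponential(tr_k)
  expect_equal(fit2$mixture$lifetimes, fit1$mixture$lifetimes,
               tolerance = 1e-4)
  expect_equal(fit2$mixture$amplitudes, k * fit1$mixture$amplitudes,
               tolerance = 1e-3)
  expect_equal(fit2$tau_avg, fit1$tau_avg, tolerance = 1e-4)
})

test_that("model selection trace has non-increasing goodness", {
  acq <- acquisition_spec(n_bins = 3000)
  tr <- simulate_decay(default_plateau_mixture(), acq, seed = 4)
  fit <- fit_multiexponential(tr)
  sel <- fit$selection_trace
  expect_true(all(diff(sel$n) == 1))
  if (nrow(sel) > 1) {
    n_obs <- length(tr$counts)
    for (k in 2:nrow(sel)) {
      # warm starts guarantee the raw objective never increases with n;
      # the reduced statistic may rise only by the dof-ratio factor
      slack <- (n_obs - 2 * sel$n[k] + 1) / (n_obs - 2 * sel$n[k] - 1)
      expect_lte(sel$reduced_chi2[k], sel$reduced_chi2[k - 1] * slack)
    }
  }
  # chosen n is the smallest the incremental rule justifies
  expect_equal(fit$mixture$n, min(fit$mixture$n, max(sel$n)))
})

test_that("refitting the model's own prediction is a fixed point", {
  acq <- acquisition_spec(n_bins = 3000)
  tr <- simulate_decay(lifetime_mixture(c(1, 1), c(5, 40)), acq, seed = 15)
  fit <- fit_multiexponential(tr)
  # rebuild a noiseless trace from the fitted model and refit it
  pred_acq <- acquisition_spec(
    n_bins = acq$n_bins, bin_width = acq$bin_width, n_flashes = 1,
    counts_per_flash_scale = 1, background_rate = fit$background)
  pred <- noiseless_trace(fit$mixture, pred_acq)
  refit <- fit_multiexponential(pred)
  expect_equal(refit$mixture$lifetimes, fit$mixture$lifetimes,
               tolerance = 1e-6)
  expect_equal(refit$tau_avg, fit$tau_avg, tolerance = 1e-6)
  # canonical ordering
  expect_true(all(diff(refit$mixture$lifetimes) > 0))
})

test_that("moment oracle reproduces lifetimes on long-tailed traces", {
  # single exponential observed to 20 lifetimes: truncation negligible
  acq <- acquisition_spec(n_bins = 2500, bin_width = 0.08)
  tr <- noiseless_trace(lifetime_mixture(1, 8), acq)  # T_end = 25 tau
  m <- moment_average_oracle(tr)
  expect_equal(as.numeric(m), 8, tolerance = 0.01)
  expect_lt(attr(m, "truncation_fraction"), 1e-10)
  # symmetric two-bin toy: equal counts centered at t = 1 and 3
  toy <- decay_trace(c(0, 2), c(5, 5))
  expect_equal(as.numeric(moment_average_oracle(toy)), 2)
  # net counts must be positive after background subtraction
  expect_error(moment_average_oracle(toy, background = 5), "net counts")
})

test_that("fit-based and moment-based averages agree on noiseless traces", {
  acq <- acquisition_spec(n_bins = 12000, bin_width = 0.08)  # 960 ms span
  for (mx in list(lifetime_mixture(1, 20),
                  lifetime_mixture(c(1, 1), c(10, 40)))) {
    tr <- noiseless_trace(mx, acq)
    fit <- fit_multiexponential(tr)
    m <- as.numeric(moment_average_oracle(tr))
    expect_equal(fit$tau_avg, m, tolerance = 0.01)
    expect_equal(fit$tau_avg, ensemble_average_lifetime(mx),
                 tolerance = 1e-4)
  }
})
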