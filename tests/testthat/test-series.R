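test_that("baseline reference lifetime is the windowed mean with its SD", {
  tt <- seq(10, 180, by = 10)
  s <- temperature_series(tt, tau_avg = rep(28.7, length(tt)))
  b <- compute_tau0(s, roi_config())
  expect_equal(b$tau0, 28.7)
  expect_equal(b$sd, 0)
  expect_equal(b$n_points, length(tt))
  # fewer than 3 baseline points is rejected
  s1 <- temperature_series(c(100, 200, 210, 220, 230),
                           tau_avg = c(28, 20, 15, 14, 13))
  expect_error(compute_tau0(s1, roi_config()), "too few baseline")
})

test_that("baseline mean is unbiased under Gaussian lifetime noise", {
  tt <- seq(10, 180, by = 10)  # 18 points
  est <- vapply(1:200, function(s) {
    vals <- withr::with_seed(s, 28.7 + stats::rnorm(length(tt), 0, 0.6))
    compute_tau0(temperature_series(tt, tau_avg = vals), roi_config())$tau0
  }, numeric(1))
  se <- 0.6 / sqrt(length(tt)) / sqrt(200)
  expect_lt(abs(mean(est) - 28.7), 3 * se)
})

test_that("normalization divides through and round-trips", {
  tt <- seq(10, 100, by = 10)
  tau <- seq(30, 21, by = -1)
  s <- temperature_series(tt, tau_avg = tau)
  n1 <- normalize_series(s, 30)
  expect_equal(n1$ratio, tau / 30)
  expect_equal(normalize_series(s, 30)$ratio,
               2 * normalize_series(s, 60)$ratio)
  expect_equal(n1$ratio * 30, n1$tau_avg, tolerance = 1e-12)
  # lifetime-scale uncertainty propagated by the same division
  s2 <- temperature_series(tt, tau_avg = tau, sd = rep(0.6, 10))
  expect_equal(normalize_series(s2, 30)$sd, rep(0.02, 10))
  # ratio-scale uncertainty (ratio already present) stays as-is
  s2r <- temperature_series(tt, tau_avg = tau, ratio = tau / 30,
                            sd = rep(0.02, 10))
  expect_equal(normalize_series(s2r, 30)$sd, rep(0.02, 10))
  expect_error(normalize_series(s, 0), "tau0")
  # all-equal case normalizes to exactly 1
  s3 <- temperature_series(tt, tau_avg = rep(28.7, 10))
  expect_equal(normalize_series(s3, 28.7)$ratio, rep(1, 10))
})

test_that("series CSV round-trips numeric fields losslessly", {
  s <- temperature_series(
    c(10.123456789012345, 100, 200.5),
    tau_avg = c(28.69999999999, 28.7, 14.35),
    ratio = c(28.69999999999, 28.7, 14.35) / 28.7,
    sd = c(0.6, 0.6, 0.3))
  path <- tempfile(fileext = ".csv")
  write_series(s, path)
  s2 <- read_series(path)
  expect_equal(s2$temperatures, s$temperatures, tolerance = 1e-14)
  expect_equal(s2$tau_avg, s$tau_avg, tolerance = 1e-14)
  expect_equal(s2$ratio, s$ratio, tolerance = 1e-14)
  expect_equal(s2$sd, s$sd, tolerance = 1e-14)
})

test_that("malformed series files are rejected with row numbers", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("temperature_K,tau_ms,ratio,sd",
               "100,28.7,,", "90,28.6,,", "110,28.5,,"), path)
  expect_error(read_series(path), "row\\(s\\) 2")
  writeLines(c("temperature_K,tau_ms,ratio,sd",
               "100,28.7,,", "110,abc,,"), path)
  expect_error(read_series(path), "non-numeric tau_ms at row\\(s\\) 2")
  writeLines(c("kelvin,tau_ms", "100,28.7"), path)
  expect_error(read_series(path), "temperature_K")
  # ratio-only file is a documented mode
  writeLines(c("temperature_K,tau_ms,ratio,sd",
               "100,,1.0,", "200,,0.8,", "210,,0.6,"), path)
  s <- read_series(path)
  expect_null(s$tau_avg)
  expect_equal(s$ratio, c(1.0, 0.8, 0.6))
})

test_that("decay fits serialize to JSON with every reported field", {
  acq <- acquisition_spec(n_bins = 1000)
  fit <- fit_multiexponential(
    simulate_decay(lifetime_mixture(1, 10), acq, seed = 3))
  path <- tempfile(fileext = ".json")
  write_decay_fit(fit, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$lifetimes_ms, fit$mixture$lifetimes)
  expect_equal(js$tau_avg_ms, fit$tau_avg)
  expect_equal(js$selection_trace$reduced_chi2,
               fit$selection_trace$reduced_chi2)
})

test_that("decay trace CSV + sidecar round-trips with its label", {
  acq <- acquisition_spec(n_bins = 64)
  tr <- simulate_decay(default_plateau_mixture(), acq, seed = 2,
                       temperature = 120)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$counts, tr$counts)
  expect_equal(tr2$times, tr$times, tolerance = 1e-12)
  expect_equal(tr2$temperature, 120)
})
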