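#' Photon-counting acquisition settings
#'
#' Describes how a decay trace is acquired: bin width (default 0.08 ms, the
#' instrument's time resolution), number of bins, number of summed
#' excitation flashes (default 14000), the expected number of detected
#' photons per flash at t = 0 per unit amplitude, and a constant expected
#' background per bin. The excitation pulse (2 us fwhm, far below the bin
#' width) is modeled as a delta function; no instrument-response convolution
#' is applied.
#'
#' @param n_bins number of time bins, >= 10.
#' @param bin_width bin width in ms, > 0.
#' @param n_flashes number of summed flashes, >= 1.
#' @param counts_per_flash_scale expected detected photons per flash at t = 0
#'   per unit amplitude, >= 0.
#' @param background_rate expected background counts per bin, >= 0.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_bins, bin_width = 0.08, n_flashes = 14000L,
                             counts_per_flash_scale = 0.05,
                             background_rate = 0) {
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (!is.finite(n_bins) || n_bins < 10) stop("n_bins must be >= 10")
  if (!is.finite(n_flashes) || n_flashes < 1) stop("n_flashes must be >= 1")
  if (!is.finite(counts_per_flash_scale) || counts_per_flash_scale < 0)
    stop("counts_per_flash_scale must be >= 0")
  if (!is.finite(background_rate) || background_rate < 0)
    stop("background_rate must be >= 0")
  structure(
    list(bin_width = bin_width, n_bins = as.integer(n_bins),
         n_flashes = as.integer(n_flashes),
         counts_per_flash_scale = counts_per_flash_scale,
         background_rate = background_rate),
    class = "acquisition_spec"
  )
}

#' Analytic expected counts per bin for a mixture under an acquisition
#'
#' The exact integral of the multi-exponential decay over each bin:
#' the expected count in bin \eqn{[t, t+\Delta)} is
#' \deqn{b + F s \sum_i A_i \tau_i (e^{-t/\tau_i} - e^{-(t+\Delta)/\tau_i})}
#' with F the number of flashes, s the per-flash count scale and b the
#' background rate. Using the bin integral rather than the midpoint value
#' removes discretization bias from lifetime-recovery studies.
#'
#' @param mixture a [lifetime_mixture()].
#' @param acq an [acquisition_spec()].
#' @return numeric vector of expected counts, one per bin.
#' @export
expected_bin_counts <- function(mixture, acq) {
  stopifnot(inherits(mixture, "lifetime_mixture"),
            inherits(acq, "acquisition_spec"))
  t0 <- (seq_len(acq$n_bins) - 1L) * acq$bin_width
  sig <- rowSums(vapply(seq_len(mixture$n), function(i) {
    a <- mixture$amplitudes[i]
    tau <- mixture$lifetimes[i]
    a * tau * (exp(-t0 / tau) - exp(-(t0 + acq$bin_width) / tau))
  }, numeric(length(t0))))
  acq$background_rate + acq$n_flashes * acq$counts_per_flash_scale * sig
}

#' Simulate one photon-counting decay trace
#'
#' Draws each bin count from a Poisson distribution whose mean is the exact
#' bin integral of the mixture decay (see [expected_bin_counts()]). The seed
#' is applied locally: identical `(mixture, acq, seed)` give bitwise
#' identical traces, and the caller's RNG state is untouched.
#'
#' @param mixture a [lifetime_mixture()] (validated on construction).
#' @param acq an [acquisition_spec()].
#' @param seed integer seed for this call.
#' @param temperature optional temperature label (K) stored on the trace.
#' @return a [decay_trace()] with generator provenance in `meta`.
#' @export
simulate_decay <- function(mixture, acq, seed, temperature = NA_real_) {
  stopifnot(inherits(mixture, "lifetime_mixture"),
            inherits(acq, "acquisition_spec"))
  mu <- expected_bin_counts(mixture, acq)
  counts <- withr::with_seed(as.integer(seed),
                             stats::rpois(length(mu), mu))
  decay_trace(
    times = (seq_len(acq$n_bins) - 1L) * acq$bin_width,
    counts = counts,
    temperature = temperature,
    meta = list(
      generator = "simulate_decay",
      seed = as.integer(seed),
      true_amplitudes = mixture$amplitudes,
      true_lifetimes = mixture$lifetimes,
      true_tau_avg = ensemble_average_lifetime(mixture),
      acquisition = unclass(acq)
    )
  )
}

#' Design of a simulated warming experiment
#'
#' The temperature grid (default: 10 K steps through the frozen plateau,
#' 5 K steps across the transition), the frozen-state decay mixture, the
#' ground-truth two-state parameters, and the Gaussian noise level applied
#' to the normalized ratio by the fast series-level generator.
#'
#' @param true_params a [two_state_params()] used as generator truth.
#' @param temperatures temperature grid (K), strictly increasing.
#' @param plateau_mixture frozen-state [lifetime_mixture()]; defaults to a
#'   3-component mixture whose ensemble average equals `true_params$tau0`.
#' @param noise_sd Gaussian sd on the normalized ratio, >= 0 (series-level
#'   generator only; trace-level noise is Poisson).
#' @return an object of class `series_design`.
#' @export
series_design <- function(true_params,
                          temperatures = c(seq(10, 180, by = 10),
                                           seq(185, 245, by = 5)),
                          plateau_mixture = NULL,
                          noise_sd = 0.02) {
  stopifnot(inherits(true_params, "two_state_params"))
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 1L) stop("empty temperature list")
  if (any(temperatures <= 0)) stop("temperatures must be > 0 K")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(plateau_mixture))
    plateau_mixture <- default_plateau_mixture(true_params$tau0)
  stopifnot(inherits(plateau_mixture, "lifetime_mixture"))
  structure(
    list(temperatures = temperatures, plateau_mixture = plateau_mixture,
         true_params = true_params, noise_sd = noise_sd),
    class = "series_design"
  )
}

#' Simulate a normalized lifetime series (fast, series-level noise)
#'
#' Evaluates the two-state model at the design's ground-truth parameters for
#' every temperature and adds Gaussian noise of sd `noise_sd` to the
#' normalized ratio (clipped to stay positive). The unnormalized average
#' lifetime `ratio * tau0` is carried alongside, and the generator truth is
#' embedded in the provenance.
#'
#' @param design a [series_design()].
#' @param seed integer seed for this call.
#' @return a [temperature_series()] with `ratio`, `tau_avg`, `sd` and
#'   ground-truth provenance.
#' @export
simulate_series <- function(design, seed) {
  stopifnot(inherits(design, "series_design"))
  p <- design$true_params
  r <- two_state_ratio(p, design$temperatures)
  if (design$noise_sd > 0) {
    noise <- withr::with_seed(
      as.integer(seed),
      stats::rnorm(length(r), 0, design$noise_sd))
    r <- pmax(r + noise, 1e-9)
  }
  temperature_series(
    design$temperatures,
    tau_avg = r * p$tau0,
    ratio = r,
    sd = if (design$noise_sd > 0) rep(design$noise_sd, length(r)) else NULL,
    provenance = list(
      generator = "simulate_series",
      seed = as.integer(seed),
      noise_sd = design$noise_sd,
      tau0 = p$tau0,
      true_params = unclass(p)
    )
  )
}

#' Simulate a full warming experiment as decay traces (trace-level noise)
#'
#' At each design temperature the frozen-state mixture's lifetimes are all
#' scaled by the noiseless two-state ratio r(T) — a uniform scaling, so the
#' ensemble-average lifetime scales by exactly r(T) — and a Poisson
#' photon-counting trace is simulated. Child seeds are derived
#' deterministically from `seed` (seed*1000 + index), so one seed fixes the
#' whole experiment while traces stay independent.
#'
#' @param design a [series_design()].
#' @param acq an [acquisition_spec()].
#' @param seed integer seed; must satisfy seed*1000 + n_temperatures < 2^31.
#' @return a list of [decay_trace()] objects, one per temperature, labeled
#'   with their temperature.
#' @export
simulate_experiment <- function(design, acq, seed) {
  stopifnot(inherits(design, "series_design"),
            inherits(acq, "acquisition_spec"))
  seed <- as.integer(seed)
  if (abs(seed) * 1000 + length(design$temperatures) >= 2^31)
    stop("seed too large to derive per-temperature child seeds")
  lapply(seq_along(design$temperatures), function(i) {
    temp <- design$temperatures[i]
    r <- two_state_ratio(design$true_params, temp)
    mx <- scale_lifetimes(design$plateau_mixture, r)
    tr <- simulate_decay(mx, acq, seed = seed * 1000L + i,
                         temperature = temp)
    tr$meta$true_ratio <- r
    tr$meta$true_params <- unclass(design$true_params)
    tr
  })
}
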