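# shared fixtures, built in code

# reference two-state parameter rows used as generator ground truth
ref_rows <- function() {
  df <- zn_hba_reference_params()
  lapply(seq_len(nrow(df)), function(i) {
    two_state_params(df$delta_E[i], df$delta_S[i], df$K_d[i],
                     tau0 = df$tau0[i])
  })
}

# random valid two-state parameters for property-style loops
random_params <- function(rng_seed) {
  withr::with_seed(rng_seed, {
    two_state_params(
      delta_E = runif(1, 40, 130),
      delta_S = runif(1, 150, 550),
      K_d = runif(1, 1.2, 40),
      tau0 = runif(1, 20, 35)
    )
  })
}

# noiseless trace with exact analytic bin means (no Poisson draw)
noiseless_trace <- function(mixture, acq, temperature = NA_real_) {
  decay_trace(
    times = (seq_len(acq$n_bins) - 1L) * acq$bin_width,
    counts = expected_bin_counts(mixture, acq),
    temperature = temperature
  )
}

# transition-window design used by the recovery studies:
# 13 points, 185-245 K in 5 K steps, Gaussian ratio noise sd 0.02
recovery_design <- function(params, noise_sd = 0.02) {
  series_design(params, temperatures = seq(185, 245, by = 5),
                noise_sd = noise_sd)
}
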