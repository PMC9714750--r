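# phosdyn

Protein conformational dynamics from oxygen-quenched phosphorescence
lifetimes.

## The problem

The millisecond phosphorescence of a Zn-protoporphyrin probe substituted
into the β-subunits of hemoglobin is quenched by molecular oxygen only when
the protein matrix is dynamically active: in the frozen matrix O₂ cannot
diffuse and the triplet lifetime is long, while thermal activation of
matrix dynamics lets O₂ reach the probe and shortens the decay. Measuring
the decay at thermal equilibrium from cryogenic temperatures upward
therefore turns the ensemble-average lifetime ⟨τ⟩(T) into a read-out of
protein dynamic activation, with a protein-specific transition near 200 K.
`phosdyn` implements the complete two-stage analysis of such experiments,
plus a synthetic-data generator with known ground truth, so every stage is
testable without access to a spectrometer.

**Stage 1 — decay deconvolution.** Each photon-counting trace is fitted
with a discrete sum of exponentials

    I(t) = b + Σᵢ Aᵢ exp(−t/τᵢ),   n ≤ 5,

by Poisson maximum likelihood with nonnegative amplitudes, the component
count chosen incrementally (stop when the reduced goodness improves by
< 5 % or the newest component carries < 0.1 % of the amplitude). The trace
is summarized by the intensity-weighted ensemble-average lifetime

    ⟨τ⟩ = Σ Aᵢτᵢ² / Σ Aᵢτᵢ.

**Stage 2 — two-state thermodynamics.** ⟨τ⟩ is flat from 10 K to about
180 K; its mean over that window is the frozen-state reference τ₀. The
normalized series ⟨τ⟩/τ₀ is fitted over the transition window with the
two-state (frozen/molten) activation model

    ⟨τ⟩/τ₀ (T) = (1 + x) / (1 + K_d·x),   x = exp(−(ΔE − TΔS)/RT),

where ΔE (kJ/mol) and ΔS (J/(mol K)) are the molar energy and entropy
differences between the frozen and molten states and K_d ≥ 1 is the factor
by which the decay is sped up under dynamic quenching. The transition
midpoint obeys

    T_MP = ΔE / (ΔS + R·ln K_d).

Fits return covariance- or bootstrap-based standard deviations and the
negative derivative −d(⟨τ⟩/τ₀)/dT whose peak marks the transition.

## Worked example

Simulate a warming series from known thermodynamic parameters, estimate
τ₀ from the frozen plateau, and refit the model:

```r
library(phosdyn)

truth  <- two_state_params(delta_E = 113.4, delta_S = 526, K_d = 2.0,
                           tau0 = 28.7)
midpoint_temperature(truth)
#> [1] 213.253

design <- series_design(truth, noise_sd = 0.02)
series <- simulate_series(design, seed = 42)
b      <- compute_tau0(series)          # frozen-window mean: 28.86 +/- 0.69 ms
fit    <- fit_transition(normalize_series(series, b$tau0))
fit
#> <transition_fit_result>
#>   delta_E = 111.6 +/- 20 kJ/mol
#>   delta_S = 515.4 +/- 92 J/(mol K)
#>   K_d     = 2.052 +/- 0.066
#>   T_MP    = 214.02 +/- 0.69 K
#>   reduced chi2 = 2.43 on 14 points (covariance SDs)
```

The generator's parameters (ΔE = 113.4, ΔS = 526, K_d = 2.0; T_MP =
213.25 K) are recovered within the quoted uncertainties from a single
noisy series. `run_pipeline()` drives the full trace-level path
(decay fits → ⟨τ⟩ series → τ₀ → transition fit) and writes every
intermediate artifact; the numbered scripts under `analysis/` run the
whole study end to end:

1. `01_simulate_experiment.R` — Poisson photon-counting traces across a
   10 K / 5 K warming grid (ground truth: the stripped-hemoglobin
   parameter row);
2. `02_fit_decays.R` — per-trace deconvolution; median |Δ⟨τ⟩|/⟨τ⟩ across
   temperatures ≈ 0.4 %;
3. `03_fit_transition.R` — normalization and transition fit (recovers
   ΔE = 112.2 ± 2.8 kJ/mol, ΔS = 520.7 ± 13.0 J/(mol K),
   K_d = 1.989 ± 0.008 against the 113.4 / 526 / 2.0 truth);
4. `04_parameter_recovery.R` — 100-replicate recovery study for all five
   reference parameter rows (worst median errors: ΔE 0.5 %, ΔS 0.3 %,
   K_d 2.9 %).

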