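---
title: "Methods: phosphorescence lifetime analysis and the two-state activation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphorescence lifetime analysis and the two-state activation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosdyn)
```

## The measurement and its model

A Zn-protoporphyrin triplet probe embedded in hemoglobin phosphoresces
with millisecond lifetimes. Dissolved O₂ quenches the triplet only if it
can diffuse through the protein matrix, and that diffusion requires
thermally activated matrix dynamics. Recording the decay at equilibrium
temperatures from 10 K upward therefore maps the onset of protein
dynamics: the ensemble-average lifetime is constant over the frozen
regime and drops sharply once dynamic quenching switches on, with a
protein-specific step near 200 K (a second, solvent-driven step at higher
temperature is outside this package's scope).

`phosdyn` covers the full inference chain and a generator of synthetic
data with known ground truth.

### Stage 1: decay deconvolution

The decaying emission of a conformationally heterogeneous ensemble is
modeled as a discrete mixture, $I(t) = b + \sum_{i=1}^{n} A_i
e^{-t/\tau_i}$ with $n \le 5$, $A_i \ge 0$, $b \ge 0$. Five components
are the practical ceiling for an acceptable fit of these decays; the
nonnegativity reflects a ground-state population decaying from a single
excited species per molecule, which cannot produce negative
pre-exponentials. The per-trace summary is the intensity-weighted average
$\langle\tau\rangle = \sum A_i\tau_i^2 / \sum A_i\tau_i$, the first
moment of the multi-exponential decay — `moment_average_oracle()`
computes the same quantity directly from background-subtracted counts and
serves as a model-free cross-check (biased low when the tail is
truncated; it reports the estimated truncation fraction).

Numerical choices that matter:

* **Bin-integrated basis.** Counts are photon sums over 0.08 ms bins, so
  the model is evaluated as the exact exponential integral over each bin,
  not the midpoint value. The fitted amplitudes then stay proportional to
  the continuous-model amplitudes and $\langle\tau\rangle$ carries no
  discretization bias. The same basis is used by the simulator and the
  fitter, with the excitation pulse (2 µs, 1/40 of a bin) treated as a
  delta function; an instrument-response convolution is deliberately not
  modeled, since its effect at this bin width is far below counting
  noise.
* **Poisson maximum likelihood.** The `"poisson"` objective minimizes the
  Poisson deviance via signed deviance residuals inside
  Levenberg–Marquardt. Chi-squared weighting with observed counts
  ($1/\max(c_j,1)$) biases low-count bins toward downward fluctuations
  and depressed the recovered $\langle\tau\rangle$ of the reference
  frozen-state mixture by ≈ 10 %; model-variance weights bias the other
  way (≈ +4 %); the deviance objective showed no measurable bias
  (≈ 0.002 % median over 20 replicate traces). The unit deviance is
  evaluated in the cancellation-safe form
  $2\mu[(1+d)\log(1+d) - d]$, $d=(y-\mu)/\mu$, near $y=\mu$, which keeps
  the optimizer stable on noiseless traces where the naive form hits
  floating-point cancellation.
* **Separable warm start, bounded refinement.** For each candidate $n$,
  lifetimes start on the interior of a logarithmic grid spanning
  $[2\Delta, 2T_\mathrm{end}]$, amplitudes and background come from
  nonnegative linear least squares at those fixed lifetimes, and all
  $2n+1$ parameters are refined by box-bounded Levenberg–Marquardt on
  log-lifetimes. A second start augments the previous $n$'s solution with
  one component at the largest spectral gap, and the better optimum is
  kept — this makes the objective non-increasing in $n$. A final restart
  from the optimum re-expands the trust region and tightens
  near-zero-residual solutions to machine precision (the fit is an exact
  fixed point under refitting its own prediction).
* **Model selection.** $n$ grows from 1 and stops when the reduced
  goodness improves by less than 5 % or the newest component carries less
  than 0.1 % of the total amplitude. Lifetimes that converge within
  relative $10^{-3}$ are merged (amplitude-weighted) and the smaller
  model refitted. The background is a free nonnegative constant: with a
  multichannel counting chain there is no a-priori zero level, and fixing
  it to zero would bias tails.

### Stage 2: baseline and the two-state activation model

$\langle\tau\rangle$ over the 10–180 K window fluctuates without trend;
its mean is the frozen-state reference $\tau_0$ (sample SD reported).
Fitting works on the normalized ratio with $\tau_0$ fixed — a two-stage
normalize-then-fit procedure rather than co-fitting $\tau_0$, which keeps
the baseline estimate independent of the transition model.

The transition is modeled as a two-state equilibrium between a frozen
state (decay rate $1/\tau_0$) and a thermally activated "molten" state
whose decay is sped up by $K_d$. With Boltzmann occupancy
$f = x/(1+x)$, $x = e^{-(\Delta E - T\Delta S)/RT}$, the observed rate is
the population-weighted mean rate, giving

$$\frac{\langle\tau\rangle}{\tau_0}(T) = \frac{1 + x}{1 + K_d x},
\qquad T_{MP} = \frac{\Delta E}{\Delta S + R\ln K_d},$$

which falls from 1 to $1/K_d$ with midpoint $T_{MP}$. Parameters and
units: $\Delta E$ in kJ/mol (converted to J/mol internally), $\Delta S$
in J/(mol K), $K_d \ge 1$ dimensionless, $R = 8.314$ J/(mol K). The
exponent is clamped to $[-700, 700]$ and the ratio evaluated via
`log1p`, so extreme arguments saturate instead of overflowing.

Fit-window defaults are `[10, 180]` K for the baseline (180 K is where
the plateau demonstrably ends) and `[180, 245]` K for the transition
(245 K keeps the solvent-driven second step out of the fit); both are
configurable through `roi_config()`. Initialization is deterministic:
$\Delta E^0 = 100$ kJ/mol, $\Delta S^0$ set so $\Delta E^0/\Delta S^0$
equals the temperature of the steepest observed drop, and
$K_d^0 = 1/\min(\text{ratio})$. A series whose minimum ratio stays above
0.95 in the window is rejected as non-identifiable rather than fitted.

Uncertainties default to the covariance of the fit (finite-difference
Jacobian at the optimum, residual-variance scaled); a seeded
nonparametric residual bootstrap (≥ 500 replicates) is the alternative,
and the method plus its settings are always recorded in the result. The
$T_{MP}$ SD propagates through the midpoint formula by the delta method
(or the bootstrap spread). How published SDs of this kind of fit were
obtained is generally not stated, so both routes are first-class.

## What the generator emulates — and what it does not

Two fidelity levels, both seeded per call with no global RNG state:

* `simulate_series()` evaluates the two-state model on the design's
  temperature grid and adds Gaussian noise (default sd 0.02) to the
  ratio. The grid default mirrors the experimental warming protocol:
  10 K steps through the plateau, 5 K steps across the transition. The
  `sd` of a series rides on the ratio scale when a ratio is present and
  on the ms scale otherwise; `normalize_series()` respects that
  convention.
* `simulate_decay()` / `simulate_experiment()` draw Poisson counts around
  exact per-bin integrals at the acquisition's scale: 0.08 ms bins,
  14 000 summed flashes, and an expected 0.05 detected photons per flash
  per unit amplitude. That last number is a fidelity knob, not a measured
  quantity — it yields ≈ 5×10⁴ photons per summed trace, a realistic
  scale for a weak, heavily quenched phosphorescence signal in
  single-photon counting. The frozen-state mixture defaults to three
  equal-amplitude components with lifetimes in the ratio 0.6 : 1 : 1.6,
  scaled so the ensemble average matches the requested $\tau_0$
  (28.7 ms, the stripped-hemoglobin reference); real decays are
  heterogeneous but their component structure is unknown, so only the
  average is pinned. In `simulate_experiment()` every component lifetime
  is scaled by the model ratio $r(T)$ — uniform scaling, so by
  homogeneity the ensemble average scales by exactly $r(T)$.

Not emulated: instrument response and excitation pulse width, detector
dead time and afterpulsing, drift between flashes, temperature-dependent
radiative rates, static quencher heterogeneity, and the high-temperature
solvent transition. Passing recovery tests therefore demonstrates the
correctness and statistical calibration of the estimators under the
stated noise models, not robustness to those instrumental effects.

## Study sizes and what the checks show

The package's own validation studies use: 100 replicate series per
reference parameter row (13 points, 185–245 K, noise sd 0.02) for
transition recovery; 20 Poisson traces (≈ 4 700 bins, ≈ 5×10⁴ counts) for
lifetime recovery; 200 replicates for unbiasedness checks of means and
totals. Median recovered $\Delta E$, $\Delta S$, $K_d$ land within a few
percent of truth for all five reference rows, and ±2 SD covariance
intervals cover the truth for ≥ 80 % of replicates.

## Known limitations

* **$K_d$ identifiability at broad transitions.** When the transition is
  wide and the fit window barely reaches the lower plateau (the BZF-like
  row: $T_{MP} \approx 226$ K against a 245 K window edge), individual
  noisy fits can run away along a high-$K_d$ likelihood ridge; they are
  flagged non-convergent and inflate the spread of recovered $K_d$, and
  the across-replicates median of $K_d$ becomes heavy-tailed. Widening
  the window is not an option in the real experiment (the solvent step
  intrudes); treating $1/K_d$ as the bounded parameter would be the
  principled extension.
* A trace-level series (fit per temperature) inherits decay-fit bias at
  strongly quenched temperatures where the signal compresses into few
  bins; at the simulated count scale this stays ≈ 0.5 %.
* Lifetime *distribution* methods (maximum entropy, regularized grids)
  and global multi-trace fitting are out of scope; the discrete mixture
  with $n \le 5$ is the model of record here.
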