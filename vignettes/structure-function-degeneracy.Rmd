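---
title: "Methods: structure-function degeneracy analysis with scfc"
author: "scfc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-function degeneracy analysis with scfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the approach

Resting-state functional connectivity (FC) is routinely read as a window on
brain computation, yet most of its variance across subjects, models and
measures may be fixed by the anatomical wiring. `scfc` operationalizes that
question as a linear-subspace problem: collect many connectivity patterns as
columns of a features-by-observations matrix `X`, decompose `X = U S Vᵗ`,
and ask how many leading dimensions are *reproducible* under resampling of
subjects. If one dimension — a common core scaled per subject by a global
constant — explains most of the sum of squares, then the measure is a
largely degenerate readout of structural connectivity (SC); genuinely
dynamical structure would have to live in the residual.

Three design commitments follow from that framing and shape everything else:

1. **The SVD is uncentered.** The object of interest is the shared positive
   core itself. Removing the column mean would subtract exactly the
   structure under study and turn the first dimension into a contrast.
   Variance fractions are therefore `s_i² / Σ_j s_j²` of the raw matrix.
   This choice changes every number and is deliberate.
2. **The bootstrap unit is the subject.** All columns belonging to one
   subject (e.g. its patterns under every generative model, in pooled
   matrices) enter or leave a bootstrap replicate together. Percentile
   intervals (95% by default; the level is configurable, as no canonical
   choice exists) on each singular value define the reproducible dimension
   `d`: the largest `d` such that, for every `i ≤ d`, the CI of `s_i` is
   disjoint from the CI of `s_{i+1}`. The contiguous reading is the default;
   a "last separated pair" variant is available (`rule = "last"`) because
   the informal phrase "the last such singular value" admits both readings.
3. **Permutation controls calibrate the machinery.** Independently per
   subject, entry labels (links), region labels, or within-hemisphere region
   labels (with homotopic pairing preserved) are permuted. These destroy the
   anatomical alignment across subjects; the bootstrap analysis should then
   find no reproducible subspace. Note one subtlety the tests encode: a
   pattern whose entries have a large common mean survives entry permutation
   as a shared constant component, so destruction tests are only meaningful
   on roughly zero-mean patterns (such as FC after global signal
   regression).

## The synthetic cohort: what it emulates, and what it does not

No empirical cohort ships with the package; the generator produces data with
the statistical structure the analyses assume, so every stage is testable
end to end.

- **Atlas.** `n` regions, `n/2` per hemisphere, region `i` paired with
  `i + n/2`. The canonical ordering makes homotopy manipulations
  index-computable and bit-reproducible.
- **Ground-truth SC.** Within-hemisphere edges with probability
  `density_intra` (default 0.3), cross-hemisphere non-homotopic edges with
  `density_inter` (0.05), lognormal weights with median `weight_scale`
  (0.01) and log-sd `weight_log_sd` (1) — heavy-tailed, as tractography
  indices are — and every homotopic pair set to `homotopic_weight` (0.5, the
  same value used by the homotopic-manipulation experiment). Intra-
  hemispheric subgraphs are resampled until connected so that coupled
  dynamics cannot split into isolated components.
- **Subjects.** `SC_s = g_s · core + noise`, with `g_s = exp(N(0, 0.2²))`
  and entrywise Gaussian noise (sd 0.002, one fifth of the median weight),
  clipped at zero and thresholded at 0.001 — measure first, then threshold.
  This reproduces the empirically observed situation in which individual
  connectomes differ essentially by a global multiplicative constant, while
  leaving a tunable residual.
- **Measurement degradation.** `degrade_sc()` zeroes each nonzero
  interhemispheric unordered pair independently with probability
  `interhemispheric_miss_rate` (default 0.8). In the experiment suite the
  dropout is drawn *once* on the shared core and inherited by every
  subject's measured SC: diffusion tractography misses interhemispheric
  (especially homotopic) connections systematically, not independently per
  person. Independent per-subject dropout would inject large cross-subject
  variance into precisely the largest entries and, at small cohort sizes,
  erase the rank-1 structure the cohort is meant to display.
- **Planted low-rank fixtures.** `planted_lowrank_dataset()` builds
  `X = Σ s_i u_i v_iᵗ + noise` with singular values chosen so the requested
  variance fractions hold for the total (signal plus expected noise) sum of
  squares. The observation loadings `v_i` are jittered sign patterns of
  near-constant magnitude rather than Haar-random orthonormal vectors: with
  Haar loadings a planted dimension can concentrate on two or three
  subjects, and subject resampling then makes its singular value arbitrarily
  unstable no matter how large it is — parameter recovery would fail for
  reasons unrelated to the method. Near-uniform loadings are also what the
  multiplicative-gain cohort model produces naturally.

What the generator does **not** emulate: spatial autocorrelation of regions,
distance-dependent connection probability, head-motion and physiological
artifacts, scanner drift, non-stationarity of the hemodynamic response, and
inter-subject anatomical variability beyond a scalar gain. Passing tests
therefore demonstrate that the machinery does what it claims on data with
the assumed structure — not that real data have that structure.

## Generative models

All time-domain models couple region `i` to the network through
`G · (W x)_i`, with `W` the row-normalized SC. Row normalization is a
modelling choice (the input scale of a region does not grow with its degree)
with the practical consequence that stability is controlled by `G` alone,
independent of the SC's overall scale. The regimes and their constants
(`default_model_params()`; all overridable):

| model | state | constants (defaults) | observable |
|---|---|---|---|
| `sar` | equilibrium | — | analytic correlation of `σ²(I − GW)⁻¹(I − GW)⁻ᵗ` |
| `rate` | `x` | `tau = 0.1 s` | `x` |
| `kuramoto` | phase `θ` | `f0 = 1 Hz`, `f_sd = 0.1 Hz` | `sin θ` |
| `wilson_cowan` | `E, I` | classic oscillatory set, `tau = 10 ms` | `E` |
| `fitzhugh_nagumo` | `v, w` | `a = 0.7, b = 0.8, φ = 0.08, I = 0.4, tau = 20 ms` | `v` |

Integration is Euler–Maruyama at `dt = 1 ms` (bias controlled by `dt` and
testable against finer steps), burn-in 10 s, observable stored every 10 ms.
All noise flows through R's RNG, so a `(seed, config)` pair determines every
trajectory bit-for-bit. The SAR model has no time-domain simulation: its FC
is computed from the closed-form covariance and, consistently, no global
signal regression is applied to it (`gsr_applied = FALSE`).

Coupling defaults sit in the weakly-coupled, responsive regime. Mean
functional coupling grows with `G` from zero *within that regime*; at strong
coupling the Wilson–Cowan sigmoid saturates and FitzHugh–Nagumo oscillations
are quenched, so the monotone trend reverses. The property tests assert the
trend up to model-specific couplings below saturation. `tune_global_coupling()`
grid-searches `G` against a target FC (Pearson correlation of vectorized
patterns), seeding each grid point reproducibly and breaking ties toward the
smaller coupling.

## Hemodynamics

The Balloon–Windkessel model maps the neural observable to BOLD per region
through the standard four states (vasodilatory signal, inflow, venous
volume, deoxyhemoglobin) with the widely used constants `κ = 0.65 s⁻¹`,
`γ = 0.41 s⁻¹`, `τ = 0.98 s`, `α = 0.32`, `E₀ = 0.34`, `V₀ = 0.02` and the
percent-signal-change read-out `100 V₀ (k₁(1−q) + k₂(1−q/v) + k₃(1−v))`.
The integrator runs on the neural sampling grid with internal substeps
capped at 5 ms (the dense-step reference oracle in the test suite showed
visible Euler truncation error at a 100 ms grid); BOLD is then sampled every
`tr` (default 3.29 s, so 200 volumes span ~11 min and the shortest dynamic-FC
window of 8 samples lasts 26.32 s). `simulate_bold()` additionally discards
the first 6 volumes so the hemodynamic states forget their initial
conditions.

## Connectivity measures

- **Vectorization** is lexicographic `(i, j), i < j` (pairs) and
  `(i, j, k), i < j < k` (triplets); at 160 regions this gives 12 720 pair
  and 669 920 triplet coefficients, 6 320 of the pairs intrahemispheric.
- **Global signal regression** removes intercept plus across-region mean by
  least squares; a constant global signal degrades to intercept-only with a
  warning rather than an error.
- **Mutual information and 3-way total correlation** use the Kraskov-type
  kNN estimator (algorithm-1 form, generalized to `d` variables), `k = 4` by
  default and natural logarithms. The estimator is deterministic (strict
  inequality in the neighbour counts, no jitter); small negative estimates
  are a known finite-sample artifact and are retained, not clipped (the
  documented tolerance is ε = 0.1). The estimator is biased low for
  near-singular dependence (true information ≳ 1 nat at the sample sizes
  used here), which is why the Gaussian-oracle checks probe correlations up
  to 0.9 (MI) and |ρ| ≤ 0.7 (CT3) and why `y = x` merely asserts growth
  with `n`. Closed forms `−½ ln(1 − ρ²)` and `−½ ln det R` serve as oracles
  for Gaussian data.
- **CT3 cost.** `C(n, 3)` triplets times an `O(T²)` estimator makes CT3 the
  pipeline's hotspot; above 20 000 triplets the call requires
  `allow_large = TRUE`. The experiment default (40 regions, 9 880 triplets,
  200 samples) runs in ~20 s.
- **Dynamic FC** uses non-overlapping windows ({8, 10, 20, 25, 40, 50, 100}
  samples by default, all divisors of 200); windows that do not divide the
  run length are an error unless `truncate = TRUE`. Pearson's internal
  centering is the only demeaning applied per window.

## Inverting the SC-FC relationship

The first-dimension SC pattern is transformed by `SC′ = ln(SC / 10⁻⁴)` on
entries ≥ 10⁻⁶; a 4th-order polynomial `FC ≈ P₄(SC′)` is then fitted by
least squares (true interpolation through thousands of scattered points
would be ill-posed) between the SC pattern and the first-dimension pattern
of the pooled FC. Inversion maps the *empirical* FC first-dimension pattern
(the empirical columns' average projection onto the pooled first singular
vector) through `P₄⁻¹` — numerically, bisection to 10⁻¹⁰ on the largest
monotone branch of `P₄` covering the central 90% of the fitted `SC′` mass;
if no single branch covers it, the error lists the turning points. FC values
outside the branch's range are clamped to the boundary and flagged. Finally
`SĈ = 10⁻³ · exp(P₄⁻¹(FC))`.

Two deliberate asymmetries: the forward reference constant (10⁻⁴) and the
output constant (10⁻³) differ by a factor of ten and are kept independently
configurable rather than silently reconciled — the self-inversion tests set
`ref_out = ref`. And entries masked out of the fit (below the SC floor)
still receive estimates on inversion: recovering connections the SC
measurement missed — homotopic ones above all — is the point of the
exercise, so suppressed entries are extrapolated and flagged rather than
dropped; masked SC entries are excluded from the fit pairing (dropped, not
zero-filled).

## Experiment suite and problem sizes

`run_experiment()` exposes thirteen tags covering the cohort SC, cFC, mFC,
CT3 and raw-BOLD analyses, the no-GSR variant, the three permutation
controls, simulated-only, pooled and residual FC, the average-subject
homotopic manipulation (homotopic entries set to 0.5), and windowed dynamic
FC. The package's default configuration — 40 regions, 5 subjects, 200
volumes, three models (SAR, Kuramoto, rate), B = 200 — was chosen so the
full suite of tags completes in about a minute on one CPU while preserving
every qualitative behaviour of interest: the SC cohort collapses to one
reproducible dimension; the pooled first dimension correlates strongly with
the true SC; the residual (empirical − simulated) first dimension loads
preferentially on interhemispheric pairs; permuted cohorts yield `d = 0`.
The full-scale setting (160 regions, 21 subjects, 7 models, B = 1000) is
reached by overriding `experiment_config()` fields; CT3 at 160 regions
(669 920 triplets) is the one stage that then requires hours rather than
minutes. The average-subject analysis uses a plain SVD (one column per
source; no subjects to resample), and the residual analysis uses the
bootstrap like every other multi-subject dataset.

## Numerical choices, edge cases, limitations

- Singular vectors are sign-aligned by orienting each left-singular vector
  to positive mean entry; bootstrap replicates contribute only singular
  values (components are matched by rank, not permutation-matched), so no
  per-replicate alignment is needed. Replicates drawing a single distinct
  subject are redrawn and counted.
- Bootstrap summaries are reported both on raw singular values (which define
  `d`) and on variance fractions (the conventional reporting scale).
- All randomness derives from one integer master seed through hashed
  substreams per (operation, subject, replicate); identical seeds give
  byte-identical cohorts, trajectories, bootstraps and reports.
- Zero-variance regions make Pearson FC an error by default
  (`drop_zero_variance = TRUE` drops them explicitly); non-finite states in
  any integrator raise a divergence error naming the blow-up time.
- Limitations: the neural-mass and spiking regimes are not implemented (the
  model interface accepts additional integrators); no uncertainty is
  propagated onto `SĈ`; the polynomial inversion is only defined on one
  monotone branch; and the synthetic cohort's simplifications listed above
  bound what green tests can claim about empirical data.
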