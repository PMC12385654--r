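---
title: "Methods: storage-quality surrogates and condition optimization for fresh wolfberry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: storage-quality surrogates and condition optimization for fresh wolfberry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`berrystore` models how the post-harvest quality of fresh wolfberry — fruit
hardness, soluble solids content (SSC, %), titratable acidity (TA, % malic
acid) and vitamin C (Vc, mg/100 g) — responds to storage temperature
(−4…24 °C), storage time (0…28 d) and initial maturity at harvest (20…90 %),
and optimizes those conditions against all four responses at once. This
vignette documents the models, the tunable parameters and the numerical and
design choices, so that the assumptions behind every number the package
produces are explicit.

All modelling happens on the normalized unit cube: each factor is mapped
linearly from its physical range to [0, 1] (`normalize_points()`), and
out-of-range inputs raise an error rather than being clamped — silent
clamping would hide data-entry mistakes. The design size for a surrogate
study follows the rule n = 2(N+1)(N+2) in the number of factors N, i.e. 40
runs for the three storage factors: roughly twice the 10 coefficients of a
full quadratic model per response, which keeps the polynomial basis
well-identified while staying affordable in a cold-storage experiment.

## Optimized Latin hypercube design

A Latin hypercube design places exactly one point in each of the n
equal-width bins of every dimension. Plain stratified sampling
(`random_lhs()`, backed by the `lhs` package) guarantees marginal coverage
but can still cluster in the joint space. `optimize_design()` therefore
evolves designs with a multi-objective evolutionary algorithm whose
offspring are produced in two streams: a fraction `p` by Latin-hypercube
local search around tournament-selected parents, the rest by
selection/crossover/mutation. Parents whose objective vector is
non-dominated search a box of half-width δ around themselves; dominated
parents search 2δ, trading exploitation against exploration. Parents and
offspring are merged each generation and the best N individuals retained by
non-dominated rank, with crowding distance and then insertion order breaking
ties (the standard NSGA-II convention), so the best design can never be
lost.

Two details are genuinely open in this class of algorithm and were fixed as
follows:

* **Uniformity objectives.** No single uniformity criterion is canonical; we
  maximize the minimum pairwise Euclidean distance (maximin) and minimize
  Hickernell's centered L2 discrepancy simultaneously. Both are standard
  space-filling criteria; optimizing them jointly produces designs that are
  both spread out and marginally balanced. The discrepancy is computed from
  its closed form; no external dependency provides it.
* **Encoding.** Designs evolve as per-column bin permutations with in-bin
  jitter, so every individual decodes to a valid Latin hypercube by
  construction: crossover exchanges whole columns between parents, mutation
  swaps two bins within a column, and local search applies a number of
  in-column swaps that scales with the search radius. This transplants the
  real-vector local-search idea into permutation space without ever breaking
  the Latin invariant.

Defaults (`moea_config()`): N = 20 individuals, G = 30 generations, p = 0.3,
δ = 0.1, H = 3 local samples, Pc = 0.9, Pm = 0.2. The loop bound for the
local-search share is ⌈pN⌉ (the product is non-integer in general), and we
run exactly G generations. The returned design is the non-dominated member
with the largest maximin distance.

## Surrogate models

All three surrogate families map normalized factors to the four responses
and share a data-frame-first interface (`rbf_train()`, `elman_train()`,
`fit_quadratic_rsm()`, each with a `predict()` method returning a tibble).

**Gaussian RBF network.** One hidden unit per training point (centers =
training inputs) responding as exp(−‖x−c‖²/2σ²); the linear output weights
solve the regularized interpolation system (Φ + λI)W = Y analytically — no
iterative training. The ridge floor λ = 1e−10 exists purely for numerical
rank-safety; duplicate training rows raise it to 1e−6 with a warning. At the
floor the network interpolates: training residuals below 1e−6 (relative) are
a tested guarantee at moderate widths. The width σ is selected by
leave-one-out cross-validation over the grid {0.1, 0.5, 1, 5, 10, 50, 100}
on normalized inputs, scoring the variance-scaled mean squared error so that
responses with different units weigh equally; ties go to the smaller width.
The value 100 — reported as the width used in the original study — is
included in the grid, but on a unit cube it is deep in the flat regime where
the kernel matrix is nearly singular; cross-validation is authoritative.

**Elman recurrent network.** Hidden layer of 10 tanh units with a context
layer that replays the previous hidden state (a one-step delay operator);
identity output layer. Weights are initialized uniform(−0.5, 0.5) from a
seed and trained by plain online gradient descent (learning rate 0.01) with
the standard one-step truncation of the context gradient. Since the storage
data are static rows, not a time series, the recursion is only meaningful if
an order is imposed: rows are presented as one ordered sequence per epoch in
dataset order, context reset to zero at each epoch start, and prediction
follows the same convention (`reset = "row"` opts into order-independent
per-row predictions). Responses are z-scored internally before training and
mapped back at prediction; without this the gradient scale differs by three
orders of magnitude between hardness and TA. Stopping: 1000-epoch cap, epoch
MSE (standardized scale) below 1e−5, or mean gradient norm below 1e−6,
whichever fires first; the fit records its `stop_reason` and full error
trace, and a non-finite loss aborts with the epoch index.

**Quadratic response surface.** Ordinary least squares per response on the
10-term basis {1, x₁, x₂, x₃, x₁², x₂², x₃², x₁x₂, x₁x₃, x₂x₃} via
`stats::lm`. A rank-deficient basis is an error; constant responses fit as a
pure intercept with an undefined (NA) R². Noise-free synthetic data
reproduces generating coefficients to 1e−8 at n = 20 — the package's
parameter-recovery guarantee. The surfaces published for this system are
packaged as `eq15_surfaces()`; their three pure quadratic coefficients were
printed without variable symbols and are attached to x₁², x₂², x₃² in that
order, the only reading consistent with the 10-term basis used throughout
the sensitivity analysis. The published hardness surface is on the gram
scale while the 40-run dataset's hardness column is in newtons; both are
kept exactly as printed and never converted.

## Fit metrics and a note on R²

`fit_metrics()` reports RMSE (rooted; the quantity is a root mean square
error even where source typesetting drops the radical), the centered
coefficient of determination R² = 1 − SSE/(ΣM² − (ΣM)²/n) — algebraically
the classical 1 − SSE/SST — MAPE (relative to observed, %), and NRMSE
(RMSE over the observed range; swap in a mean-normalized variant by
computing it from `rmse()` directly).

One empirical caveat matters when judging surrogate accuracy on the packaged
40-run data. Under the centered R² above, held-out accuracy is poor for
every split we screen: the responses scatter strongly around any smooth
function of the three factors (the full-data quadratic fit explains between
19 % and 67 % of variance, as `glance(fit_quadratic_rsm(load_table2()))`
shows). Replacing the centered denominator with the *uncentered* ΣM²
inflates all of these numbers into the 0.85–0.98 range. Published claims of
held-out R² above 0.9 for this dataset are consistent with the uncentered
reading and not with the centered one; the package deliberately reports the
centered statistic, and `screen_heldout_splits()` makes the split-seed
protocol explicit so the gap is reproducible rather than hidden.

## Sensitivity decomposition

`main_effects()` sweeps each factor over equispaced levels and averages
predictions over a background of settings of the other factors. The
background is a deterministic Halton sequence (256 points by default):
deterministic at any dimension, accurate enough that the curve of a
quadratic surface matches a dense-grid average to well under 1 % of the
response range (a tested property), and reproducible without seed
bookkeeping. A seeded Latin hypercube background is available as an option.

`term_contributions()` attributes to each non-intercept term of a quadratic
surface the share |bₜ|/Σ|b|·100, signed by the coefficient. Because inputs
are normalized, absolute coefficients are comparable across terms. This is
a coefficient-share approximation, not a variance decomposition: the
commercial software used in the original study does not disclose its Pareto
formula, and its printed percentages are not reproducible from the printed
coefficients by any simple share. Dominant-term identity and signs are
robust to the choice and are what the package asserts; exact percentages
are not.

## SMPSO storage optimization

The storage problem maximizes all four predicted responses over the
condition box (`storage_problem()`), optionally freezing factors at raw
values — `scenario_query()` freezes storage time, matching the practical
question "given I must store for t days, how should I harvest and at what
temperature?". The optimizer is SMPSO: velocities are scaled by the
constriction factor χ(φ) = 2/|2 − φ − √(φ² − 4φ)| for φ = c₁ + c₂ > 4 (1
otherwise), clamped componentwise to half the variable range, and positions
leaving a bound are clamped with the velocity component reversed. Leaders
come from a crowding-bounded external archive (capacity 100) by binary
crowding tournament; c₁, c₂ are resampled from U(1.5, 2.5) per update;
polynomial mutation (distribution index 20) hits ~15 % of particles;
personal bests update on dominance, with a coin flip when mutually
non-dominated. These internals follow the published SMPSO reference; the
study itself fixes only the swarm size (12) and generation count (50),
read as 600 objective-evaluation rounds. The archive's mutual non-dominance
is verified against a brute-force pairwise oracle in the tests, and the
whole run is reproducible from one seed.

`select_optimal()` implements the automatic choice of a single solution:
min–max normalize each objective across the archive and take the member
closest to the ideal point, ties broken by larger crowding distance and then
by index. On the 40-run data this knee is honest but blunt: maximizing
hardness, SSC, TA and Vc simultaneously rewards corners of the condition box
(cold for hardness, warm for SSC), and with the packaged data's scatter the
selected temperature need not land in the industry cold range. The
acceptance suite therefore treats the published 10-day optimum
(≈10 °C, SSC 17.5 %, TA 1.22 %, Vc 18.5 mg/100 g) as an advisory tolerance
band, not a hard target: those values derive from the original study's
unpublished trained networks, which the printed data and polynomials
contradict.

## Synthetic data: what it does and does not emulate

`generate_from_rsm()` draws responses from a quadratic truth surface plus
independent homoscedastic Gaussian noise per response. This matches the
validation needs of the pipeline (parameter recovery, metric behavior,
optimizer smoke tests) but deliberately ignores heteroscedasticity,
response correlations and batch effects that real storage measurements
carry — passing tests on synthetic data therefore certify the algorithms,
not the field accuracy of any surrogate.

`generate_kinetic_profiles()` produces single-factor sweeps that interpolate
the observed stage-wise anchors exactly: SSC and Vc parabolic in temperature
peaking at 8 °C (24.95 %, 28.37 mg/100 g); hardness strictly decreasing in
temperature; hardness and Vc peaking on day 4 (1636.54 g, 35.16 mg/100 g)
and SSC/TA on day 8 (23.54 %, 1.65 %); hardness and TA falling with
maturity, SSC rising, Vc V-shaped with its green-stage peak at
26.89 mg/100 g. Between anchors the time and maturity profiles use
shape-preserving monotone Hermite splines (no named kinetic law is implied
by the narrative they encode), and temperature profiles use the parabola
through the peak and a reference endpoint. Anchor values that were never
printed — day-0 levels, off-peak endpoints, the maturity mid-points of the
V — are package defaults chosen once to sit inside the observed indicator
ranges (e.g. hardness 1500 g at day 0, between the reported 659.85–2135.96 g
span; TA constant at 1.65 % across temperature, reflecting its reported
stability). They are visible in `kinetic_anchors()` and the profiles are
validated against the anchors and shape constraints, not against wet-lab
data.

## Maturity calibrations

`maturity_index()` linearly interpolates an indicator between its unripe and
fully-ripe values (0–100 %). The site-specific calibrations
`maturity_from_ssc()` (3.958 − 0.258·y) and `maturity_from_vc()`
(0.237·y − 0.434) are implemented exactly as calibrated even though their
outputs are not confined to [0, 100] and their printed units are internally
inconsistent; they are not forced to agree with each other (the claim that
both give identical results does not hold algebraically for arbitrary
inputs), and no rescaling is applied.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and leaves the global RNG
untouched (`withr::with_seed`); `run_pipeline()` derives per-stage seeds
from one master seed by a stable 31-bit polynomial hash of the stage name,
so reports reproduce byte-for-byte. The test suite exercises the full study
scale where it is cheap (40-point optimized designs, 32/8 surrogate splits,
12 × 50 SMPSO runs) and smaller sizes (e.g. 20-point designs, 10–15 MOEA
generations) where a property does not depend on scale; the methods above
state which guarantees are exact (interpolation, parameter recovery,
stratification) and which are statistical.

## Known limitations

* The Elman surrogate's sequence convention makes default predictions depend
  on row order; use `reset = "row"` when that matters.
* The coefficient-share sensitivity measure ignores factor-distribution
  variance; Sobol-style indices are out of scope.
* Maximizing all four responses treats "more TA" and "harder fruit" as
  unconditionally better; no preference weighting is applied.
* The packaged 40-run dataset carries large measurement scatter relative to
  any smooth surface in the three factors; surrogates trained on it
  interpolate faithfully but generalize poorly, as the metrics module makes
  visible.
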