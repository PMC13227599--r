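---
title: "Response-surface modeling and constrained dose nomination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface modeling and constrained dose nomination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmopt)
```

## The problem

Combination dosing studies test a small panel of agents over a grid of
dose combinations and read out a phenotype: normalized cell viability in
percent for in vitro work, or a per-animal immune endpoint in vivo — here
the hepatic macrophage infiltration ratio, the liver-area-normalized
macrophage density at 15 dpf divided by the same animal's density at a
baseline timepoint (9 or 12 dpf). The analysis question is not "which
tested condition looked best" but "which point of the *continuous* tested
dose box is predicted best, subject to explicit tolerability
constraints". `rsmopt` implements that workflow in five stages: ingest
and aggregate replicated tables, fit an interpretable quadratic response
surface per (endpoint, context), check model adequacy, nominate a dose
set by constrained optimization strictly inside the tested bounds, and
report.

## Replicate structure and aggregation

In vitro data arrive as per-well records: each dose condition measured in
triplicate wells (technical replicates) within each of three independent
runs on different days (biological replicates). Aggregation is a strict
two-stage mean: wells are averaged within (dose, context, biological
replicate), and those per-run means are averaged across runs. The per-run
means are retained, because the bootstrap resamples at the level the
model is fit on — the aggregated condition — not at the raw well level.
Unbalanced technical replicates are averaged as-is rather than weighted;
the two-stage mean is the declared estimand, not a mixed model, so a
run with fewer wells still contributes one mean. Viability values above
100% are retained: clipping at the vehicle level would censor the noise
distribution asymmetrically and bias the least-squares surface downward
near the control corner.

In vivo, each fish contributes one infiltration ratio; batches play the
role of biological replicates (`bio_rep = batch`, one "technical"
replicate per fish). Fish with zero baseline density have an undefined
ratio and are excluded with a logged count rather than imputed. Cohorts
mixing 9- and 12-dpf baselines are refused by default — a single fitted
model assumes a single baseline definition — with an explicit override
that carries the baseline label through.

## The quadratic surface and its parameterization

The surface is the full second-order polynomial: intercept, `d` linear
terms, `d` squared terms and `d(d-1)/2` pairwise interactions, in a
frozen term order so coefficient tables are comparable across endpoints
and contexts. Fitting is ordinary least squares on the condition means.
OLS is retained deliberately even where diagnostics flag deviations:
the coefficients are directly interpretable (sign and magnitude of main
effects and drug-drug interactions), and robustness is judged by
out-of-sample RMSE and bootstrap intervals rather than by swapping the
estimator.

Dose units are wildly heterogeneous — a fold-dilution near 1e-4 sits ten
orders of magnitude below a millimolar concentration — so raw polynomial
columns would be catastrophically ill-conditioned. Internally every axis
is divided by its tested upper bound before the quadratic expansion and
the fitted coefficients are back-transformed to original units by the
exact affine reparameterization of the quadratic form. This is purely a
conditioning device: in exact arithmetic the reported original-unit fit
is unchanged, and the tests verify fitted values agree to ~1e-8 between
parameterizations. A z-score standardization mode is provided as a
sensitivity analysis; it alters the coefficient scale (and is reported on
that scale) but leaves fitted values and R² identical. Whether a
logarithmic propolis axis would be preferable is genuinely open; linear
original units are the default and a log transform can be applied
upstream of the panel definition if wanted.

Degenerate inputs have defined behavior: a constant response yields an
intercept-only fit reported with R² = 1 and a degeneracy flag (SST = 0
makes the usual ratio undefined; the convention keeps reports
machine-readable); rank-deficient designs raise an error naming the
collinear terms; fewer conditions than terms raise an under-determined
error.

## Adequacy and robustness suite

The prespecified diagnostics per fitted surface are:

* **Shapiro–Wilk** on residuals (normality), via the standard library
  implementation, with explicit refusal of degenerate input;
* **Breusch–Pagan** in the studentized Lagrange-multiplier form
  `n·R²` of the auxiliary regression of squared residuals on the design,
  χ² with `p − 1` degrees of freedom;
* **Durbin–Watson** statistic `Σ(eₜ−eₜ₋₁)²/Σeₜ²` on run-ordered
  residuals, reported as a statistic only (no p-value);
* **VIFs** on the mean-centered, rescaled design, flagged at the
  prespecified VIF ≥ 3. Exact collinearity reports `Inf` per offending
  term instead of erroring, so the full pattern is visible. On compact
  grids the polynomial terms are intrinsically correlated and flags are
  expected; the cut is a screening aid, not a gate.
* **K-fold CV RMSE** (default K = 5 — unstated in the source protocol,
  chosen as the standard small-n default and configurable), with seeded
  shuffling and rank-deficient folds skipped under warning;
* **Nonparametric bootstrap** (default B = 1000 percentile intervals,
  likewise a standard default), case-resampling aggregated conditions;
  rank-deficient resamples are redrawn and counted, and more than 50%
  rank-deficiency aborts as unstable. When a nomination problem is
  attached, each replicate is re-nominated to give per-agent dose
  intervals.

Durbin–Watson, Breusch–Pagan and VIF are implemented from their defining
formulas (each a few lines) and are cross-validated in the test suite
against `lmtest::dwtest`, `lmtest::bptest` and `car::vif` as independent
references. Diagnostics only ever warn; nomination proceeds regardless,
with the report carrying the flags.

## Constrained nomination

The default ("hard constraint") problem minimizes the objective surface
(tumor viability, or the infiltration ratio in vivo) over the tested box
subject to each constraint surface staying at or above its floor θ. The
floor is a required, explicit analysis parameter: no universal value
exists, and examples in this package use 70% as a documented
illustration only. A weighted-sum mode
(`w₁·objective − Σ w_c·constraint`) is provided for exploration; because
a weighted combination of quadratic forms is again a quadratic form, it
reuses the same solver on combined coefficients.

The solver is multistart local optimization: a Latin-hypercube start set
(default 32 points, seeded and deterministic) plus all box corners and
the center, each polished by an augmented-Lagrangian loop whose inner
problems are box-bounded quasi-Newton solves with analytic gradients of
the quadratic forms. Two numerical details matter. First, the outer loop
must not stop at the first feasible iterate: a still-active multiplier
biases the iterate into the interior, so convergence additionally
requires the iterate to have settled. Second, the initial penalty weight
is scaled to the objective magnitude so the first inner solve already
feels the constraints. Indefinite quadratic surfaces genuinely have
multiple local optima on a box, hence the multistart; the brute-force
tensor-grid oracle (51 points per axis by default, exact arg-min among
feasible grid points) is the package's independent verifier, and the
test suite holds the optimizer to "never worse than the grid, and never
better than one grid cell's objective variation can explain" on random
instances.

Ties within 1e-6 of the best objective are broken toward the lowest
total normalized dose burden `Σ dose/upper`, then lexicographically by
agent order — dose-sparing and reproducible. If no start is feasible, a
smooth feasibility pre-scan minimizes the summed squared violations; a
genuinely infeasible problem returns the least-violating dose flagged
`feasible = FALSE`, never a silent answer. Predictions are not clipped
during optimization (clipping destroys smoothness); the report layer
clips displayed values at zero with a flag.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without any external
download, at the study's own replication structure.

* `generate_viability_table()` draws
  `value = quadratic(dose) + bio_offset + tech_noise` with Gaussian
  technical noise (default SD 5 viability points per well) and a shared
  Gaussian per-run offset (default SD 3 points) over 3 technical × 3
  biological replicates — plate-reader-like additive noise. Defaults are
  declared choices, not estimates from the motivating data, which state
  the replication layout but not noise magnitudes.
* `generate_fa_shift_pair()` models a context (e.g. fatty-acid
  enrichment) as a coefficient delta added to the base truth — the
  mechanism by which a context reshapes the surface and thereby moves
  the constrained optimum within the same box.
* `generate_fish_cohort()` draws lognormal baselines (default
  `meanlog = log 5`, `sdlog = 0.3`), multiplies by the true ratio
  surface, a per-fish lognormal noise (default σ = 0.15 on the log
  scale) and a shared per-batch lognormal factor (default σ = 0.1), for
  2–3 batches of ~10–20 fish per group. Lognormal noise keeps densities
  positive and right-skewed, as count-per-area data are; note it biases
  group mean ratios upward by `exp(σ²/2)` (~1%) relative to the surface,
  which the tests account for.

All generators are pure functions of (truth, seed), with named random
substreams per (context, replicate, batch): adding a replicate or
context never perturbs existing draws. What the generators do *not*
emulate: plate edge effects, spatially correlated well noise,
heteroscedastic viability noise, fish dropout correlated with dose, or
any real pharmacology. Passing tests therefore demonstrate correctness
of the estimators and the optimizer under the declared noise model, not
fidelity of any particular biological claim.

The default dose grid takes per-agent levels {0, ¼, ½, ¾, 1} of the
box span and prunes the 125-point factorial to a deterministic greedy
maximin subset of 27 points — space-filling, comfortably above the
10-term identifiability minimum, and matching the scale of a realistic
three-agent screen. The motivating study's exact grid is unpublished;
all functions accept arbitrary grids.

## Problem sizes used in verification

The automated checks run at sizes chosen to keep the full suite fast on
a laptop while leaving Monte-Carlo error well below the asserted
margins: 100 random optimizer/oracle instances at 51 grid points per
axis; 200 simulation seeds per noise level for recovery; 500 null
simulations each for the Breusch–Pagan and Shapiro–Wilk calibration
bands; bootstrap checks at B = 100–500 with coverage over 100 outer
seeds. The acceptance script reproduces the same computations from a
single root seed.

## Known limitations

* The quadratic surface is an interpolating summary of the tested box;
  it says nothing outside it, and the optimizer refuses to leave it.
* Fitting condition means discards within-condition variance from the
  point estimates; the `per_bio` fitting switch and the bootstrap are
  the provided sensitivity routes.
* The bootstrap treats the aggregated condition as the exchangeable
  unit; with only ~27 conditions, percentile intervals are approximate
  and can undercover slightly.
* Efficiency-corrected ΔΔCt assumes a single calibrated amplification
  factor (default 1.94 per cycle, ≈94%) shared by target and reference;
  gene-specific efficiencies would need the two-efficiency variant,
  which is out of scope here.
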