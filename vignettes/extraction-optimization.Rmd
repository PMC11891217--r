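---
title: "Methods: response-surface and neural-network surrogate optimization of a polysaccharide extraction process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface and neural-network surrogate optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pracopt)
```

## The problem

Microwave-assisted extraction of polysaccharides from *Radix Actinidiae
Chinensis* (PRAC) depends on four process factors: liquid-to-solid ratio
(mL/g), extraction temperature (°C), extraction time (min) and microwave
power (W). The package models the yield response (% of dry mass) measured
over a four-factor, three-level Box-Behnken design (BBD) — 24 edge runs
(each pair of factors at ±1, the rest at center) plus 5 center replicates,
29 runs in all — and compares two families of surrogate model fitted to
those runs:

1. a full second-order polynomial (response-surface methodology), and
2. small feedforward neural networks (4–h–1) trained by backpropagation,
   either from random initial weights (BP), from weights found by a
   real-coded genetic algorithm (GA-BP), or from weights found by a
   GA-seeded ant-colony optimizer (GA-ACO-BP).

Both families are then used for the same purpose: predicting yield and
locating the factor settings that maximize it over the experimental box.

## The quadratic model and its ANOVA

The response surface is the full 15-term quadratic

$$\hat y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j
  + \sum_i \beta_{ii} x_i^2 ,$$

fitted by ordinary least squares (`fit_quadratic()`). Coefficients can be
expressed in actual units or in the usual −1/0/+1 coding; the two
parameterizations are algebraically equivalent and `convert_units()` maps
between them exactly (the fitted values and every sum of squares are
invariant).

`quad_anova()` reports the conventions of DoE software such as
Design-Expert, which is what practitioners in this field compare against:

* **Per-term sums of squares** are partial (Type-III) — the increase in
  residual SS when that single column is dropped — computed **in coded
  units**. This matters: in actual units the linear and quadratic columns
  of the same factor are nearly collinear and partial SS become
  uninterpretable, while in coded units the linear and interaction columns
  of a BBD are mutually orthogonal. The pure-quadratic columns are *not*
  mutually orthogonal even when coded, so per-term SS need not add up to
  the model SS exactly; the additivity identities that do hold (and are
  tested) are SS(Model) + SS(Residual) = SS(Total) and
  SS(Residual) = SS(Lack of fit) + SS(Pure error).
* **Pure error** comes from within-replicate-group scatter (here, the five
  center replicates, df = 4); lack of fit is tested against it with
  F = MS(LoF)/MS(PE). With no replicated runs the table omits the
  partition and warns.
* **PRESS** uses the hat-matrix identity \(e_{(i)} = e_i/(1-h_{ii})\)
  rather than n refits (`press_stats()`); a leverage of 1 (a run its own
  sole predictor) raises an explicit error, and `quad_anova()` then
  reports the leave-one-out statistics as `NA`. Predicted R² is
  1 − PRESS/SS(Total).
* F-test p-values are one-sided upper-tail probabilities (stored exactly;
  printed as `<0.0001` below that floor), and CV% is
  100·√MS(Residual)/mean(y).

On the packaged 29-run experiment this machinery reproduces the study's
published ANOVA: R² = 0.8876, adjusted R² = 0.7752, model F = 7.90
(p = 0.0002), temperature F ≈ 76.2, pure-error SS 0.0525 on 4 df, CV% 7.76.

### Precision of the published inputs

The packaged run sheet carries yields printed to three decimals, whereas
the original summary statistics were evidently computed from unrounded
laboratory data. Recomputation from the printed yields therefore shifts a
few fourth-digit quantities: residual SS comes out 0.8121 (published
0.8119), predicted R² 0.3831 (0.3834), the temperature F 76.22 (76.26) and
the regression intercept −0.2647 (−0.2634). The acceptance tests assert
the published values at printed precision and deliberately leave these
few expectations failing rather than widen the tolerance; every other
published quantity — including all twelve model-comparison cells —
reproduces at printed precision.

A second transcription note: the published run-sheet column headers are
internally inconsistent (the level sets do not match the labels). The
package fixes the mapping by the level values — 60/80/100 °C is
temperature, 60/90/120 min is time, 300/400/500 W is power — which is the
unique assignment consistent with the published regression equation (its
value at the center point reproduces the published center prediction of
3.01) and with the reported optimum settings.

## Surface optimization

`optimize_surface()` maximizes the fitted quadratic over the experimental
box by multi-start bounded quasi-Newton search (L-BFGS-B from all 2^k
corners plus the center, analytic gradient, tolerance driven to machine
precision). A quadratic over a box frequently attains its maximum on the
boundary, which the corner starts cover; results are cross-checked against
a dense grid in the tests. Ties within 1e-8 are broken toward the
lexicographically smallest settings so the result is deterministic.

Both the refit and the published polynomial place the constrained maximum
at ratio 22, 100 °C, 120 min, 300 W (about 4.65–4.67% predicted yield).
The study instead reports 95 min; a desirability configuration that was
not published presumably pulled the time off its boundary, so the package
reports the box-constrained maximizer and does not attempt to reproduce
the unpublished setting.

## The neural-network surrogates

Design choices where the study is silent, made once and fixed:

* **Architecture**: one hidden layer of width h with tanh activation and a
  linear output — the standard small-sample regression surrogate. Hidden
  widths are screened over `round(sqrt(m+n)) + 1..10` (`hidden_candidates()`,
  giving 3–12 for a 4-input/1-output net) by training-set MSE
  (`select_hidden_size()`); analyses fix h = 4, the width the study
  selected, for comparability.
* **Scaling**: inputs and response are min-max scaled to [−1, 1], fitted
  on the training data only. "Thresholds" are the bias terms.
* **Training** (`train_bp()`): full-batch gradient descent on the MSE,
  stopping at 1000 epochs or a scaled training MSE below 1e-5 (the study's
  stated stopping rule). The best parameters seen are returned, so the
  final training error provably never exceeds the initial one and
  best-so-far histories are monotone. Weights initialize uniformly on
  (−0.5, 0.5) from a seeded generator; everything is bitwise reproducible
  under its seed.
* **Learning rate**: default 0.5. This was calibrated by convergence
  diagnostics on the scaled 29-run problem: rates of 0.05–0.2 fail to
  interpolate the design within the 1000-epoch budget, while 0.5 reaches
  training R² > 0.95 reliably. On smoother low-curvature targets plain
  gradient descent at 0.5 can settle into a small limit cycle, so generic
  uses should pass a smaller rate (the test-suite's linear-target check
  trains at 0.2). Momentum and adaptive optimizers are intentionally out
  of scope.

### Metaheuristic trainers

`ga_minimize()` is a real-coded GA — tournament selection of size 2,
arithmetic blend crossover, per-gene Gaussian mutation with σ = 10% of the
gene's bound width, one-elite elitism — run at the study's stated budget
(population 30, 50 generations, crossover 0.8, mutation 0.2). Elitism
makes the best-so-far trace provably monotone, which the tests exploit.
Non-finite objective values are penalized rather than fatal.

`aco_minimize()` adapts ant-colony search to continuous weights through
per-parameter candidate grids: each of the d parameters is discretized
into 40 equally spaced candidates, and a pheromone value is kept per
candidate. Each ant picks, per dimension, the argmax-pheromone candidate
with probability q0 = 0.2 and otherwise samples proportionally to
pheromone; after each iteration pheromone decays by the retention factor
0.9 and the iteration-best path receives a deposit sized so the grand
total stays at 1 (the study's "total amount of information"). The
retention reading of the 0.9 "volatilization coefficient" is a config
field, so the opposite convention (retention 0.1) can be run without code
changes. Ant count and iteration budget default to 30 and 50, mirroring
the GA budget.

The hybrids follow the study's narrative: **GA-BP** lets the GA search the
flattened 25-vector of weights and thresholds for minimal training MSE,
then refines its best vector by backpropagation. **GA-ACO-BP** runs three
stages: a small GA (population 10, 10 generations — it only shapes a
prior) searches one bias value per candidate-grid column, mapped through
`exp()` to a positive starting-pheromone profile and scored by short ACO
probes (10 ants, 5 iterations); the full ACO run then starts from the best
profile; backpropagation refines the colony's best weights. Stage
objectives are nonincreasing from colony search to refinement by
construction.

**Weight-search bounds** for the GA and the ACO grids default to [−1, 1]
in scaled space. Wider boxes (e.g. ±3) push proposals into the saturated
region of the tanh units where gradients vanish, and the refinement stage
then underperforms even random initialization; the narrow box keeps the
metaheuristics proposing points that gradient descent can actually
improve.

### What the training comparison does and does not show

The study's single printed training artifacts (a best fitness of 0.022, a
stabilization at iteration 23, the three model-specific optima) are
seed- and implementation-specific and are not reproduction targets. The
package instead asserts distributional properties over five seeds, with
the trainers run on all 29 runs — the same basis on which the published
model-comparison metrics were computed: the hybrid's median full-29-run
R² exceeds 0.90 and is at least plain BP's median, the GA solves a 5-d
sphere benchmark under the study budget, every best-so-far trace is
monotone, and the colony's error typically stabilizes before its
iteration budget. At this budget the honest summary is that all three
trainers converge well (R² ≈ 0.95–0.97) and the hybrids' advantage is
modest — on other seed sets BP and GA-ACO-BP are statistically tied —
so the property tested is "the hybrid machinery does not hurt and the
published ordering is plausible", not "ACO is necessary".

## The synthetic-experiment generator

`generate_bbd()` builds the deterministic edge-pair-plus-centers BBD for
3–7 factors. `simulate_response()` adds the data-generating assumption
behind the study's design: a true quadratic surface (by default the
published polynomial) plus i.i.d. Gaussian noise. The default noise scale
in `paper_like_spec()` is √0.058 ≈ 0.24% yield — the fitted model's
residual mean square, the only error information the study provides
(center-replicate scatter alone, MS 0.0131, would understate total
variation). An optional smooth perturbation
`amplitude · cos(πc_i)cos(πc_j)` (coded units) injects non-quadratic
signal that the quadratic basis cannot absorb, for exercising the
lack-of-fit test.

What passing simulation tests shows is calibration under these
assumptions — unbiased coefficient recovery, error scaling linearly with
noise, F-test power ≈ 1 at the study's noise level. Real extraction data
need not have Gaussian, homoscedastic, run-order-independent errors, and
a 29-run design cannot check those assumptions from within.

## Release kinetics and assay formulas

The formulation helpers are closed-form (yield, purity, encapsulation
efficiency, loading capacity, stability coefficient), with explicit
domain errors on zero denominators. `fit_release()` fits the first-order
release law M(t) = M∞(1 − e^(−kt)) by Levenberg–Marquardt, with starting
values M∞₀ = max(M) and k₀ from the earliest positive-time point's
log-slope, falling back to direct Nelder–Mead least squares on
log-parameters when the problem is too ill-conditioned for the gradient
solver (e.g. decreasing "release" data, which also trigger a quality
warning). The per-timepoint release measurements behind the study's two
fitted curves (93.47, 0.30 h⁻¹ at pH 2; 90.68, 0.24 h⁻¹ at pH 7.6) were
not published, so the fitter is validated by self-consistency — noiseless
samples of each curve return the generating parameters to 1e-6 — and by
Monte-Carlo robustness to 1%-scale noise, not by reproducing the published
R² values.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`withr::with_seed`,
leaving the session RNG untouched). The simulation studies use 100–200
replicates per condition and the training comparisons 5 seeds; these sizes
give Monte-Carlo standard errors comfortably below the margins being
asserted while keeping every analysis script and the full test suite
runnable in minutes on a single core. The numbered scripts under
`analysis/` regenerate every table in `results/` from scratch.
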