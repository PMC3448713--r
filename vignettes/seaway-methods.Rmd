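---
title: "Methods: presence-only distribution modelling of a shelf-constrained migrant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only distribution modelling of a shelf-constrained migrant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seaway)
```

## The problem

Green sturgeon and similar shelf-constrained migratory fishes are observed
almost exclusively where someone is listening: acoustic receivers record the
passage of tagged animals at fixed sites, and a handful of historical
capture reports fill the geographic gaps. There are no systematic absences.
`seaway` implements the full estimation chain for this setting: turning raw
detections into seasonal presence records, engineering covariates that
encode both oceanography and migratory behaviour, fitting a presence-only
maximum-entropy (MaxEnt-style) density-ratio model per season, and
subjecting each model to a standard evaluation battery. A seeded
synthetic-world generator supplies a coastal domain, ocean fields, a virtual
species and a telemetry array, so the chain is testable end to end without
any external data.

## The model

Let $f(x)$ be a vector of features (transformations of the covariates) and
let the background sample $\{x_i\}_{i=1}^N$ represent the covariate
distribution of the study area. The model for the presence density relative
to background is the Gibbs form

$$\pi_\lambda(x) \;=\; \frac{e^{\lambda^\top f(x)}}{Z_\lambda},
\qquad Z_\lambda=\sum_{i=1}^N e^{\lambda^\top f(x_i)},$$

fitted by maximizing the L1-penalized average presence log-likelihood

$$\ell(\lambda) \;=\; \frac{1}{m}\sum_{j=1}^m \lambda^\top f(x_j)
\;-\;\log\!\Big(\tfrac1N\sum_i e^{\lambda^\top f(x_i)}\Big)
\;-\;\sum_k \beta_k |\lambda_k|.$$

$\ell(0)=0$, so the fitted objective *is* the model "gain" over the uniform
null, which is what the jackknife reports. The logistic output used for all
maps and thresholds is
$p(x)=\tau e^{\eta'}/(1-\tau+\tau e^{\eta'})$ with
$\eta'=\lambda^\top f(x)-\log Z+H$, $H$ the entropy of the fitted
distribution over the background, and assumed prevalence $\tau = 0.5$
(configurable; it affects the scale of the map, not the ranking).

### Features and regularization

Features are linear, quadratic, pairwise-product, threshold, and
forward/reverse hinge transforms (knots at empirical quantiles;
`hinge_knots = 5` by default), all min–max scaled to $[0,1]$ on the combined
presence+background sample. The penalty is
$\beta_k = r \cdot b(\text{class}, m)\cdot \mathrm{sd}_k / \sqrt m$, with
$b$ the published per-class base constants interpolated in the presence
count $m$, and $r$ the regularization multiplier. Defaults follow the
source study: $r = 3$, convergence threshold $10^{-5}$, at most $10{,}000$
iterations, 8000 background points.

### Optimizer

The penalized likelihood is maximized by proximal-Newton ascent: each
iteration reweights the background under the current Gibbs density, builds
the gradient and the full weighted feature covariance (the Hessian of the
log-partition term), solves the L1-penalized quadratic model by inner
coordinate descent with soft-threshold updates, and backtracks the step
with a halving line search on the true objective. The objective is
therefore non-decreasing by construction (asserted in tests). A diagonal
Hessian is *not* sufficient here: linear and quadratic features of one
covariate are nearly collinear, and a diagonal-quadratic step stalls far
below the optimum while its per-iteration gain drops beneath any tolerance
— this failure mode motivated the full-covariance inner solve.

### Covariate engineering

* **Cost surface and attraction distances.** Bathymetry is reclassified to
  traversal costs 1 (10–200 m, the migration band), 5 (0–10 m) and 10
  (> 200 m). The distance to the spawning rivers and to the overwintering
  ground is the least accumulated cost over the 8-connected grid, with step
  cost equal to the mean of the two cells' costs times the step length
  (cell size, or cell size $\times\sqrt2$ diagonally). The overwintering
  attraction enters only the autumn and winter models; the spawning
  attraction only the spring and summer models. This season rule is
  enforced when sample matrices are built and asserted per emitted row.
* **Kriging.** Coarse ocean-model point output is interpolated to the 1-km
  grid by ordinary kriging with an isotropic spherical variogram fitted by
  weighted least squares to the binned empirical variogram. With a zero
  nugget the predictor interpolates exactly; a singular system falls back
  to inverse-distance weighting with a warning; negative weights are
  logged. Auto-fitting needs at least 3 non-collinear points; a
  user-supplied variogram allows 2 (the spec's closed-form two-point check).
* **Temporal matching.** Occurrence records inside the 2004–2006 window take
  their own season-and-year layers; records outside the window and all
  background points take the multi-year seasonal averages.

### Occurrence processing

Residence is accrued only between *consecutive detections at the same
hydrophone with no intervening detection elsewhere*; a single isolated
detection contributes nothing. Accrued time is attributed to the month
containing the interval's start (the simplest auditable rule; seasonal
aggregation blurs month detail anyway). A hydrophone yields at most one
presence record per season, when any single tag accumulated at least one
day there (a pooled-across-tags option exists). Winter spans the year
boundary and is labelled with the year of its December. Supplementary
reports snap to the nearest valid cell within 10 km and take the season of
their collection month.

## Evaluation battery

* **K-fold CV** ($K=10$): presences are partitioned; the background is
  shared across folds (the reference software's behaviour; the paper is
  silent).
* **ROC/AUC** against the background pseudo-absences, ties counted ½
  (identical to exhaustive pairwise comparison; asserted against that
  oracle).
* **Threshold**: the candidate score minimizing
  $|\text{sensitivity}-\text{specificity}|$, ties broken toward the lower
  threshold — false presences are tolerated in preference to false
  absences.
* **Binomial omission test**: one-sided
  $p = P(X \ge n_\text{test}-n_\text{omitted})$,
  $X\sim\mathrm{Bin}(n_\text{test}, a)$ with $a$ the share of background
  predicted present (the paper does not define $a$; this is the natural
  choice).
* **Permutation importance**: the covariate's column is permuted jointly
  across all rows (all features of that covariate see the permuted values,
  since importances are reported per covariate); AUC drops are floored at 0
  and normalized to 100.
* **Jackknife gain**: full, leave-one-out and single-covariate fits; gain
  is the fitted objective (null gain is exactly 0).
* **Median test**: counts above vs at-or-below the pooled median per group,
  chi-squared with $G-1$ df, no continuity correction by default (Yates
  optional for 2×2).

## The synthetic world: what it emulates, and what it does not

The generator is a *stated world*, not a tuning dial; its defaults were
fixed once, for the reasons below, before the acceptance suite was frozen.

* **Domain**: a shelf corridor bounded by the 200-m isobath along one grid
  edge (default 30 km wide, 1-km cells), latitude affine in the row index
  (36–52° N by default), with a one-cell fringe deeper than 200 m so the
  highest-avoidance cost class exists. Attractors default to mid-shelf
  cells near 40.6° N (spawning) and 51° N (overwintering).
* **Fields**: temperature falls from 9–10 °C in the south at
  0.11 °C per degree latitude, cools mildly with depth (0.003 °C/m), and in
  winter and spring drops sharply north of a configurable break; oxygen
  sits near saturation with a low-oxygen pocket at the southern extreme;
  currents are small-magnitude. Spatial noise is smoothed white noise
  (Gaussian blur, correlation length 10 cells) with standard deviation
  1.0 °C for temperature, split into a **persistent** component shared by
  all years of a season and a **transient** per-year component. The split
  matters: a three-year seasonal average divides independent noise by
  $\sqrt3$, and if the deterministic (latitudinal) part then dominates,
  temperature becomes collinear with the likewise-latitudinal attraction
  distances and *no* method could attribute the signal — violating the
  generator's own recoverability contract. Persistent mesoscale structure
  (standing eddies, topographic steering) is also the physically realistic
  choice.
* **Telemetry**: hydrophones are evenly spaced alongshore with a *random*
  cross-shore position (a constant-isobath array would make depth a perfect
  fingerprint of the sites and let the model memorize them). Each tag
  occupies one site per month with probability proportional to true
  suitability and emits Poisson-timed detections (2/day by default).
  Tags move independently between site-months: the pipeline consumes
  season-aggregated presences, not tracks.
* **Not emulated**: hydrodynamics, projections/cartography, observer-bias
  structure, tag loss, detection-range variation. A green test on this
  world certifies the estimation chain (signal in → signal recovered); it
  does not certify oceanographic realism, and the inflated AUCs that the
  real study attributes to residual spatial autocorrelation reproduce here
  for the same reason (repeated sites, correlated fields).

## Numerical choices and degenerate inputs

Single-feature updates shrink exactly to zero under the soft threshold;
fits that exhaust `max_iter` are returned flagged, not rejected. Degenerate
score vectors yield AUC 0.5 and a threshold equal to the common value, with
warnings. An all-equal sample makes the median test return $p=1$ with a
warning. Unreachable cells in the cost distance stay infinite and are
counted in a warning. Background draws are uniform without replacement and
error when the request exceeds the valid-cell count (the pipeline caps the
request with a message instead). All randomness descends from one integer
seed through a documented splitting rule (polynomial hash of the stream
name modulo $2^{31}-1$), so every artifact is a pure function of its
configuration and seed.

## Known limitations

Spatially blocked cross-validation, bias grids / target-group background,
AICc-based model selection and fade-by-clamping are deliberately out of
scope. The cost-unit scale of the attraction covariates is arbitrary on a
synthetic domain (the real study's "about 5000 cost units between spawning
and overwintering grounds" depends on real bathymetry). Monthly layers are
represented as season-by-year means; a finer monthly mode exists only
behind the matching rule's year lookup.

## A small worked run

```{r, eval = FALSE}
library(seaway)
res <- run_pipeline(seed = 7,
                    config = domain_config(n_rows = 200, n_cols = 60, seed = 7),
                    n_background = 4000, K = 10)
res$table          # Table-1-shaped report: statistics x seasons
res$thresholds     # per-season equal sensitivity-specificity thresholds
```

The README shows the output this prints; every number in it was produced by
the code above, and nothing in this vignette states an empirical result
that the tests or the acceptance script do not themselves compute.
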