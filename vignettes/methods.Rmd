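---
title: "Model, inference and design choices in spdeSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, inference and design choices in spdeSDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdeSDM)
```

## The model

spdeSDM fits presence–absence species distribution models of the
hierarchical Bayesian GAM family used for fisheries observer data. For
fishing set $i$ at location $s_i$,

$$y_i \sim \mathrm{Bernoulli}(\pi_i), \qquad
\mathrm{logit}(\pi_i) = \alpha_0 + X_i\beta + \sum_k f_k(x_{ki}) + w(s_i).$$

* $\alpha_0$ and $\beta$ are fixed effects. The three-level purse-seine
  set-type factor (Dolphin, FloatingObject, School) can enter either with
  treatment contrasts (`settype_encoding = "factor"`) or as three indicator
  columns with no reference level (`"dummy"`). In the dummy encoding the
  level effects are identified relative to the intercept only through their
  common vague prior, which is why their posterior SDs are very large while
  pairwise differences remain well determined; this mirrors how such models
  are usually reported for this data type. All fixed effects get independent
  $N(0, 100)$ priors.
* $f_k$ are nonlinear covariate effects with second-order random-walk (RW2)
  priors over `n_bins` (default 20) equal-quantile bins of each covariate;
  RW2 penalizes second differences of adjacent bin levels and is the
  discrete analogue of a cubic smoothing spline. Month uses a cyclic RW2
  over its 12 natural levels so December joins January. Each smooth carries
  one sum-to-zero constraint; its level belongs to the intercept.
* $w(s)$ is a zero-mean Matérn ($\nu = 1$) Gaussian field represented by
  the SPDE finite-element approximation on a triangulated mesh:
  $Q(\kappa,\tau) = \tau^2(\kappa^4 C + 2\kappa^2 G + G C^{-1} G)$ with
  lumped mass matrix $C$ and stiffness matrix $G$. The correlation is
  $\rho(d) = \kappa d\, K_1(\kappa d)$, the range (correlation
  $\approx 0.13$) is $\sqrt{8}/\kappa$, and the marginal variance is
  $1/(4\pi\kappa^2\tau^2)$. Smoothness is fixed at $\alpha = 2$
  ($\nu = 1$), the standard two-dimensional default.

### RW2 scaling and hyperpriors

Each RW2 penalty is rescaled so the geometric mean of the marginal
variances of its pseudo-inverse equals one. This makes the log-precision
hyperparameter $\log\tau_k$ comparable across terms with different numbers
of bins; each gets a weakly informative $N(0, 2^2)$ hyperprior. The field
is parameterized by $(\log \text{range}, \log \sigma_w)$ with priors
$N(\log(\text{domain diameter}/5), 1)$ and $N(0, 1.5^2)$. The $N(0,100)$
prior is applied to fixed effects only, not to hyperparameters.

## Inference: a nested Laplace approximation

Inference is empirical-Bayes Laplace, a deliberately simplified member of
the integrated-nested-Laplace family:

1. **Inner step.** For fixed hyperparameters $\theta$, a safeguarded Newton
   iteration (step halving on the penalized log-likelihood, convergence at
   max score $< 10^{-6}$, cap 50 iterations) finds the mode $x^*$ of
   $p(x \mid y, \theta)$ and the Gaussian approximation with precision
   $Q_{\text{prior}}(\theta) + A^\top W(x^*) A$, where
   $W = \mathrm{diag}(\pi(1-\pi))$ are the Bernoulli-logit curvatures.
   Sum-to-zero constraints are imposed by conditioning (kriging
   correction) on the mean, covariance and every posterior draw.
2. **Skewness correction.** The Bernoulli log-likelihood is skewed in
   $\eta$, so the posterior mean sits off the mode. The reported mean adds
   the third-order correction
   $\tfrac12\,\Sigma A^\top\!\big(\ell'''(\eta^*)\odot
   \mathrm{var}(\eta)\big)$ with
   $\ell'''(\eta) = -\pi(1-\pi)(1-2\pi)$ — the moment that
   simplified-Laplace-style marginals correct. It is exactly zero for the
   Gaussian family, so the Gaussian-likelihood path remains the closed-form
   conjugate posterior. The test suite checks the corrected mean against a
   long random-walk Metropolis chain and a deterministic three-dimensional
   quadrature.
3. **Outer step.** The Laplace evidence
   $\log p(y\mid\theta) \approx \ell(x^*) - \tfrac12 x^{*\top} Q_p x^* +
   \tfrac12\log|Q_p|_{+} - \tfrac12\log|Q_{\text{post}}|$
   (with generalized, rank-aware log-determinants for the intrinsic RW2
   blocks) plus the hyperprior is maximized by derivative-free Nelder–Mead
   from a seeded multi-start (`optimize()` in one dimension; an optional
   coarse-grid mode for replicated simulation studies). A small axial grid
   around the optimum ($\pm 1.5$ curvature SDs per dimension) then yields a
   weighted mixture of Gaussian approximations; marginal summaries (mean,
   SD, 0.025/0.5/0.975 quantiles) aggregate over that mixture with
   per-component Gaussian quantiles.

The $O(1)$ constraint-correction term is omitted from the evidence; it is
nearly constant in $\theta$ and immaterial at the tolerances the recovery
tests use (log-precision within $\pm 0.7$, range within a factor two).
If a posterior Cholesky fails, a single $10^{-10}$ ridge is added before
raising an error.

## Mesh construction

No triangulation library is assumed: the mesh is a Bowyer–Watson Delaunay
triangulation built from the merged observation locations (points closer
than `cutoff`, default `inner_max_edge/5`, are merged keeping the first
occurrence) plus structured fill points — a fine grid over the inner zone
at the `inner_max_edge` target and a coarse grid over an outer ring of
width `extension_width` (default 20% of the domain diameter, or the
prior range estimate) at the `outer_max_edge` target. This produces the
conventional fine-to-coarse transition that pushes boundary artifacts away
from the data. The inner zone is the bounding box of the data plus a small
margin — a convex superset of a buffered convex hull, chosen for robust
point location; cells outside it are masked at prediction time rather than
extrapolated. Grid fill points carry a deterministic sub-cell jitter to
break the cocircular degeneracies of regular grids. Longitudes are scaled
by $\cos(\text{mean latitude})$ before meshing so Euclidean distance in
the meshed plane approximates isotropic distance in degrees; at basin
scale this equirectangular treatment is adequate and no map projection is
required.

## Model selection and validation

* **DIC** uses the latent-$\eta$ plug-in: $\hat D$ is the deviance at the
  posterior mean of $\eta$, $\bar D$ a Monte-Carlo mean over posterior
  draws, $p_D = \bar D - \hat D$, $\mathrm{DIC} = \hat D + 2 p_D$.
* **CPO** uses the harmonic identity
  $\mathrm{CPO}_i = [\mathbb E_{\text{post}}\, 1/p(y_i\mid\eta_i)]^{-1}$
  with 2000 draws by default; $\mathrm{LCPO}$ is the *negative mean* log
  CPO (a sum variant is exposed behind a flag, since sum-based scores are
  also in circulation). Degenerate estimates are flagged, and a failure
  fraction above 1% warns.
* **Candidate grid.** `enumerate_candidates()` crosses
  {linear, RW2} × {spatial, non-spatial} × {factor, dummy} and appends
  intercept-only and drop-one covariate reductions. `forward_stepwise()`
  adds covariates greedily and stops when the best DIC drop falls below 2
  (the conventional "substantial" threshold; the selection rule had to be
  fixed somewhere and this is documented as ours).
* **Cross-validation** is stratified 5-fold (80/20) repeated five times
  with derived seeds. Besides the conventional 0.5 threshold, sensitivity,
  specificity and kappa are also reported at the training-prevalence
  threshold: at 0.5% prevalence a 0.5 cutoff classifies everything absent,
  so the prevalence threshold is the informative one.

## Prediction surfaces

`predict_surface()` samples the latent posterior (default 1000 draws),
pushes each draw through the inverse logit on a regular cell-center grid,
and reports cellwise mean, SD and empirical 2.5%/97.5% quantiles on the
probability scale — empirical rather than Gaussian-z because the inverse
logit is nonlinear. An alternative `"gaussian"` route (monotone-transform
quantiles, Gauss–Hermite means on the Gaussian $\eta$ marginals) is
exposed and must agree within Monte-Carlo error; the missing-response view
of prediction is equivalent here because prediction cells carry no
likelihood contribution. Out-of-range covariate values at prediction time
are clamped to the outermost training bin (RW2 levels are undefined
outside training support) with a clamp counter in the output. A grid cell
has no fishing mode of its own, so maps are produced for a chosen set-type
scenario (and month scenario); neither choice is claimed to be canonical.
Rasters are written as ESRI ASCII grids (the plain-text raster format);
no GeoTIFF writer is provided.

## The synthetic-data generator

The generator emulates the structure of a confidential tropical
purse-seine observer dataset so that every stage is testable end to end:

* clustered effort locations from a Thomas-style process (seeded parents,
  Gaussian offspring, default 15 clusters with 2° spread) in an eastern
  tropical Pacific style box (default 120°W–80°W, 15°S–25°N);
* per-set covariates sampled from smooth gridded fields confined to each
  variable's documented (min, max) envelope — e.g. SST in
  [16.69, 29.63] °C, chlorophyll in [0.024, 1.83] mg m⁻³;
* built-in true response curves: a chlorophyll dome peaking between 0.1
  and 0.2 mg m⁻³, an oxygen window peaking between 210 and 220 mg/l,
  monotone-decreasing SSH, a low-to-medium nitrate preference, and a
  seasonal cosine peaking in boreal winter;
* a three-level set-type factor with configurable sampling fractions
  (uniform by default — the per-type composition of the real data is not
  public) and effects that are lowest for FloatingObject sets;
* prevalence near 0.5% by default, matching the roughly 1 300 presences in
  260 000 sets of the observer-data regime; the intercept is calibrated by
  bisection whenever a prevalence target is set;
* a Matérn ($\nu=1$) residual field (default range 8°, SD 1), drawn by
  dense Cholesky of the closed-form covariance for small n and through the
  SPDE precision for large n — both paths are exposed and their
  correlograms are compared in the tests.

A `TruthRecord` (intercept, set-type effects, field values, true linear
predictor and probabilities) is returned and written as a JSON sidecar so
recovery tests never re-derive the truth. What the generator does **not**
emulate: real oceanographic fields and their seasonal dynamics, vessel
behaviour and effort targeting, multi-year trends, or observation error in
species identification. Passing tests therefore demonstrate internal
correctness of the statistical machinery under known truth, not fidelity
to any particular ocean.

## Collinearity screening

`screen_covariates()` applies two deterministic stages: while any pair has
$|r| > 0.6$, the member of the worst pair with the larger mean absolute
correlation to the remaining variables is dropped (alphabetical
tie-break); then generalized variance-inflation factors — determinant
ratios of the predictor correlation matrix, reported alongside the
df-corrected $\mathrm{GVIF}^{1/(2\,\mathrm{df})}$ — are recomputed and the
largest is dropped until all are ≤ 5. Which member of a correlated pair to
keep is not prescribed anywhere authoritative, so the rule above is this
package's own documented, order-invariant choice. The retained set feeds
the model spec but remains user-overridable configuration.

## Problem sizes and numerical choices in the test suite

The suite exercises the machinery at sizes chosen to make each property
sharply testable: oracle comparisons at $n = 200$ (Metropolis, 200 000
iterations) and $n = 60$ (leave-one-out CPO refits); coverage at 100
replicates of $n = 2000$; spatial-range recovery at $n = 3000$; DIC
model-comparison studies at 20 replicates of $n = 1200$–1500 with the
coarse-grid hyperparameter mode; and an end-to-end smoke run at
$n = 2000$ sets. Replicated studies fix the simulation and fitting seeds;
every random quantity in the package takes an explicit seed argument, and
the pipeline derives per-stage seeds from one master seed.

## Known limitations

* Marginals are Gaussian mixtures over a small hyperparameter grid, not
  full simplified-Laplace marginals; very skewed latent marginals (tiny
  counts per bin) will be summarized optimistically.
* The mesh inner zone is a bounding box, not a shaped hull; for strongly
  non-convex study areas (coastlines) some inner cells lie far from data.
* The equirectangular plane distorts distances at high latitudes; the
  generator's default box is tropical, where the distortion is small.
* No temporal random effects: month is the only seasonal term, matching
  the model family this package targets.
* LCPO is reported as a negative mean log score; comparisons with
  sum-based reports require the exposed sum variant.
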