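# spdeSDM

Bayesian spatial species distribution modelling for presence–absence
bycatch data, in the hierarchical GAM style used for fisheries observer
records: a Bernoulli-logit latent Gaussian model with second-order
random-walk (RW2) covariate smooths, a cyclic seasonal effect, set-type
fixed effects, and a Matérn spatial random field represented through the
SPDE finite-element approximation. Everything — the triangulation, the
sparse Matérn precision, the nested Laplace inference, DIC/CPO model
selection, stratified cross-validation and posterior prediction mapping —
is implemented in this package on top of `Matrix` sparse algebra.

## Who this is for

Analysts of very-low-prevalence presence–absence data (bycatch observer
programs, rare-species surveys) who need spatially explicit occurrence
probabilities **with uncertainty** — posterior mean, SD and credible-bound
maps — and who want the model-comparison workflow (linear vs smooth
effects, with vs without a spatial field, factor vs dummy encodings)
reproducible end to end. Because such datasets are usually confidential,
the package ships a synthetic observer-data generator with known ground
truth, so every stage is testable without access to real records.

## The model

For fishing set *i* at location *s<sub>i</sub>*:

```
y_i ~ Bernoulli(pi_i)
logit(pi_i) = alpha_0 + X_i beta + sum_k f_k(x_ki) + w(s_i)
```

* `X_i beta` — intercept, set-type effects (Dolphin / FloatingObject /
  School; treatment contrasts or all-indicator "dummy" encoding) and any
  linear covariates, each with a vague N(0, 100) prior;
* `f_k` — RW2 smooths over equal-quantile bins of each environmental
  covariate (chlorophyll, oxygen, nitrate, SSH/SST, ...), cyclic RW2 for
  month, each with a sum-to-zero constraint;
* `w(s)` — zero-mean Matérn (ν = 1) Gaussian field, correlation
  ρ(d) = κd·K₁(κd), range √8/κ, discretized by finite elements on a
  two-zone Delaunay mesh into a sparse GMRF precision
  Q = τ²(κ⁴C + 2κ²G + GC⁻¹G).

Inference is an empirical-Bayes nested Laplace approximation: Newton
optimization of the latent field at fixed hyperparameters, a third-order
skewness correction to the posterior mean, derivative-free maximization of
the Laplace evidence over hyperparameters, and a small grid mixture for
marginal summaries. See `vignettes/methods.Rmd` for the full account.

## Worked example

Simulate an observer-style dataset with a known spatial field, fit the
full model, and map the posterior occurrence probability:

```r
library(spdeSDM)

cfg  <- sim_config(n_sets = 3000, covariates = c("Chl", "O2", "SSH"),
                   prevalence_target = 0.02,
                   field_params = list(range_r = 8, sigma_w = 1), seed = 7)
grids <- generate_covariate_fields(cfg)
sim   <- simulate_observations(cfg, grids)      # obs + ground truth

mesh <- build_mesh(cbind(sim$obs$lon, sim$obs$lat),
                   inner_max_edge = 5, outer_max_edge = 12)
spec <- model_spec(covariates = c(Chl = "rw2", O2 = "rw2", SSH = "linear",
                                  month = "rw2_cyclic"),
                   include_spatial = TRUE, settype_encoding = "dummy",
                   n_bins = 12)
fit  <- fit_sdm(sim$obs, spec, mesh,
                control = list(maxit = 120, n_starts = 1, grid_mixture = FALSE))

nt <- length(fit$theta_hat)
exp(fit$theta_hat[nt - 1])   # estimated Matern range (deg)
exp(fit$theta_hat[nt])       # estimated field SD

dic(fit, 500, seed = 2)$DIC
cpo_lcpo(fit, 500, seed = 3)$lcpo

g <- prediction_grid(list(lon = c(-120, -80), lat = c(-15, 25)), 1)
s <- predict_surface(fit, g, grids, n_samples = 500, seed = 4)
write_surface(s, "surfaces")   # mean/sd/q025/q975/field_mean/field_sd .asc
```

Output from this exact run:

```
estimated spatial range 12.3 deg (truth 8), sigma_w 1.18 (truth 1)
DIC 531.7 (pD 25.7), LCPO 0.0889
mean layer range: 0.000588126 0.3941902
```

The estimated range lies within a factor two of the simulation truth and
the field SD within 20% — the accuracy regime the recovery tests assert.
The six raster layers are ESRI ASCII grids; probability layers satisfy
q025 ≤ mean ≤ q975 cellwise, and cells outside the inner mesh zone are
NODATA. `run_pipeline()` drives the same stages (simulate → screen →
mesh → fit → select → validate → predict) from a single config list with
one master seed and writes a hashed artifact manifest.

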