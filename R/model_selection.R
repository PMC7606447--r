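# DIC / CPO model-selection machinery, candidate-grid enumeration
# (linear vs smooth, with/without the spatial field, set-type factor vs
# dummy) and forward stepwise search.

#' Bernoulli deviance
#'
#' D = -2 sum[y log pi + (1 - y) log(1 - pi)], pi = logit^-1(eta), with pi
#' clipped to [1e-12, 1 - 1e-12] to keep the sum finite.
#'
#' @param y 0/1 response vector.
#' @param eta linear predictor, same length.
#' @return deviance (scalar).
#' @export
bernoulli_deviance <- function(y, eta) {
  if (length(y) != length(eta)) stop_sdm("length mismatch",
                                         class = "sdm_data_error")
  p <- clip_prob(plogis(eta))
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' DIC from posterior linear-predictor samples
#'
#' Dhat is the deviance at the posterior-mean eta (latent plug-in), Dbar the
#' Monte-Carlo mean deviance over samples, pD = Dbar - Dhat, and
#' DIC = Dhat + 2 pD.
#'
#' @param y response.
#' @param eta_mean posterior mean of eta.
#' @param eta_samples n x S matrix of eta draws.
#' @return list: DIC, pD, Dbar, Dhat, mc_se (Monte-Carlo SE of Dbar).
#' @export
dic_samples <- function(y, eta_mean, eta_samples) {
  Dhat <- bernoulli_deviance(y, eta_mean)
  devs <- apply(eta_samples, 2, function(e) bernoulli_deviance(y, e))
  Dbar <- mean(devs)
  pD <- Dbar - Dhat
  list(DIC = Dhat + 2 * pD, pD = pD, Dbar = Dbar, Dhat = Dhat,
       mc_se = sd(devs) / sqrt(length(devs)))
}

#' DIC of a fitted model
#'
#' @param fit an `sdm_fit`.
#' @param n_samples posterior draws (a value below 100 records a warning).
#' @param seed integer seed.
#' @export
dic <- function(fit, n_samples = 1000, seed = 1L) {
  if (n_samples < 100) warning("DIC with fewer than 100 samples is noisy")
  eta_mean <- Reduce(`+`, lapply(seq_along(fit$components), function(i)
    fit$weights[i] * fit$components[[i]]$fit$eta_mean))
  dic_samples(fit$assembly$y, eta_mean, sample_eta(fit, n_samples, seed))
}

#' Conditional predictive ordinates from eta samples
#'
#' Harmonic identity: CPO_i = [E_post(1 / p(y_i | eta_i))]^-1 estimated over
#' posterior draws; LCPO = -mean_i log CPO_i (the negative mean log score; a
#' sum variant is available via `summary = "sum"`).
#'
#' @param y response.
#' @param eta_samples n x S matrix of eta draws.
#' @param summary "mean" (default) or "sum" for the LCPO aggregation.
#' @return list: cpo (vector), lcpo, failed (indices where the estimate
#'   degenerated to 0).
#' @export
cpo_samples <- function(y, eta_samples, summary = c("mean", "sum")) {
  summary <- match.arg(summary)
  p <- clip_prob(plogis(eta_samples))
  lik <- p * y + (1 - p) * (1 - y)          # p(y_i | eta_i) rowwise
  inv_mean <- rowMeans(1 / lik)
  cpo <- 1 / inv_mean
  failed <- which(!is.finite(cpo) | cpo <= 0)
  cpo[failed] <- .Machine$double.xmin
  lcpo <- if (summary == "mean") -mean(log(cpo)) else -sum(log(cpo))
  list(cpo = cpo, lcpo = lcpo, failed = failed)
}

#' CPO / LCPO of a fitted model
#' @param fit an `sdm_fit`.
#' @param n_samples,seed posterior sampling controls.
#' @param summary "mean" or "sum" LCPO aggregation.
#' @export
cpo_lcpo <- function(fit, n_samples = 2000, seed = 1L,
                     summary = c("mean", "sum")) {
  out <- cpo_samples(fit$assembly$y, sample_eta(fit, n_samples, seed), summary)
  if (length(out$failed) > 0.01 * length(out$cpo))
    warning("more than 1% of CPO estimates degenerated")
  out
}

#' Enumerate the candidate-model option grid
#'
#' The crossing of {linear, rw2} x {spatial, no spatial} x {set-type factor,
#' dummy}, plus stepwise-style reduced covariate sets (intercept-only and
#' drop-one variants of the full smooth model), labelled option 1..N.
#'
#' @param base_spec the full [model_spec()] whose covariates define the pool.
#' @return named list of `model_spec` objects (>= 10 options).
#' @export
enumerate_candidates <- function(base_spec) {
  covs <- base_spec$covariates
  opts <- list()
  for (form in c("linear", "rw2")) {
    cv <- covs
    if (length(cv)) {
      cv[] <- ifelse(names(cv) == "month",
                     ifelse(form == "rw2", "rw2_cyclic", "linear"), form)
    }
    for (spatial in c(TRUE, FALSE))
      for (enc in c("factor", "dummy"))
        opts[[length(opts) + 1]] <- model_spec(
          covariates = cv, include_spatial = spatial,
          include_settype = base_spec$include_settype,
          settype_encoding = enc, n_bins = base_spec$n_bins,
          fixed_prior_variance = base_spec$fixed_prior_variance)
  }
  # stepwise-style reductions of the full smooth + spatial + dummy option
  opts[[length(opts) + 1]] <- model_spec(
    covariates = character(0), include_spatial = base_spec$include_spatial,
    include_settype = base_spec$include_settype, settype_encoding = "dummy",
    n_bins = base_spec$n_bins,
    fixed_prior_variance = base_spec$fixed_prior_variance)
  if (length(covs) > 1) {
    for (v in names(covs))
      opts[[length(opts) + 1]] <- model_spec(
        covariates = covs[setdiff(names(covs), v)],
        include_spatial = base_spec$include_spatial,
        include_settype = base_spec$include_settype,
        settype_encoding = "dummy", n_bins = base_spec$n_bins,
        fixed_prior_variance = base_spec$fixed_prior_variance)
  }
  names(opts) <- paste0("option_", seq_along(opts))
  opts
}

#' Score a list of candidate models by DIC and LCPO
#'
#' Fits every candidate on the same data and tabulates DIC, pD and LCPO;
#' the best option minimizes DIC (ties broken by smaller pD).
#'
#' @param obs observation data.frame.
#' @param candidates named list of `model_spec`s.
#' @param mesh mesh for the spatial candidates.
#' @param n_samples,seed DIC/CPO sampling controls.
#' @param control fitting control (see [optimize_hyperparameters()]).
#' @return list of class `selection_table`: `table` (data.frame),
#'   `best_option`, `fits`.
#' @export
score_candidates <- function(obs, candidates, mesh = NULL, n_samples = 500,
                             seed = 1L, control = list()) {
  rows <- list(); fits <- list()
  for (id in names(candidates)) {
    sp <- candidates[[id]]
    f <- tryCatch(fit_sdm(obs, sp, mesh = if (sp$include_spatial) mesh,
                          control = control),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[id]] <- data.frame(option_id = id, description = spec_label(sp),
                               DIC = NA, pD = NA, LCPO = NA,
                               note = conditionMessage(f))
      next
    }
    d <- dic(f, n_samples, derive_seed(seed, paste0("dic_", id)))
    cp <- cpo_lcpo(f, n_samples, derive_seed(seed, paste0("cpo_", id)))
    rows[[id]] <- data.frame(option_id = id, description = spec_label(sp),
                             DIC = d$DIC, pD = d$pD, LCPO = cp$lcpo, note = "")
    fits[[id]] <- f
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$DIC)
  best <- tab$option_id[ok][order(tab$DIC[ok], tab$pD[ok])][1]
  structure(list(table = tab, best_option = best, fits = fits),
            class = "selection_table")
}

#' @exportS3Method base::print
print.selection_table <- function(x, ...) {
  print(x$table[, c("option_id", "description", "DIC", "pD", "LCPO")],
        row.names = FALSE)
  cat("best:", x$best_option, "\n")
  invisible(x)
}

#' Forward stepwise covariate selection by DIC
#'
#' Starts from the intercept(+set-type, +spatial per `base_spec`) model and
#' greedily adds the covariate with the largest DIC drop, stopping when the
#' best drop is below `min_improvement` (2 DIC units, the conventional
#' "substantial" threshold). Candidates whose fit fails are skipped with a
#' logged reason.
#'
#' @param obs observation data.frame.
#' @param covariate_pool named character vector (name -> form) of candidates.
#' @param base_spec template [model_spec()] (its covariates are ignored).
#' @param mesh mesh if the base includes the field.
#' @param n_samples,seed DIC sampling controls.
#' @param min_improvement stopping threshold in DIC units.
#' @param control fitting control.
#' @return list: `selected` (named forms), `trajectory` (data.frame of step,
#'   candidate, DIC), `final_fit`, `skipped`.
#' @export
forward_stepwise <- function(obs, covariate_pool, base_spec = model_spec(),
                             mesh = NULL, n_samples = 500, seed = 1L,
                             min_improvement = 2, control = list()) {
  if (!length(covariate_pool)) stop_sdm("empty covariate pool",
                                        class = "sdm_config_error")
  mk <- function(cv) model_spec(covariates = cv,
                                include_spatial = base_spec$include_spatial,
                                include_settype = base_spec$include_settype,
                                settype_encoding = base_spec$settype_encoding,
                                n_bins = base_spec$n_bins,
                                fixed_prior_variance = base_spec$fixed_prior_variance)
  fit_dic <- function(cv, tag) {
    f <- fit_sdm(obs, mk(cv), mesh = if (base_spec$include_spatial) mesh,
                 control = control)
    list(fit = f, dic = dic(f, n_samples, derive_seed(seed, tag))$DIC)
  }
  selected <- covariate_pool[0]
  cur <- fit_dic(selected, "step0")
  traj <- data.frame(step = 0L, added = "(none)", DIC = cur$dic)
  skipped <- character(0)
  pool <- covariate_pool
  step <- 0L
  while (length(pool)) {
    step <- step + 1L
    cand <- lapply(names(pool), function(v) {
      tryCatch(fit_dic(c(selected, pool[v]), paste0("s", step, "_", v)),
               error = function(e) e)
    })
    names(cand) <- names(pool)
    err <- vapply(cand, inherits, logical(1), "error")
    skipped <- c(skipped, names(cand)[err])
    cand <- cand[!err]
    if (!length(cand)) break
    dics <- vapply(cand, `[[`, numeric(1), "dic")
    best <- names(dics)[which.min(dics)]
    if (cur$dic - dics[best] < min_improvement) break
    selected <- c(selected, pool[best])
    cur <- cand[[best]]
    traj <- rbind(traj, data.frame(step = step, added = best, DIC = cur$dic))
    pool <- pool[setdiff(names(pool), best)]
  }
  list(selected = selected, trajectory = traj, final_fit = cur$fit,
       skipped = skipped)
}
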