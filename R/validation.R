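# k-fold cross-validation and the presence-absence metric suite.

#' k-fold split
#'
#' Disjoint folds with sizes differing by at most one; stratified mode keeps
#' the presence count per fold balanced within one, which matters at the
#' sub-percent prevalences typical of observer bycatch data.
#'
#' @param n number of rows (or, with `y`, length of the response).
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratified balance presences across folds (requires `y`).
#' @param y 0/1 response for stratification.
#' @return integer fold assignment of length n.
#' @export
kfold_split <- function(n, k = 5, seed = 1L, stratified = FALSE, y = NULL) {
  if (n < k) stop_sdm("n < k", class = "sdm_config_error")
  withr::local_seed(seed)
  if (stratified) {
    if (is.null(y)) stop_sdm("stratified split needs y", class = "sdm_config_error")
    if (sum(y == 1) < k)
      stop_sdm("fewer presences than folds; use stratified = FALSE",
               class = "sdm_data_error")
    fold <- integer(n)
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  } else {
    sample(rep_len(seq_len(k), n))
  }
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random presence scores above a random absence, ties
#' counted one half.
#'
#' @param y 0/1 response (both classes must be present).
#' @param scores predicted scores or probabilities.
#' @return AUC in [0, 1].
#' @export
auc <- function(y, scores) {
  if (length(unique(y)) < 2)
    stop_sdm("AUC undefined with a single class", class = "sdm_data_error")
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Predictions are positive when score >= threshold. Sensitivity is
#' TP/(TP+FN), specificity TN/(TN+FP), and kappa the chance-corrected
#' agreement (p_o - p_e)/(1 - p_e) with p_e from the table marginals. Empty
#' classes yield NA for the affected metric rather than 0.
#'
#' @param y 0/1 response.
#' @param scores predicted probabilities.
#' @param threshold classification threshold in (0, 1).
#' @return list: sensitivity, specificity, kappa, table (2x2).
#' @export
confusion_metrics <- function(y, scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop_sdm("threshold must be in (0,1)", class = "sdm_config_error")
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & y == 1); FN <- sum(pred == 0 & y == 1)
  FP <- sum(pred == 1 & y == 0); TN <- sum(pred == 0 & y == 0)
  n <- TP + FN + FP + TN
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  po <- (TP + TN) / n
  pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  kap <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  list(sensitivity = sens, specificity = spec, kappa = kap,
       table = matrix(c(TP, FN, FP, TN), 2, 2,
                      dimnames = list(pred = c("1", "0"), obs = c("1", "0"))))
}

#' Repeated k-fold cross-validation of a model specification
#'
#' Per repeat: split (stratified by default, given the extreme class
#' imbalance), fit on the training folds, predict held-out probabilities,
#' and compute AUC / sensitivity / specificity / kappa. Metrics are reported
#' at the fixed `threshold` and also at the prevalence of the training data
#' (`threshold = "prevalence"` rows), since at ~0.5% prevalence a 0.5 cutoff
#' classifies everything absent.
#'
#' @param obs observation data.frame.
#' @param spec a [model_spec()].
#' @param mesh mesh if the spec is spatial.
#' @param k folds (default 5: 80% train / 20% test).
#' @param repeats independent k-fold repeats averaged in the report.
#' @param seed master seed; per-repeat seeds are derived.
#' @param threshold fixed classification threshold.
#' @param stratified stratify folds on presence.
#' @param n_samples posterior draws per prediction.
#' @param control fitting control.
#' @return list of class `metric_report`: `per_fold` (data.frame), `mean`
#'   (averaged metrics), `failed_folds`.
#' @export
cross_validate <- function(obs, spec, mesh = NULL, k = 5, repeats = 5,
                           seed = 1L, threshold = 0.5, stratified = TRUE,
                           n_samples = 200, control = list()) {
  rows <- list(); failed <- character(0)
  for (r in seq_len(repeats)) {
    fold <- kfold_split(nrow(obs), k, derive_seed(seed, paste0("cv", r)),
                        stratified = stratified, y = obs$presence)
    for (fd in seq_len(k)) {
      train <- obs[fold != fd, , drop = FALSE]
      test <- obs[fold == fd, , drop = FALSE]
      res <- tryCatch({
        f <- fit_sdm(train, spec, mesh = if (spec$include_spatial) mesh,
                     control = control)
        p <- predict_prob(f, test,
                          n_samples = n_samples,
                          seed = derive_seed(seed, paste0("pr", r, "_", fd)))
        a <- auc(test$presence, p)
        m1 <- confusion_metrics(test$presence, p, threshold)
        thr_prev <- max(min(mean(train$presence), 1 - 1e-9), 1e-9)
        m2 <- confusion_metrics(test$presence, p, thr_prev)
        data.frame(repeat_ix = r, fold = fd, n_test = nrow(test),
                   auc = a, sensitivity = m1$sensitivity,
                   specificity = m1$specificity, kappa = m1$kappa,
                   sensitivity_prev = m2$sensitivity,
                   specificity_prev = m2$specificity, kappa_prev = m2$kappa,
                   threshold = threshold, threshold_prev = thr_prev)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, sprintf("r%df%d: %s", r, fd, conditionMessage(res)))
      } else rows[[length(rows) + 1]] <- res
    }
  }
  per_fold <- do.call(rbind, rows)
  mcols <- c("auc", "sensitivity", "specificity", "kappa",
             "sensitivity_prev", "specificity_prev", "kappa_prev")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[mcols], na.rm = TRUE),
                 failed_folds = failed, k = k, repeats = repeats,
                 threshold = threshold),
            class = "metric_report")
}

#' @exportS3Method base::print
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d-fold x %d repeats (threshold %.3g)\n",
              x$k, x$repeats, x$threshold))
  print(round(x$mean, 4))
  if (length(x$failed_folds)) cat("failed folds:", length(x$failed_folds), "\n")
  invisible(x)
}

#' Posterior mean presence probability for new observations
#'
#' Builds the new rows' design against the training assembly (smooth
#' covariates are looked up in the training bins, values outside the training
#' range clamped to the outermost bin) and averages logit^-1(eta) over
#' posterior draws.
#'
#' @param fit an `sdm_fit`.
#' @param newdata data.frame with the model's covariate columns (and lon/lat
#'   for spatial models).
#' @param n_samples posterior draws.
#' @param seed integer seed.
#' @return vector of probabilities.
#' @export
predict_prob <- function(fit, newdata, n_samples = 200, seed = 1L) {
  A <- design_for_newdata(fit, newdata)$A
  x <- sample_posterior(fit, n_samples, seed)
  rowMeans(plogis(as.matrix(A %*% x)))
}

# Sparse design map for new rows, re-using the training block layout.
# Returns list(A, clamped = count of out-of-range smooth lookups,
# outside = count of points outside the mesh).
design_for_newdata <- function(fit, newdata, settype = NULL) {
  assembly <- fit$assembly
  n <- nrow(newdata)
  cols <- list()
  clamped <- 0L; outside <- 0L
  for (b in assembly$blocks) {
    if (b$type == "fixed") {
      Xf <- matrix(1, n, 1)
      lbl <- b$labels
      stcols <- grep(" set$", lbl, value = TRUE)
      if (length(stcols)) {
        st <- settype %||% newdata$set_type
        if (is.null(st)) stop_sdm("set_type needed for prediction",
                                  class = "sdm_data_error")
        st <- factor(as.character(st), levels = set_type_levels)
        for (sc in stcols) {
          levn <- sub(" set$", "", sc)
          Xf <- cbind(Xf, as.numeric(st == levn))
        }
      }
      lins <- setdiff(lbl, c("(Intercept)", stcols))
      for (v in lins) {
        xv <- newdata[[v]]
        if (is.null(xv)) stop_sdm("covariate '", v, "' missing",
                                  class = "sdm_data_error")
        Xf <- cbind(Xf, xv - assembly$lin_centers[[v]])
      }
      cols[[length(cols) + 1]] <- Matrix(Xf, sparse = TRUE)
    } else if (b$type %in% c("rw2", "rw2_cyclic")) {
      xv <- newdata[[b$name]]
      if (is.null(xv)) stop_sdm("covariate '", b$name, "' missing",
                                class = "sdm_data_error")
      br <- b$breaks
      below <- xv < br[1]; above <- xv > br[length(br)]
      clamped <- clamped + sum(below | above)
      lev <- as.integer(cut(pmin(pmax(xv, br[1]), br[length(br)]), br,
                            include.lowest = TRUE))
      cols[[length(cols) + 1]] <-
        Matrix::sparseMatrix(i = seq_len(n), j = lev, x = 1,
                             dims = c(n, b$n_bins))
    } else if (b$type == "field") {
      pr <- suppressWarnings(
        make_projector(fit$mesh, cbind(newdata$lon, newdata$lat)))
      outside <- outside + pr$n_outside
      cols[[length(cols) + 1]] <- pr$A
    }
  }
  list(A = as_dgC(do.call(cbind, cols)), clamped = clamped, outside = outside)
}
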