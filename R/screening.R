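# Pre-modelling collinearity screen: pairwise Pearson correlation with an
# |r| > 0.6 rule, then iterative removal of the largest generalized variance
# inflation factor until all GVIF <= 5.

#' Pairwise Pearson correlation matrix
#'
#' @param table data.frame of numeric columns.
#' @return symmetric matrix with unit diagonal; pairs involving a
#'   zero-variance column are NA and the column names are recorded in the
#'   `"flagged"` attribute.
#' @export
pearson_matrix <- function(table) {
  table <- as.data.frame(table)
  if (nrow(table) < 2) stop_sdm("need >= 2 rows", class = "sdm_data_error")
  num <- vapply(table, is.numeric, logical(1))
  if (!all(num)) stop_sdm("non-numeric columns: ",
                          paste(names(table)[!num], collapse = ", "),
                          class = "sdm_data_error")
  sds <- vapply(table, sd, numeric(1))
  flagged <- names(table)[sds == 0]
  R <- suppressWarnings(cor(table))
  diag(R) <- 1
  attr(R, "flagged") <- flagged
  R
}

#' Generalized variance inflation factor of one term
#'
#' For a 1-df numeric term this is the classical VIF = 1/(1 - R^2) from
#' regressing it on all other terms. For a d-df factor the GVIF is the
#' determinant ratio det(R11) det(R22) / det(R) of the predictor correlation
#' matrix partitioned into the term's columns and the rest; the
#' df-corrected value GVIF^(1/(2d)) is returned alongside.
#'
#' @param table data.frame of predictors (numeric and/or factor columns).
#' @param term column name to assess.
#' @return list with `gvif`, `df`, `gvif_corrected` (= GVIF^(1/(2 df))).
#'   Perfect collinearity yields `gvif = Inf`.
#' @export
gvif <- function(table, term) {
  table <- as.data.frame(table)
  if (!term %in% names(table)) stop_sdm("unknown term '", term, "'",
                                        class = "sdm_config_error")
  X <- model.matrix(~ . , data = table)[, -1, drop = FALSE]
  asg <- attr(model.matrix(~ ., data = table), "assign")[-1]
  cols <- which(asg == match(term, names(table)))
  if (ncol(X) == length(cols))  # no other terms
    return(list(gvif = 1, df = length(cols), gvif_corrected = 1))
  R <- cor(X)
  if (any(!is.finite(R))) stop_sdm("zero-variance predictor column",
                                   class = "sdm_data_error")
  d <- function(M) det(as.matrix(M))
  detR <- d(R)
  g <- if (detR < 1e-12) Inf else
    d(R[cols, cols, drop = FALSE]) * d(R[-cols, -cols, drop = FALSE]) / detR
  if (!is.finite(g) || g < 0) g <- Inf
  df <- length(cols)
  list(gvif = g, df = df,
       gvif_corrected = if (is.finite(g)) g^(1 / (2 * df)) else Inf)
}

#' Screen covariates for collinearity
#'
#' Two-stage deterministic screen: (1) while any pair has |r| > `r_max`, drop
#' the member of the worst pair with the larger mean absolute correlation to
#' the remaining variables (alphabetical tie-break); (2) recompute GVIF and
#' repeatedly drop the largest until all GVIF <= `vif_max`.
#'
#' @param table data.frame of candidate predictors (numeric; factors allowed,
#'   they participate in the VIF stage only).
#' @param r_max pairwise correlation threshold (default 0.6).
#' @param vif_max GVIF threshold (default 5).
#' @return list of class `screening_report`: `correlation_matrix`, `gvif`
#'   (named, for retained terms), `dropped` (data.frame: variable, reason,
#'   value), `retained`.
#' @export
screen_covariates <- function(table, r_max = 0.6, vif_max = 5) {
  if (r_max <= 0 || vif_max <= 0)
    stop_sdm("thresholds must be > 0", class = "sdm_config_error")
  table <- as.data.frame(table)
  numvars <- names(table)[vapply(table, is.numeric, logical(1))]
  R_full <- pearson_matrix(table[numvars])
  dropped <- data.frame(variable = character(), reason = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  keep <- numvars
  repeat {
    if (length(keep) < 2) break
    R <- pearson_matrix(table[keep])
    Rabs <- abs(R); diag(Rabs) <- 0
    if (max(Rabs, na.rm = TRUE) <= r_max) break
    w <- which(Rabs == max(Rabs, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- keep[w]
    score <- vapply(pair, function(v)
      mean(Rabs[v, setdiff(keep, v)], na.rm = TRUE), numeric(1))
    drop_v <- pair[order(-score, pair)][1]
    dropped <- rbind(dropped, data.frame(variable = drop_v,
                                         reason = "correlation",
                                         value = max(Rabs, na.rm = TRUE)))
    keep <- setdiff(keep, drop_v)
  }
  retained <- c(keep, setdiff(names(table), numvars))
  repeat {
    if (length(retained) < 2) break
    gv <- vapply(retained, function(v) gvif(table[retained], v)$gvif, numeric(1))
    if (max(gv) <= vif_max) break
    worst <- names(gv)[order(-gv, names(gv))][1]
    dropped <- rbind(dropped, data.frame(variable = worst, reason = "vif",
                                         value = gv[[worst]]))
    retained <- setdiff(retained, worst)
  }
  if (!length(retained))
    stop_sdm("screening dropped every variable (empty retained set)",
             class = "sdm_data_error")
  gv_final <- if (length(retained) >= 2)
    vapply(retained, function(v) gvif(table[retained], v)$gvif, numeric(1))
  else setNames(1, retained)
  structure(list(correlation_matrix = R_full, gvif = gv_final,
                 dropped = dropped, retained = retained,
                 r_max = r_max, vif_max = vif_max),
            class = "screening_report")
}

#' @exportS3Method base::print
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    cat(" dropped :", paste(sprintf("%s (%s %.3g)", x$dropped$variable,
                                    x$dropped$reason, x$dropped$value),
                            collapse = "; "), "\n")
  invisible(x)
}

#' Write a screening report to disk
#'
#' JSON report plus a CSV correlation matrix.
#'
#' @param report a `screening_report`.
#' @param dir output directory.
#' @export
write_screening_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$correlation_matrix, file.path(dir, "correlation_matrix.csv"))
  jsonlite::write_json(list(retained = report$retained,
                            dropped = report$dropped,
                            gvif = as.list(report$gvif),
                            r_max = report$r_max, vif_max = report$vif_max),
                       file.path(dir, "screening.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
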