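#' @importFrom methods as is new
#' @importFrom stats approx cor dist dnorm lm model.matrix optim optimize
#'   pnorm qnorm quantile rbinom rnorm runif sd var setNames plogis qlogis
#' @importFrom utils read.csv write.csv modifyList str
#' @importFrom tools md5sum
#' @import Matrix
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sdm <- function(..., class = "sdm_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Inverse-logit transform
#'
#' @param x numeric vector on the linear-predictor (logit) scale.
#' @return probabilities in (0, 1).
#' @keywords internal
inv_logit <- function(x) plogis(x)

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Derive a reproducible stage seed from a master seed
#'
#' Each pipeline stage gets its own pseudo-independent stream derived
#' deterministically from the master seed and the stage name, so stages can be
#' re-run in isolation without replaying earlier stages.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (as.double(master) * 48271 + h * 69621) %% (2^31 - 1)
  as.integer(max(1, s))
}

# Planar equirectangular scaling: longitudes compressed by cos(reference lat)
# so Euclidean distance in the scaled plane approximates great-circle distance
# in degrees at desk scale.
scale_coords <- function(lon, lat, lat0) {
  cbind(x = lon * cos(lat0 * pi / 180), y = lat)
}

# Pairwise Euclidean distances between rows of two matrices.
cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

as_dgC <- function(m) as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
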