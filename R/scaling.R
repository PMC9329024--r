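# Min-max feature scaling and principal-component reduction.
#
# Both are fit on a training matrix and frozen; at predict time the scaler
# clips out-of-range values to [0, 1] so downstream models never see inputs
# outside the fitted box, and the projection centres with the fitted mean.

#' Fit a per-feature min-max scaler
#'
#' @param x numeric matrix (rows = samples).
#' @return An object of class `feature_scaler` holding per-feature minima
#'   and maxima.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 1L)
  structure(
    list(min = apply(x, 2, min), max = apply(x, 2, max)),
    class = "feature_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature by `(x - min) / (max - min)`; constant features map to
#' 0 and out-of-range values are clipped to `[0, 1]`.
#'
#' @param scaler a [fit_scaler()] result.
#' @param x numeric matrix with the same columns as the fit matrix.
#' @return The scaled matrix, entries in `[0, 1]`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(scaler$min))
  rng <- scaler$max - scaler$min
  constant <- rng == 0
  rng[constant] <- 1
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2, rng, "/")
  out[, constant] <- 0  # features with no fitted spread carry no signal
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Fit a principal-component projection
#'
#' The effective number of retained components is
#' `min(k, nrow(x) - 1, ncol(x))`: with T fitted rows at most T - 1
#' components carry variance, so a configured k above that bound is capped
#' rather than padded.
#'
#' @param x numeric matrix with at least 2 rows.
#' @param k requested number of components (>= 1).
#' @return An object of class `projection_model` with fields `center`,
#'   `rotation` (orthonormal columns), `sdev` and `k` (effective).
#' @export
fit_projection <- function(x, k) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k_eff <- min(k, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(k_eff, ncol(pc$rotation)))
  structure(
    list(center = pc$center,
         rotation = pc$rotation[, keep, drop = FALSE],
         sdev = pc$sdev[keep],
         k = length(keep)),
    class = "projection_model"
  )
}

#' Project rows onto fitted principal components
#'
#' @param model a [fit_projection()] result.
#' @param x numeric matrix (or a single row as a vector).
#' @return Matrix of scores with `model$k` columns.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "projection_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(as.matrix(x), 2, model$center, "-") %*% model$rotation
}
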