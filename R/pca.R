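#' Fit a PCA reduction on training features
#'
#' Mean-centered principal axes ordered by descending explained variance,
#' computed with [stats::prcomp()] (no scaling, no whitening). Component
#' signs are fixed so that the largest-magnitude loading of every component
#' is positive, making the fit deterministic. The model is intended to be fit
#' on training features only and applied unchanged to test features.
#'
#' @param train_features `n x d` numeric matrix, `n >= out_dim + 1`.
#' @param out_dim Number of retained components (the pipeline default reduces
#'   4,000-dimensional visual representations to 100).
#' @return An object of class `bok_pca` with fields `mean` (length `d`),
#'   `components` (`out_dim x d`, row-orthonormal) and `explained_variances`
#'   (non-increasing).
#' @export
#' @examples
#' x <- matrix(rnorm(200 * 50), 200, 50)
#' p <- fit_pca(x, out_dim = 10)
#' dim(apply_pca(p, x))
fit_pca <- function(train_features, out_dim = 100) {
  stopifnot(is.matrix(train_features), is.numeric(train_features))
  if (anyNA(train_features) || any(!is.finite(train_features)))
    stop("features contain non-finite values")
  n <- nrow(train_features)
  if (n < out_dim + 1)
    stop(sprintf(
      "PCA needs at least out_dim + 1 = %d training rows but got %d; reduce out_dim to at most %d",
      out_dim + 1, n, n - 1))
  pr <- stats::prcomp(train_features, center = TRUE, scale. = FALSE,
                      rank. = out_dim)
  comp <- t(pr$rotation)                       # out_dim x d
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(mean = pr$center, components = comp,
                 explained_variances = pr$sdev[seq_len(nrow(comp))]^2,
                 out_dim = nrow(comp)),
            class = "bok_pca")
}

#' @export
print.bok_pca <- function(x, ...) {
  cat(sprintf("<bok_pca> %d -> %d dimensions, leading variance %.4g\n",
              length(x$mean), x$out_dim, x$explained_variances[1]))
  invisible(x)
}

#' Project features through a fitted PCA model
#'
#' @param model A `bok_pca` object.
#' @param features `n x d` matrix with `d` matching the fit.
#' @return `n x out_dim` matrix of scores.
#' @export
apply_pca <- function(model, features) {
  stopifnot(inherits(model, "bok_pca"))
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$mean))
    stop(sprintf("feature dimension (%d) does not match the PCA fit (%d)",
                 ncol(features), length(model$mean)))
  sweep(features, 2, model$mean) %*% t(model$components)
}

#' @export
predict.bok_pca <- function(object, newdata, ...) apply_pca(object, newdata)
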