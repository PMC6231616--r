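#' Random-forest configuration
#'
#' Defaults follow the reference setup: 1,000 bagged trees grown deep
#' (unlimited depth) with the `sqrt(d)` features-per-split heuristic.
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth; `Inf` grows trees to purity.
#' @param features_per_split Number of candidate features per split; `NULL`
#'   uses `floor(sqrt(d))`.
#' @param bootstrap If `FALSE`, every tree sees the full training set (useful
#'   for memorization checks); the default is bootstrap bagging.
#' @param seed Integer seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1000, max_depth = Inf,
                      features_per_split = NULL, bootstrap = TRUE, seed = 1) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 features_per_split = features_per_split,
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "rf_config")
}

#' Train a bagged random forest on reduced features
#'
#' Thin deterministic wrapper around [ranger::ranger()] (single-threaded,
#' seeded) keeping the class universe of the training labels.
#'
#' @param features `n x d` numeric matrix.
#' @param labels Character or factor class labels, length `n`.
#' @param config An [rf_config()] object.
#' @return An object of class `rf_model`.
#' @export
#' @examples
#' x <- matrix(rnorm(60 * 5), 60, 5)
#' y <- rep(c("a", "b"), 30)
#' m <- train_random_forest(x, y, rf_config(n_trees = 50))
#' mean(predict(m, x)$labels == y)
train_random_forest <- function(features, labels, config = rf_config()) {
  stopifnot(is.matrix(features), inherits(config, "rf_config"))
  if (nrow(features) < 2) stop("random-forest training needs at least 2 samples")
  if (length(labels) != nrow(features))
    stop("`labels` must have one entry per feature row")
  y <- factor(as.character(labels))
  d <- ncol(features)
  mtry <- config$features_per_split %||% max(1L, floor(sqrt(d)))
  if (nlevels(y) == 1) {
    # degenerate but legal: a single observed class, predicted unconditionally
    return(structure(list(forest = NULL, levels = levels(y), d = d,
                          config = config),
                     class = "rf_model"))
  }
  dat <- data.frame(features, check.names = FALSE)
  colnames(dat) <- paste0("f", seq_len(d))
  fit <- ranger::ranger(
    x = dat, y = y,
    num.trees = config$n_trees,
    mtry = min(mtry, d),
    max.depth = if (is.finite(config$max_depth)) config$max_depth else NULL,
    replace = config$bootstrap,
    sample.fraction = if (config$bootstrap) 1 else 1,
    seed = config$seed,
    num.threads = 1,
    verbose = FALSE)
  structure(list(forest = fit, levels = levels(y), d = d, config = config),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, %d features, %d class(es)\n",
              x$config$n_trees, x$d, length(x$levels)))
  invisible(x)
}

#' Predict classes by majority vote over trees
#'
#' @param object An `rf_model`.
#' @param newdata `n x d` feature matrix.
#' @param ... Unused.
#' @return A list with `labels` (majority-vote class per row, distance ties
#'   resolving to the lexicographically smallest label) and `votes`
#'   (`n x n_classes` matrix of per-class vote fractions, rows summing to 1).
#' @export
predict.rf_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$d)
    stop(sprintf("feature dimension (%d) does not match training (%d)",
                 ncol(newdata), object$d))
  if (is.null(object$forest)) {
    votes <- matrix(1, nrow(newdata), 1, dimnames = list(NULL, object$levels))
    return(list(labels = rep(object$levels, nrow(newdata)), votes = votes))
  }
  dat <- data.frame(newdata, check.names = FALSE)
  colnames(dat) <- paste0("f", seq_len(object$d))
  pr <- stats::predict(object$forest, data = dat, predict.all = TRUE,
                       num.threads = 1)$predictions
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(dat))
  lev <- object$forest$forest$levels
  n_class <- length(lev)
  votes <- t(apply(pr, 1, tabulate, nbins = n_class)) / ncol(pr)
  # order classes lexicographically so which.max tie-breaks to the smallest
  ord <- order(lev)
  votes <- votes[, ord, drop = FALSE]
  colnames(votes) <- lev[ord]
  labels <- colnames(votes)[apply(votes, 1, which.max)]
  list(labels = labels, votes = votes)
}

#' Exact-match annotation accuracy
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction of exact matches in `[0, 1]`.
#' @export
evaluate_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(predicted), length(truth)))
  if (length(truth) == 0) stop("cannot score zero predictions")
  mean(as.character(predicted) == as.character(truth))
}
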