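#' Build a visual-word codebook by k-means clustering
#'
#' Lloyd iterations over a descriptor pool: centers are initialized from `k`
#' random distinct data points, each descriptor is assigned to its nearest
#' center under L2 (kd-tree lookup, exact by default, ANN-style approximate
#' when `max_comparisons` is finite), centers are recomputed as assignment
#' means, and empty clusters are re-seeded from the points farthest from
#' their centers. Iteration stops when assignments no longer change or after
#' `max_iter` rounds; the within-cluster sum of squares is recorded at every
#' assignment step.
#'
#' @param pool Descriptor pool: an `n x d` matrix (or the list returned by
#'   [sample_descriptors()]).
#' @param k Number of visual words.
#' @param max_iter Maximum number of Lloyd iterations.
#' @param seed Integer seed for initialization.
#' @param max_comparisons Per-query budget of center points examined during
#'   assignment; `Inf` (default) requests exact nearest-center search.
#' @return An object of class `bok_codebook` with fields `centers` (`k x d`),
#'   `k`, `objective` (WCSS per iteration), `iterations`, `converged`,
#'   `train_seed` and `max_comparisons`.
#' @export
#' @examples
#' pool <- matrix(runif(200 * 16), 200, 16)
#' book <- build_codebook(pool, k = 5, seed = 1)
#' book$k
build_codebook <- function(pool, k, max_iter = 20, seed = 1,
                           max_comparisons = Inf) {
  if (is.list(pool) && !is.null(pool$descriptors)) pool <- pool$descriptors
  stopifnot(is.matrix(pool), is.numeric(pool))
  n <- nrow(pool)
  if (n < k)
    stop(sprintf("descriptor pool (%d) is smaller than the requested codebook size (%d)",
                 n, k))
  mc <- if (is.finite(max_comparisons)) max_comparisons else 0

  init <- with_seed(seed, sample.int(n, k))
  centers <- pool[init, , drop = FALSE]
  assign_prev <- NULL
  objective <- numeric(0)
  iterations <- 0L
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    q <- if (mc == 0) linear_quantize_cpp(pool, centers)
         else kdtree_quantize_cpp(pool, centers, mc)
    objective <- c(objective, sum(q$d2))
    iterations <- it
    if (!is.null(assign_prev) && identical(q$idx, assign_prev)) {
      converged <- TRUE
      break
    }
    assign_prev <- q$idx
    sums <- rowsum(pool, group = q$idx)      # one row per occupied cluster
    sizes <- tabulate(q$idx, nbins = k)
    nonempty <- sizes > 0
    rows <- match(which(nonempty), as.integer(rownames(sums)))
    centers[nonempty, ] <- sums[rows, , drop = FALSE] / sizes[nonempty]
    empty <- which(!nonempty)
    if (length(empty) > 0) {
      far <- order(q$d2, decreasing = TRUE)[seq_along(empty)]
      centers[empty, ] <- pool[far, , drop = FALSE]
    }
  }

  structure(list(centers = centers, k = as.integer(k), objective = objective,
                 iterations = iterations, converged = converged,
                 train_seed = as.integer(seed), max_comparisons = max_comparisons),
            class = "bok_codebook")
}

#' @export
print.bok_codebook <- function(x, ...) {
  cat(sprintf("<bok_codebook> k = %d, d = %d, %d iteration(s)%s, final WCSS = %.4g\n",
              x$k, ncol(x$centers), x$iterations,
              if (x$converged) " (converged)" else "",
              utils::tail(x$objective, 1)))
  invisible(x)
}

#' Quantize descriptors against a codebook
#'
#' Maps every non-low-contrast descriptor to the index of its nearest
#' codebook center under L2, using a kd-tree over the centers. Exact search
#' (the default) agrees with brute force; a finite `max_comparisons` gives
#' the approximate-nearest-neighbour behaviour used to speed up large
#' codebooks. Distance ties resolve to the lowest center index.
#'
#' @param desc A `descriptor_set` (low-contrast frames are excluded) or a
#'   plain descriptor matrix.
#' @param book A `bok_codebook`.
#' @param max_comparisons Per-query budget of centers examined; `NULL` uses
#'   the codebook's own setting; `Inf` forces exact search.
#' @param engine Search backend: `"kdtree"` (branch-and-bound, required for a
#'   finite budget), `"linear"` (exact partial-distance scan) or `"auto"`
#'   (kd-tree when budgeted, linear when exact). Both exact routes return
#'   identical assignments.
#' @return A list with `words` (1-based word ids), `frames` (the surviving
#'   frames, when `desc` is a descriptor set) and `d2` (squared distances).
#' @export
quantize <- function(desc, book, max_comparisons = Inf,
                     engine = c("auto", "kdtree", "linear")) {
  stopifnot(inherits(book, "bok_codebook"))
  frames <- NULL
  if (inherits(desc, "descriptor_set")) {
    keep <- !desc$low_contrast
    frames <- desc$frames[keep, , drop = FALSE]
    x <- desc$descriptors[keep, , drop = FALSE]
  } else {
    x <- desc
  }
  stopifnot(is.matrix(x))
  if (ncol(x) != ncol(book$centers) && nrow(x) > 0)
    stop(sprintf("descriptor dimension (%d) does not match codebook (%d)",
                 ncol(x), ncol(book$centers)))
  if (nrow(x) == 0)
    return(list(words = integer(0), frames = frames, d2 = numeric(0)))
  mc <- max_comparisons %||% book$max_comparisons
  engine <- match.arg(engine)
  if (engine == "auto") engine <- if (is.finite(mc)) "kdtree" else "linear"
  q <- if (engine == "linear") linear_quantize_cpp(x, book$centers)
       else kdtree_quantize_cpp(x, book$centers, if (is.finite(mc)) mc else 0)
  list(words = q$idx, frames = frames, d2 = q$d2)
}
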