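#' Multi-scale dense SIFT descriptors
#'
#' SIFT descriptors (4 x 4 spatial cells x 8 orientation bins = 128
#' dimensions) are computed on a regular grid with spacing `step` at every
#' scale in `bin_sizes`; at bin size `b` a frame covers a `4b x 4b` support.
#' Gradient magnitude is shared linearly between the two adjacent orientation
#' bins; spatial pooling over the cells is flat. Descriptors are
#' L2-normalized, clamped at 0.2 and renormalized. Frames whose mean gradient
#' magnitude over the support falls below `contrast_threshold` are flagged
#' low-contrast and emitted as zero vectors.
#'
#' @param img Grayscale intensity matrix in `[0, 1]`.
#' @param step Grid spacing in pixels.
#' @param bin_sizes Integer vector of spatial bin sizes (pixel scales).
#' @param contrast_threshold Mean-gradient-magnitude cutoff on the `[0, 1]`
#'   intensity scale below which a frame is flagged low-contrast.
#' @return A list of class `descriptor_set`:
#'   `frames` (data.frame of 0-based center coordinates `x`, `y` and `scale`),
#'   `descriptors` (`n x 128` matrix) and `low_contrast` (logical flags).
#' @export
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' ds <- dense_sift(img, step = 4, bin_sizes = c(4, 6))
#' nrow(ds$descriptors)
dense_sift <- function(img, step = 4, bin_sizes = c(4, 6, 8, 10),
                       contrast_threshold = 0.005) {
  assert_gray_image(img)
  stopifnot(step >= 1, all(bin_sizes >= 1))
  fx <- fy <- fs <- vector("list", length(bin_sizes))
  descs <- vector("list", length(bin_sizes))
  flags <- vector("list", length(bin_sizes))
  multi <- dsift_multi_cpp(img, as.integer(step), as.integer(bin_sizes),
                           contrast_threshold)
  for (s in seq_along(bin_sizes)) {
    b <- as.integer(bin_sizes[s])
    res <- multi[[s]]
    nf <- res$nr * res$nc
    if (nf == 0) next
    support <- 4L * b
    fr <- rep(seq_len(res$nr) - 1L, times = res$nc)
    fc <- rep(seq_len(res$nc) - 1L, each = res$nr)
    fx[[s]] <- fc * step + (support - 1) / 2
    fy[[s]] <- fr * step + (support - 1) / 2
    fs[[s]] <- rep(b, nf)
    descs[[s]] <- res$descriptors
    flags[[s]] <- res$flags
  }
  keep <- !vapply(descs, is.null, logical(1))
  if (!any(keep)) {
    warning(sprintf(
      "image (%d x %d) is smaller than the smallest descriptor support (%d); no frames emitted",
      nrow(img), ncol(img), 4 * min(bin_sizes)))
    return(structure(list(frames = data.frame(x = numeric(0), y = numeric(0),
                                              scale = numeric(0)),
                          descriptors = matrix(0, 0, 128),
                          low_contrast = logical(0)),
                     class = "descriptor_set"))
  }
  structure(list(frames = data.frame(x = unlist(fx), y = unlist(fy),
                                     scale = unlist(fs)),
                 descriptors = do.call(rbind, descs[keep]),
                 low_contrast = do.call(c, flags[keep])),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d frames (%d low-contrast), scales: %s\n",
              nrow(x$descriptors), sum(x$low_contrast),
              paste(unique(x$frames$scale), collapse = ", ")))
  invisible(x)
}

#' Pool descriptors from several images for codebook training
#'
#' Draws a uniform sample without replacement of at most `n` descriptors from
#' the non-low-contrast descriptors of a collection of descriptor sets.
#'
#' @param sets List of `descriptor_set` objects.
#' @param n Maximum pool size; `min(n, available)` descriptors are returned.
#' @param seed Integer seed making the sample reproducible.
#' @return A list with `descriptors` (pooled matrix) and `source` (index of
#'   the originating set per pooled descriptor).
#' @export
sample_descriptors <- function(sets, n, seed) {
  stopifnot(is.list(sets), length(sets) >= 1, n >= 1)
  usable <- lapply(sets, function(s) {
    stopifnot(inherits(s, "descriptor_set"))
    s$descriptors[!s$low_contrast, , drop = FALSE]
  })
  counts <- vapply(usable, nrow, integer(1))
  total <- sum(counts)
  if (total == 0) stop("all descriptors are flagged low-contrast; nothing to pool")
  pool <- do.call(rbind, usable)
  src <- rep(seq_along(usable), counts)
  take <- min(n, total)
  sel <- with_seed(seed, sample.int(total, take))
  sel <- sort(sel)
  list(descriptors = pool[sel, , drop = FALSE], source = src[sel])
}
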