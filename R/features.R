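#' Spatially binned visual-word histogram
#'
#' The image is split into a 2 x 2 grid of quadrants (with odd sizes the
#' extra pixel goes to the right/bottom cells); a `k`-bin word-count
#' histogram is formed per quadrant and the four histograms are concatenated
#' in row-major quadrant order (top-left, top-right, bottom-left,
#' bottom-right), giving a `4k`-dimensional representation (4,000 at the
#' default codebook size of 1,000).
#'
#' @param frames Frame coordinates (data.frame with 0-based `x`, `y`), one
#'   row per quantized descriptor.
#' @param words 1-based word ids, parallel to `frames`.
#' @param image_size `c(height, width)` of the source image.
#' @param k Codebook size.
#' @param normalize If `TRUE`, L1-normalize the concatenated histogram
#'   (counts are the default; tree ensembles are insensitive to monotone
#'   per-feature scaling).
#' @return Numeric vector of length `4 * k`.
#' @export
spatial_histogram <- function(frames, words, image_size, k, normalize = FALSE) {
  stopifnot(length(words) == nrow(frames), k >= 1)
  if (length(words) > 0 && max(words) > k)
    stop(sprintf("word id %d exceeds codebook size %d", max(words), k))
  H <- image_size[1]; W <- image_size[2]
  if (length(words) > 0 &&
      (any(frames$x < 0) || any(frames$x > W - 1) ||
       any(frames$y < 0) || any(frames$y > H - 1)))
    stop("frame coordinates fall outside the image bounds")
  # 0-based centers; first cell spans floor(size/2) pixels
  qrow <- as.integer(frames$y >= floor(H / 2))
  qcol <- as.integer(frames$x >= floor(W / 2))
  quadrant <- qrow * 2L + qcol          # 0..3, row-major
  idx <- quadrant * k + as.integer(words)
  tabulate(idx, nbins = 4 * k) * (if (normalize && length(words) > 0)
    1 / length(words) else 1)
}

#' Bag-of-Keypoints feature vector of a prepared image
#'
#' Convenience wrapper chaining [dense_sift()], [quantize()] and
#' [spatial_histogram()]. Layered (3-channel) inputs are collapsed to
#' luminance before descriptor extraction, the standard grayscale treatment
#' of dense SIFT on color inputs.
#'
#' @param img Grayscale matrix or layered array.
#' @param book A `bok_codebook`.
#' @param step,bin_sizes,contrast_threshold Dense-SIFT settings.
#' @param max_comparisons Quantization budget (see [quantize()]).
#' @param normalize Passed to [spatial_histogram()].
#' @return Numeric vector of length `4 * book$k`.
#' @export
extract_bok_feature <- function(img, book, step = 4, bin_sizes = c(4, 6, 8, 10),
                                contrast_threshold = 0.005,
                                max_comparisons = Inf, normalize = FALSE) {
  gray <- if (is_layered(img)) pmin(pmax(luminance(img), 0), 1) else img
  ds <- dense_sift(gray, step = step, bin_sizes = bin_sizes,
                   contrast_threshold = contrast_threshold)
  q <- quantize(ds, book, max_comparisons = max_comparisons)
  spatial_histogram(q$frames, q$words, dim(gray), book$k, normalize = normalize)
}
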