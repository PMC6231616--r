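#' CLAHE parameters
#'
#' Defaults follow the enhancement configuration used throughout the package:
#' an 8 x 8 tile grid, a clip limit of 0.01 (fraction of the tile pixel
#' count), 256 histogram bins, output spanning the full `[0, 1]` range and a
#' uniform target histogram. `alpha` is the shape parameter of the Rayleigh
#' target distribution and is inert under the default uniform shape.
#'
#' @param num_tiles Integer `(rows, cols)` of the tile grid.
#' @param clip_limit Histogram clip limit as a fraction in `(0, 1]` of the
#'   tile pixel count.
#' @param n_bins Number of histogram bins.
#' @param distribution Target histogram shape, `"uniform"` or `"rayleigh"`.
#' @param alpha Rayleigh shape parameter.
#' @return A list of class `clahe_params`.
#' @export
clahe_params <- function(num_tiles = c(8, 8), clip_limit = 0.01, n_bins = 256,
                         distribution = c("uniform", "rayleigh"), alpha = 0.4) {
  distribution <- match.arg(distribution)
  stopifnot(length(num_tiles) == 2, all(num_tiles >= 1), n_bins >= 2, alpha > 0)
  if (!is.numeric(clip_limit) || clip_limit <= 0 || clip_limit > 1)
    stop("`clip_limit` must lie in (0, 1]")
  structure(list(num_tiles = as.integer(num_tiles), clip_limit = clip_limit,
                 n_bins = as.integer(n_bins), distribution = distribution,
                 alpha = alpha),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is partitioned into a `num_tiles` grid (edge tiles absorb the
#' remainder rows/columns). Each tile's `n_bins` histogram is clipped at
#' `ceiling(clip_limit * tile_pixel_count)`; the clipped excess is
#' redistributed uniformly over all bins, iterating until the residual excess
#' falls below one count. The tile mapping is the cumulative distribution of
#' the clipped histogram scaled to the full output range (for the Rayleigh
#' shape, passed through the inverse Rayleigh CDF and rescaled). Each output
#' pixel bilinearly interpolates the mappings of its up-to-four surrounding
#' tile centers, with clamped replication beyond the outermost centers.
#'
#' @param img Grayscale intensity matrix in `[0, 1]`.
#' @param params A [clahe_params()] object.
#' @return Enhanced intensity matrix in `[0, 1]`.
#' @export
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' out <- apply_clahe(img, clahe_params())
apply_clahe <- function(img, params = clahe_params()) {
  assert_gray_image(img)
  stopifnot(inherits(params, "clahe_params"))
  H <- nrow(img); W <- ncol(img)
  tr <- params$num_tiles[1]; tc <- params$num_tiles[2]
  if (H < tr || W < tc)
    stop(sprintf("image (%d x %d) is smaller than the %d x %d tile grid",
                 H, W, tr, tc))
  nb <- params$n_bins

  row_breaks <- tile_breaks(H, tr)
  col_breaks <- tile_breaks(W, tc)
  centers_r <- (row_breaks$lo + row_breaks$hi) / 2
  centers_c <- (col_breaks$lo + col_breaks$hi) / 2

  bins <- pmin(floor(img * nb), nb - 1)  # bin index, 0-based

  # per-tile mappings, flattened [n_bins x (tr*tc)] with tile (i,j) in
  # column (j-1)*tr + i
  maps <- matrix(0, nb, tr * tc)
  for (i in seq_len(tr)) {
    ri <- row_breaks$lo[i]:row_breaks$hi[i]
    for (j in seq_len(tc)) {
      cj <- col_breaks$lo[j]:col_breaks$hi[j]
      hist <- tabulate(bins[ri, cj] + 1L, nbins = nb)
      maps[, (j - 1L) * tr + i] <- clahe_tile_mapping(hist, params)
    }
  }

  # bilinear interpolation between tile-center mappings
  rw <- interp_weights(seq_len(H), centers_r)
  cw <- interp_weights(seq_len(W), centers_c)
  i0 <- rep(rw$i0, times = W); wi <- rep(rw$w, times = W)
  j0 <- rep(cw$i0, each = H);  wj <- rep(cw$w, each = H)
  i1 <- pmin(i0 + 1L, tr); j1 <- pmin(j0 + 1L, tc)
  b1 <- as.vector(bins) + 1L
  gather <- function(ii, jj) maps[b1 + ((jj - 1L) * tr + ii - 1L) * nb]
  out <- (1 - wi) * (1 - wj) * gather(i0, j0) +
         (1 - wi) * wj       * gather(i0, j1) +
         wi       * (1 - wj) * gather(i1, j0) +
         wi       * wj       * gather(i1, j1)
  out <- matrix(out, H, W)
  pmin(pmax(out, 0), 1)
}

# tile index ranges: tiles 1..(n-1) get floor(size/n), the last absorbs the rest
tile_breaks <- function(size, n) {
  base <- size %/% n
  lo <- (seq_len(n) - 1L) * base + 1L
  hi <- c(seq_len(n - 1L) * base, size)
  list(lo = lo, hi = hi)
}

# histogram clipping with iterated uniform redistribution, then scaled CDF
clahe_tile_mapping <- function(hist, params) {
  n_pix <- sum(hist)
  nb <- length(hist)
  clip <- ceiling(params$clip_limit * n_pix)
  repeat {
    excess <- sum(pmax(hist - clip, 0))
    if (excess < 1) break
    hist <- pmin(hist, clip) + excess / nb
  }
  cdf <- cumsum(hist) / n_pix
  if (params$distribution == "rayleigh") {
    # inverse Rayleigh CDF, rescaled so the mapping still spans [0, 1]
    p <- pmin(cdf, 1 - 1e-12)
    y <- params$alpha * sqrt(-2 * log(1 - p))
    ymax <- params$alpha * sqrt(-2 * log(1e-12))
    y / ymax
  } else {
    cdf
  }
}

# for each coordinate x: left center index i0 and weight w of center i0+1
interp_weights <- function(x, centers) {
  n <- length(centers)
  if (n == 1) return(list(i0 = rep(1L, length(x)), w = rep(0, length(x))))
  i0 <- findInterval(x, centers)
  w <- numeric(length(x))
  inside <- i0 >= 1 & i0 < n
  ii <- i0[inside]
  w[inside] <- (x[inside] - centers[ii]) / (centers[ii + 1] - centers[ii])
  w[i0 < 1] <- 0
  i0[i0 < 1] <- 1L
  w[i0 >= n] <- 1
  i0[i0 >= n] <- n - 1L
  list(i0 = i0, w = w)
}
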