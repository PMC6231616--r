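#' Non-local-means parameters
#'
#' Defaults use a patch half-width ("kernel ratio") of 4 pixels, a search
#' half-width ("window ratio") of 4 pixels — i.e. 9 x 9 patches compared
#' within 9 x 9 search windows — and a filter strength `h = 0.05` on the
#' `[0, 1]` intensity scale.
#'
#' @param kernel_radius Patch half-width in pixels.
#' @param window_radius Search-window half-width in pixels.
#' @param filter_strength Exponential decay scale `h` of the patch-distance
#'   weights.
#' @return A list of class `nlm_params`.
#' @export
nlm_params <- function(kernel_radius = 4, window_radius = 4,
                       filter_strength = 0.05) {
  stopifnot(kernel_radius >= 1, window_radius >= 1, filter_strength > 0)
  structure(list(kernel_radius = as.integer(kernel_radius),
                 window_radius = as.integer(window_radius),
                 filter_strength = filter_strength),
            class = "nlm_params")
}

#' Non-local-means denoising
#'
#' Every pixel becomes the weighted average of the pixels in its search
#' window; the weight of neighbour `j` decays exponentially with the
#' Gaussian-weighted mean squared difference between the patches around `i`
#' and `j` (`w = exp(-d / h^2)`, patch Gaussian `sigma = kernel_radius / 2`,
#' patch weights normalized to sum one). The self weight is set to the
#' maximum of the other weights in the window. Patches and window neighbours
#' beyond the image border are read from a symmetric (mirror) extension.
#'
#' @param img Grayscale intensity matrix in `[0, 1]`.
#' @param params An [nlm_params()] object.
#' @return Denoised intensity matrix in `[0, 1]`.
#' @export
#' @examples
#' img <- matrix(runif(32 * 32), 32, 32)
#' out <- apply_nl_means(img, nlm_params())
apply_nl_means <- function(img, params = nlm_params()) {
  assert_gray_image(img)
  stopifnot(inherits(params, "nlm_params"))
  out <- nlm_filter_cpp(img, params$kernel_radius, params$window_radius,
                        params$filter_strength)
  pmin(pmax(out, 0), 1)
}
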