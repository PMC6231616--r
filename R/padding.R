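#' Padding parameters
#'
#' @param target_side Side length in pixels of the square output canvas.
#' @return A list of class `pad_params`.
#' @export
pad_params <- function(target_side = 512) {
  stopifnot(target_side >= 1)
  structure(list(target_side = as.integer(target_side)), class = "pad_params")
}

#' Repetition padding to a fixed square canvas
#'
#' The image is first rescaled preserving its aspect ratio so that its longer
#' side equals `target_side` (bilinear interpolation); along the deficient
#' axis, cyclic copies of the rescaled image are then appended — restarting
#' from its first row or column and cropping the last copy — until the canvas
#' is exactly `target_side x target_side`. Content is anchored top-left. An
#' image that is already `target_side` square is returned unchanged.
#'
#' @param img Grayscale intensity matrix in `[0, 1]`.
#' @param params A [pad_params()] object.
#' @param fill Optional constant in `[0, 1]`; when supplied, the deficit is
#'   filled with this value instead of cyclic repetition.
#' @return A `target_side x target_side` intensity matrix.
#' @export
#' @examples
#' img <- matrix(runif(200 * 320), 200, 320)
#' dim(pad_with_repetition(img, pad_params()))
pad_with_repetition <- function(img, params = pad_params(), fill = NULL) {
  assert_gray_image(img)
  stopifnot(inherits(params, "pad_params"))
  side <- params$target_side
  H <- nrow(img); W <- ncol(img)
  if (H == side && W == side) return(img)

  scale <- side / max(H, W)
  new_h <- if (H >= W) side else max(1L, as.integer(round(H * scale)))
  new_w <- if (W > H) side else max(1L, as.integer(round(W * scale)))
  scaled <- resize_bilinear(img, new_h, new_w)

  out <- matrix(if (is.null(fill)) 0 else fill, side, side)
  if (is.null(fill)) {
    out[] <- scaled[((seq_len(side) - 1L) %% new_h) + 1L,
                    ((seq_len(side) - 1L) %% new_w) + 1L]
  } else {
    if (fill < 0 || fill > 1) stop("`fill` must lie in [0, 1]")
    out[seq_len(new_h), seq_len(new_w)] <- scaled
  }
  out
}
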