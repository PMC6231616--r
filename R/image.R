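#' Grayscale and layered image containers
#'
#' Images are plain base-R objects: a grayscale image is a numeric matrix
#' (rows = image rows, top-left origin) with intensities in `[0, 1]`; a
#' layered image is an `h x w x 3` numeric array whose channels are, in order,
#' the original intensities, the CLAHE-enhanced layer and the
#' non-local-means-denoised layer. 8-bit files map onto `[0, 1]` by `v / 255`
#' on read and `round(v * 255)` on write.
#'
#' @param img Object to validate.
#' @return `TRUE`, invisibly; otherwise an error is thrown.
#' @export
assert_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("a grayscale image must be a numeric matrix")
  if (nrow(img) < 1 || ncol(img) < 1)
    stop("image must have at least one row and one column")
  if (anyNA(img) || any(!is.finite(img)))
    stop("image contains non-finite intensities")
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1)
    stop(sprintf("intensities must lie in [0, 1]; observed range [%g, %g]",
                 rng[1], rng[2]))
  invisible(TRUE)
}

#' @rdname assert_gray_image
#' @export
assert_layered_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("a layered image must be an h x w x 3 array")
  for (ch in 1:3) assert_gray_image(img[, , ch])
  invisible(TRUE)
}

is_layered <- function(img) is.array(img) && length(dim(img)) == 3

#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file and returns a `[0, 1]` intensity matrix. RGB files
#' are collapsed to luminance (Rec. 601 weights); alpha channels are dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF): %s",
                 ext, path))
  )
  if (is_layered(img)) img <- luminance(img[, , 1:3, drop = FALSE])
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- dim(img)[1:2]
  img
}

#' Write an image as an 8-bit PNG or TIFF
#'
#' Grayscale matrices are written single-channel, layered arrays as 24-bit
#' RGB. Intensities are quantized with `round(v * 255)`.
#'
#' @param img Grayscale matrix or layered array.
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is_layered(img)) assert_layered_image(img) else assert_gray_image(img)
  q <- round(pmin(pmax(img, 0), 1) * 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q, path),
    tif = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format '.%s' (use PNG or TIFF)", ext))
  )
  invisible(path)
}

# Rec. 601 luminance of an h x w x 3 array
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# bilinear resize of an intensity matrix to out_h x out_w
resize_bilinear <- function(img, out_h, out_w) {
  if (nrow(img) == out_h && ncol(img) == out_w) return(img)
  out <- EBImage::resize(img, w = out_h, h = out_w, filter = "bilinear")
  out <- as.matrix(out)
  pmin(pmax(out, 0), 1)
}
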