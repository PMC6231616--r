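#' Stack original and enhanced layers into a pseudo-RGB image
#'
#' Radiographs are single-channel, but classifiers and pretrained networks
#' designed for natural images expect three channels. The layered
#' representation fills the three channels with the original intensities (R),
#' the CLAHE-enhanced layer (G) and the non-local-means-denoised layer (B).
#'
#' @param original,clahe_layer,nlm_layer Grayscale matrices of identical
#'   dimensions.
#' @return An `h x w x 3` layered array.
#' @export
stack_layers <- function(original, clahe_layer, nlm_layer) {
  assert_gray_image(original)
  assert_gray_image(clahe_layer)
  assert_gray_image(nlm_layer)
  if (!identical(dim(original), dim(clahe_layer)) ||
      !identical(dim(original), dim(nlm_layer)))
    stop(sprintf(
      "layer dimensions differ: original %s, clahe %s, nlm %s",
      paste(dim(original), collapse = "x"),
      paste(dim(clahe_layer), collapse = "x"),
      paste(dim(nlm_layer), collapse = "x")))
  array(c(original, clahe_layer, nlm_layer), dim = c(dim(original), 3))
}

#' The six input-preparation modes
#'
#' @return Character vector of mode identifiers, in canonical report order.
#' @export
input_modes <- function() {
  c("padded", "padded_layered", "layered", "clahe", "nlmeans", "original")
}

#' Display names of the input modes, as used in report rows
#' @param modes Mode identifiers.
#' @return Character vector of display labels.
#' @export
input_mode_labels <- function(modes = input_modes()) {
  labels <- c(padded = "Image Padding",
              padded_layered = "Image Padding/Layered",
              layered = "Image Layered",
              clahe = "CLAHE Image",
              nlmeans = "NLMEANS Image",
              original = "Original Image")
  if (!all(modes %in% names(labels)))
    stop(sprintf("unknown input mode(s): %s",
                 paste(setdiff(modes, names(labels)), collapse = ", ")))
  unname(labels[modes])
}

#' Prepare an image under one of the six input modes
#'
#' `original` returns the input unchanged; `clahe` and `nlmeans` apply the
#' respective enhancement; `layered` stacks the original with both enhanced
#' layers; `padded` applies repetition padding; `padded_layered` pads first
#' and then computes both enhancement layers on the padded image (keeping the
#' CLAHE tile grid aligned with the final geometry) before stacking.
#'
#' @param img Grayscale intensity matrix in `[0, 1]`.
#' @param mode One of [input_modes()].
#' @param clahe,nlm,pad Parameter objects.
#' @return A grayscale matrix, or an `h x w x 3` array for the layered modes.
#' @export
#' @examples
#' img <- matrix(runif(64 * 48), 64, 48)
#' dim(prepare_input(img, "layered"))
prepare_input <- function(img, mode, clahe = clahe_params(), nlm = nlm_params(),
                          pad = pad_params()) {
  assert_gray_image(img)
  if (!is.character(mode) || length(mode) != 1 || !(mode %in% input_modes()))
    stop(sprintf("unknown input mode '%s'; valid modes: %s",
                 paste(mode, collapse = ","), paste(input_modes(), collapse = ", ")))
  switch(mode,
    original = img,
    clahe    = apply_clahe(img, clahe),
    nlmeans  = apply_nl_means(img, nlm),
    layered  = stack_layers(img, apply_clahe(img, clahe), apply_nl_means(img, nlm)),
    padded   = pad_with_repetition(img, pad),
    padded_layered = {
      p <- pad_with_repetition(img, pad)
      stack_layers(p, apply_clahe(p, clahe), apply_nl_means(p, nlm))
    })
}

#' Export enhanced images for external training
#'
#' Runs [prepare_input()] over every image of a label table and writes the
#' result next to its original filename under `out_dir` — 8-bit grayscale PNG
#' for single-channel modes, 24-bit RGB PNG for the layered modes. Unreadable
#' inputs are logged and skipped.
#'
#' @param table Label table with an `image_id` column.
#' @param image_dir Directory containing the input images.
#' @param mode One of [input_modes()].
#' @param out_dir Output directory (created if missing).
#' @param clahe,nlm,pad Parameter objects.
#' @return A manifest `data.frame` with columns `image_id`, `path`, `status`;
#'   the number written is `sum(status == "written")`.
#' @export
export_enhanced <- function(table, image_dir, mode, out_dir,
                            clahe = clahe_params(), nlm = nlm_params(),
                            pad = pad_params()) {
  table <- validate_label_table(table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- character(nrow(table))
  paths <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    src <- file.path(image_dir, table$image_id[i])
    dst <- file.path(out_dir, paste0(tools::file_path_sans_ext(table$image_id[i]), ".png"))
    ok <- tryCatch({
      img <- read_gray_image(src)
      write_image(prepare_input(img, mode, clahe, nlm, pad), dst)
      TRUE
    }, error = function(e) {
      message(sprintf("skipping %s: %s", table$image_id[i], conditionMessage(e)))
      FALSE
    })
    status[i] <- if (ok) "written" else "skipped"
    paths[i] <- if (ok) dst else NA_character_
  }
  manifest <- data.frame(image_id = table$image_id, path = paths,
                         status = status, stringsAsFactors = FALSE)
  attr(manifest, "n_written") <- sum(status == "written")
  manifest
}
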