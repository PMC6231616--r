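#' Synthetic radiograph generator configuration
#'
#' The generator emulates the properties of annotated radiograph corpora that
#' the pipeline has to cope with — variable heights, widths and aspect ratios
#' (so padding is exercised in both directions), smooth radial vignetting,
#' additive Gaussian noise — and ties each axis of the synthetic multi-axial
#' code to a visually discriminative factor:
#'
#' * `T` (technical) selects the global contrast/texture regime,
#' * `D` (directional) selects the rotation of the whole scene,
#' * `A` (anatomical) selects the foreground shape family
#'   (ellipse / elongated bar / compound blob / ring),
#' * `B` (biological) selects the pitch of the oriented interior texture.
#'
#' The default vocabularies (2 T, 3 D, 4 A, 2 B values, 48 combinations)
#' mirror the ordering of difficulty of real multi-axial annotation: the T
#' scheme has the fewest classes and the strongest signal, the A and full
#' IRMA schemes the most classes.
#'
#' @param n_images Number of images to generate.
#' @param t_vocab,d_vocab,a_vocab,b_vocab Axis vocabularies (strings of the
#'   axis' width, characters `0-9a-z`).
#' @param height_range,width_range Inclusive pixel ranges sizes are drawn
#'   from.
#' @param noise_sigma Standard deviation of the additive Gaussian noise on
#'   the `[0, 1]` intensity scale.
#' @param vignette_strength Peak relative darkening at the image corners.
#' @param train_fraction Fraction of each full-code class routed to the
#'   training split.
#' @param seed Integer master seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_images = 300,
                             t_vocab = c("1121", "1124"),
                             d_vocab = c("127", "410", "228"),
                             a_vocab = c("732", "620", "213", "443"),
                             b_vocab = c("500", "625"),
                             height_range = c(200, 512),
                             width_range = c(200, 512),
                             noise_sigma = 0.05,
                             vignette_strength = 0.3,
                             train_fraction = 0.8,
                             seed = 1) {
  stopifnot(n_images >= 1,
            length(t_vocab) >= 1, length(d_vocab) >= 1,
            length(a_vocab) >= 1, length(b_vocab) >= 1,
            all(nchar(t_vocab) == 4), all(nchar(d_vocab) == 3),
            all(nchar(a_vocab) == 3), all(nchar(b_vocab) == 3),
            height_range[1] >= 64, width_range[1] >= 64,
            height_range[2] <= 512, width_range[2] <= 512,
            noise_sigma >= 0, vignette_strength >= 0, vignette_strength < 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_images = as.integer(n_images),
                 t_vocab = t_vocab, d_vocab = d_vocab,
                 a_vocab = a_vocab, b_vocab = b_vocab,
                 height_range = as.integer(height_range),
                 width_range = as.integer(width_range),
                 noise_sigma = noise_sigma,
                 vignette_strength = vignette_strength,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Render one synthetic radiograph
#'
#' Rendering is deterministic given `(code, seed)`. The scene — foreground
#' shape, its oriented interior texture and the T-regime background texture —
#' is evaluated on coordinates rotated about the image center by the D-axis
#' angle, so two codes differing only in D produce the same image up to that
#' rotation. Geometry (canvas size, shape scale and offset) is drawn from a
#' random stream keyed on the T/A/B axes and the seed, excluding D. An
#' isotropic radial vignette and i.i.d. Gaussian noise are applied last and
#' the result is clipped to `[0, 1]`.
#'
#' @param code An `irma_code` (or code string) with axis values drawn from
#'   the configured vocabularies.
#' @param config A [generator_config()].
#' @param seed Integer seed for this image.
#' @return A grayscale intensity matrix.
#' @export
#' @examples
#' cfg <- generator_config(noise_sigma = 0, vignette_strength = 0)
#' img <- generate_image("1121-127-732-500", cfg, seed = 7)
generate_image <- function(code, config = generator_config(), seed = 1) {
  if (is.character(code)) code <- parse_irma_code(code)
  stopifnot(inherits(code, "irma_code"), inherits(config, "generator_config"))
  ti <- match(code$technical, config$t_vocab)
  di <- match(code$directional, config$d_vocab)
  ai <- match(code$anatomical, config$a_vocab)
  bi <- match(code$biological, config$b_vocab)
  if (anyNA(c(ti, di, ai, bi)))
    stop(sprintf("code %s uses axis values outside the generator vocabularies",
                 format(code)))

  # geometry stream is keyed without the D axis: D-only changes rotate the
  # scene but leave canvas and placement untouched
  geom_seed <- derive_seed(seed, paste("geom", code$technical,
                                       code$anatomical, code$biological))
  geom <- with_seed(geom_seed, {
    list(h = sample(seq(config$height_range[1], config$height_range[2]), 1),
         w = sample(seq(config$width_range[1], config$width_range[2]), 1),
         scale_jit = stats::runif(1, 0.85, 1.1),
         off_u = stats::runif(1, -0.08, 0.08),
         off_v = stats::runif(1, -0.08, 0.08))
  })
  H <- geom$h; W <- geom$w

  # D selects the scene rotation; families below are 180-degree symmetric,
  # so angles are spread over [0, 180) to keep classes distinct
  n_d <- length(config$d_vocab)
  angle <- (di - 1) * pi / max(n_d, 2)

  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  y <- matrix(rep(seq_len(H), times = W), H, W) - cy
  u <- cos(angle) * x + sin(angle) * y
  v <- -sin(angle) * x + cos(angle) * y

  s <- 0.32 * min(H, W) * geom$scale_jit       # shape scale in pixels
  uu <- (u / s) - geom$off_u
  vv <- (v / s) - geom$off_v

  # A selects the shape family via a soft-edged membership field in [0, 1]
  soft <- function(q, edge = 2 / s) pmin(pmax((1 - q) / edge + 0.5, 0), 1)
  family <- (ai - 1) %% 4 + 1
  alpha <- switch(family,
    soft(sqrt(uu^2 + (vv / 0.6)^2)),                               # ellipse
    soft(pmax(abs(uu), abs(vv) / 0.3)),                            # bar
    pmin(1, soft(sqrt((uu - 0.55)^2 + vv^2) / 0.55) +
            soft(sqrt((uu + 0.55)^2 + vv^2) / 0.5)),               # twin blob
    {
      r <- sqrt(uu^2 + vv^2)                                       # ring
      soft(r) * (1 - soft(r / 0.55))
    })

  # interior texture: each shape family (A) has its own pattern style, so
  # the anatomical factor is carried by texture statistics as well as by
  # the outline; B selects the pattern pitch; all patterns are functions of
  # the rotated frame, so orientation still carries the D signal
  pitch <- c(5, 11)[(bi - 1) %% 2 + 1]
  tex <- 0.12 * switch(family,
    sin(2 * pi * v / pitch),                           # transverse stripes
    sin(2 * pi * u / pitch),                           # longitudinal stripes
    sin(2 * pi * u / pitch) * sin(2 * pi * v / pitch), # checkerboard
    {
      r_px <- sqrt(u^2 + v^2)                          # two-armed spiral
      sin(2 * pi * r_px / pitch + 2 * atan2(vv, uu))
    })

  # T selects the global regime: contrast level and a fine background weave
  # (amplitude well above the noise floor so the regime survives denoising)
  fg <- c(0.75, 0.55)[(ti - 1) %% 2 + 1]
  bg <- 0.15
  weave <- if (ti %% 2 == 0)
    0.14 * sin(2 * pi * u / 6) * sin(2 * pi * v / 6) else 0
  img <- bg + weave + alpha * (fg - bg + tex)

  if (config$vignette_strength > 0) {
    r2 <- (x^2 + y^2) / ((H^2 + W^2) / 4)
    img <- img * (1 - config$vignette_strength * r2)
  }
  if (config$noise_sigma > 0) {
    noise_seed <- derive_seed(seed, paste("noise", format(code)))
    img <- img + with_seed(noise_seed,
      matrix(stats::rnorm(H * W, 0, config$noise_sigma), H, W))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic annotated dataset
#'
#' Writes `n_images` PNG files plus a CSV label table (`image_id,irma_code,
#' split`). Codes cycle through the full cross-product of the axis
#' vocabularies, so class frequencies are balanced up to one image; the
#' train/test split is stratified by full code with at least one training
#' image per class.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `dir`, `labels` (the label table) and
#'   `label_path`.
#' @export
generate_dataset <- function(config = generator_config(), out_dir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory: %s", out_dir))
  combos <- expand.grid(t = config$t_vocab, d = config$d_vocab,
                        a = config$a_vocab, b = config$b_vocab,
                        stringsAsFactors = FALSE)
  codes_all <- paste(combos$t, combos$d, combos$a, combos$b, sep = "-")
  n <- config$n_images
  codes <- rep_len(codes_all, n)
  ord <- with_seed(derive_seed(config$seed, "assignment"), sample.int(n))
  codes <- codes[ord]

  ids <- sprintf("synthetic_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    img <- generate_image(codes[i], config,
                          seed = derive_seed(config$seed, paste("image", i)))
    write_image(img, file.path(out_dir, ids[i]))
  }

  # stratified split hitting the global train fraction exactly: every class
  # keeps at least one training image; test seats are allocated per class by
  # floor, the remainder going to the classes with the largest fractional
  # entitlement (ties broken by class enumeration order)
  split <- rep("train", n)
  split_seed <- derive_seed(config$seed, "split")
  classes <- codes_all[codes_all %in% codes]
  counts <- vapply(classes, function(cl) sum(codes == cl), integer(1))
  want <- (1 - config$train_fraction) * counts
  n_te <- pmin(floor(want), counts - 1L)
  left <- round((1 - config$train_fraction) * n) - sum(n_te)
  if (left > 0) {
    room <- counts - 1L - n_te
    ord <- order(-(want - floor(want)), seq_along(classes))
    for (ci in ord) {
      if (left == 0) break
      add <- min(room[ci], 1L, left)
      n_te[ci] <- n_te[ci] + add
      left <- left - add
    }
  }
  for (ci in seq_along(classes)) {
    if (n_te[ci] == 0) next
    idx <- which(codes == classes[ci])
    te <- with_seed(split_seed + match(classes[ci], codes_all),
                    sample(idx, n_te[ci]))
    split[te] <- "test"
  }
  labels <- data.frame(image_id = ids, irma_code = codes, split = split,
                       stringsAsFactors = FALSE)
  label_path <- file.path(out_dir, "labels.csv")
  write_label_table(labels, label_path)
  invisible(list(dir = out_dir, labels = labels, label_path = label_path))
}
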