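test_that("stacking keeps the channels in original/CLAHE/NLM order", {
  a <- matrix(0.2, 10, 12); b <- matrix(0.5, 10, 12); c3 <- matrix(0.8, 10, 12)
  lay <- stack_layers(a, b, c3)
  expect_equal(dim(lay), c(10, 12, 3))
  expect_identical(lay[, , 1], a)
  expect_identical(lay[, , 2], b)
  expect_identical(lay[, , 3], c3)
  expect_error(stack_layers(a, b, matrix(0.8, 11, 12)), "dimensions differ")
})

test_that("a constant input stays constant through the layered pipeline", {
  img <- matrix(0.4, 32, 32)
  lay <- stack_layers(img, apply_clahe(img), apply_nl_means(img))
  for (ch in 1:3) expect_equal(diff(range(lay[, , ch])), 0)
})

test_that("prepare_input implements the six modes", {
  img <- rand_img(64, 48, 701)
  expect_identical(prepare_input(img, "original"), img)
  expect_equal(prepare_input(img, "clahe"), apply_clahe(img))
  expect_equal(prepare_input(img, "nlmeans"), apply_nl_means(img))

  lay <- prepare_input(img, "layered")
  expect_equal(dim(lay), c(64, 48, 3))
  expect_identical(lay[, , 1], img)

  expect_equal(dim(prepare_input(img, "padded")), c(512, 512))
  pl <- prepare_input(img, "padded_layered")
  expect_equal(dim(pl), c(512, 512, 3))
  # pad first, then enhance: channel 1 is the padded image
  expect_identical(pl[, , 1], pad_with_repetition(img))

  expect_error(prepare_input(img, "sharpen"), "valid modes")
  expect_equal(length(input_modes()), 6)
  expect_equal(input_mode_labels(input_modes()),
               c("Image Padding", "Image Padding/Layered", "Image Layered",
                 "CLAHE Image", "NLMEANS Image", "Original Image"))
})

test_that("export writes one PNG per readable image and skips the rest", {
  dir <- tempfile("export")
  dir.create(dir)
  tab <- data.frame(image_id = sprintf("img%d.png", 1:3),
                    irma_code = rep("1121-127-732-500", 3))
  for (i in 1:2) write_image(rand_img(40 + i, 50, 702 + i),
                             file.path(dir, sprintf("img%d.png", i)))
  write_image(rand_img(40, 50, 705), file.path(dir, "img3.png"))

  out <- file.path(dir, "enhanced")
  man <- export_enhanced(tab, dir, "layered", out)
  expect_equal(attr(man, "n_written"), 3)
  for (i in 1:3) {
    arr <- png::readPNG(file.path(out, sprintf("img%d.png", i)))
    expect_equal(dim(arr)[3], 3)   # 24-bit RGB
  }

  # empty table
  man0 <- export_enhanced(tab[0, ], dir, "original", out)
  expect_equal(attr(man0, "n_written"), 0)
  expect_equal(nrow(man0), 0)

  # missing file is logged and skipped
  tab_bad <- data.frame(image_id = "missing.png", irma_code = "1121-127-732-500")
  expect_message(man_bad <- export_enhanced(tab_bad, dir, "original", out),
                 "skipping")
  expect_equal(attr(man_bad, "n_written"), 0)
  expect_equal(man_bad$status, "skipped")

  # padded_layered exports are square RGB
  man_pl <- export_enhanced(tab[1, , drop = FALSE], dir, "padded_layered", out)
  arr <- png::readPNG(file.path(out, "img1.png"))
  expect_equal(dim(arr), c(512, 512, 3))
})
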