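test_that("spatial histograms conserve counts in quadrant-major layout", {
  k <- 30
  frames <- data.frame(x = c(1, 2, 60, 61, 1, 2), y = c(0, 3, 2, 1, 50, 49))
  words <- c(1L, 5L, 5L, 30L, 2L, 2L)
  h <- spatial_histogram(frames, words, image_size = c(64, 64), k = k)
  expect_equal(length(h), 4 * k)
  expect_equal(sum(h), length(words))
  # top-left quadrant: words 1 and 5 once each
  expect_equal(h[1], 1); expect_equal(h[5], 1)
  # top-right: word 5 once, word 30 once
  expect_equal(h[k + 5], 1); expect_equal(h[k + 30], 1)
  # bottom-left: word 2 twice
  expect_equal(h[2 * k + 2], 2)
  expect_equal(sum(h[3 * k + 1:k]), 0)

  # permutation invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(spatial_histogram(frames[perm, ], words[perm], c(64, 64), k), h)

  # all frames in the top-left quadrant -> only the first k bins populated
  fr_tl <- data.frame(x = c(0, 3, 10), y = c(0, 7, 12))
  h_tl <- spatial_histogram(fr_tl, c(4L, 4L, 9L), c(64, 64), k)
  expect_equal(sum(h_tl[1:k]), 3)
  expect_equal(sum(h_tl[-(1:k)]), 0)

  # odd sizes put the extra pixel in the bottom/right cells
  h_odd <- spatial_histogram(data.frame(x = 2, y = 2), 1L, c(5, 5), k)
  expect_equal(which(h_odd > 0), 3 * k + 1)   # (2,2) 0-based is bottom-right

  expect_error(spatial_histogram(frames, rep(31L, 6), c(64, 64), 30), "exceeds")
  expect_error(spatial_histogram(data.frame(x = 70, y = 0), 1L, c(64, 64), 30),
               "outside")

  # L1 normalization
  hn <- spatial_histogram(frames, words, c(64, 64), k, normalize = TRUE)
  expect_equal(sum(hn), 1)
})

test_that("feature vectors have length 4k for gray and layered inputs", {
  set.seed(1200)
  book <- build_codebook(matrix(runif(200 * 128), 200, 128), k = 25, seed = 1)
  img <- rand_img(48, 48, 1201)
  f <- extract_bok_feature(img, book, bin_sizes = c(4, 6))
  expect_equal(length(f), 100)
  ds <- dense_sift(img, bin_sizes = c(4, 6))
  expect_equal(sum(f), sum(!ds$low_contrast))

  lay <- prepare_input(img, "layered")
  fl <- extract_bok_feature(lay, book, bin_sizes = c(4, 6))
  expect_equal(length(fl), 100)
})

test_that("the packed 8-bit pipeline agrees with the public operations", {
  set.seed(1202)
  cfg <- micro_config()
  img <- rand_img(70, 80, 1203)
  ex <- radannot:::extract_image_features(img, "original", cfg)
  book <- build_codebook(matrix(runif(300 * 128), 300, 128), k = 20, seed = 2)

  # unpack and quantize through the public path
  unpacked <- matrix(as.integer(ex$desc_raw) / 255, nrow = ex$n, ncol = 128,
                     byrow = TRUE)
  pub <- quantize(unpacked, book)$words
  packed <- radannot:::quantize_packed(ex, book)
  expect_equal(mean(packed == pub) > 0.999, TRUE)

  # packing quantizes descriptors to within half a step of 1/255
  ds <- dense_sift(img, step = cfg$step, bin_sizes = cfg$bin_sizes)
  keep <- !ds$low_contrast
  expect_lt(max(abs(unpacked - ds$descriptors[keep, , drop = FALSE])), 0.5 / 255 + 1e-12)
})
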