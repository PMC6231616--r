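test_that("a uniform image yields only zero, low-contrast descriptors", {
  ds <- dense_sift(matrix(0.7, 48, 48), bin_sizes = c(4, 6))
  expect_true(all(ds$low_contrast))
  expect_true(all(ds$descriptors == 0))
})

test_that("frame counts follow the closed-form grid formula", {
  for (case in list(list(h = 64, w = 64, step = 4, bins = c(4, 6, 8, 10)),
                    list(h = 50, w = 73, step = 4, bins = c(4, 8)),
                    list(h = 41, w = 99, step = 7, bins = c(5)))) {
    img <- rand_img(case$h, case$w, 800 + case$h)
    ds <- dense_sift(img, step = case$step, bin_sizes = case$bins)
    expected <- sum(vapply(case$bins, function(b) {
      s <- 4 * b
      floor((case$h - s) / case$step + 1) * floor((case$w - s) / case$step + 1)
    }, numeric(1)))
    expect_equal(nrow(ds$descriptors), expected)
    expect_equal(nrow(ds$frames), expected)
  }
})

test_that("descriptors are 128-dim, non-negative, clamped and unit-norm", {
  ds <- dense_sift(rand_img(60, 60, 801))
  expect_equal(ncol(ds$descriptors), 128)
  expect_true(all(ds$descriptors >= 0))
  ok <- !ds$low_contrast
  norms <- sqrt(rowSums(ds$descriptors[ok, , drop = FALSE]^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  # before renormalization entries are clamped at 0.2, so no entry can
  # exceed 0.2 / min attainable norm = 1
  expect_true(all(ds$descriptors <= 1 + 1e-12))
})

test_that("images smaller than the smallest support emit an empty set", {
  expect_warning(ds <- dense_sift(rand_img(10, 10, 802), bin_sizes = c(4)),
                 "smaller than")
  expect_equal(nrow(ds$descriptors), 0)
})

test_that("descriptor pooling is seeded, capped and excludes low contrast", {
  sets <- lapply(1:4, function(i) dense_sift(rand_img(40, 40, 810 + i),
                                             bin_sizes = c(4, 6)))
  total <- sum(vapply(sets, function(s) sum(!s$low_contrast), numeric(1)))

  # saturation: asking for more than available returns all
  pool <- sample_descriptors(sets, n = total + 1000, seed = 5)
  expect_equal(nrow(pool$descriptors), total)

  # determinism
  p1 <- sample_descriptors(sets, 100, seed = 9)
  p2 <- sample_descriptors(sets, 100, seed = 9)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$descriptors), 100)

  # sources drawn roughly proportionally to per-set descriptor counts
  counts <- vapply(sets, function(s) sum(!s$low_contrast), numeric(1))
  big <- sample_descriptors(sets, 2000, seed = 3)
  obs <- tabulate(big$source, nbins = 4)
  chi <- suppressWarnings(stats::chisq.test(obs, p = counts / sum(counts)))
  expect_gt(chi$p.value, 1e-4)

  # all-flagged input errors
  flat <- dense_sift(matrix(0.5, 32, 32), bin_sizes = c(4))
  expect_error(sample_descriptors(list(flat), 10, seed = 1), "low-contrast")
})
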