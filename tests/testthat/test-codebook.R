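test_that("a pool of exactly k distinct points is its own codebook", {
  set.seed(900)
  pool <- matrix(runif(6 * 16), 6, 16)
  book <- build_codebook(pool, k = 6, seed = 2)
  # centers equal the points, in some order
  reord <- brute_nn(book$centers, pool)
  expect_equal(sort(reord), 1:6)
  expect_equal(book$centers, pool[reord, ], ignore_attr = TRUE)
  expect_equal(utils::tail(book$objective, 1), 0)
  expect_error(build_codebook(pool, k = 7, seed = 1), "smaller than")
})

test_that("the Lloyd objective is non-increasing in exact mode", {
  set.seed(901)
  pool <- matrix(runif(400 * 24), 400, 24)
  book <- build_codebook(pool, k = 12, max_iter = 15, seed = 3)
  expect_true(all(diff(book$objective) <= 1e-9))
})

test_that("two well-separated blobs are recovered to 0.01", {
  set.seed(902)
  mu1 <- runif(32); mu2 <- mu1 + 1 / sqrt(32)   # unit distance apart
  pool <- rbind(
    matrix(rnorm(250 * 32, 0, 0.01), 250, 32) + matrix(mu1, 250, 32, byrow = TRUE),
    matrix(rnorm(250 * 32, 0, 0.01), 250, 32) + matrix(mu2, 250, 32, byrow = TRUE))
  book <- build_codebook(pool, k = 2, seed = 7)
  d <- rbind(sqrt(colSums((t(book$centers) - mu1)^2)),
             sqrt(colSums((t(book$centers) - mu2)^2)))
  # each true mean has a recovered center within 0.01
  expect_lt(max(apply(d, 1, min)), 0.01)
})

test_that("an unbounded ANN budget reproduces exact Lloyd", {
  set.seed(903)
  pool <- matrix(runif(300 * 16), 300, 16)
  exact <- build_codebook(pool, k = 9, seed = 5)
  ann <- build_codebook(pool, k = 9, seed = 5, max_comparisons = 1e9)
  expect_equal(ann$centers, exact$centers)
  expect_equal(ann$objective, exact$objective)
})

test_that("duplicated points force empty-cluster reseeding to distinct centers", {
  pool <- matrix(runif(3 * 8), 3, 8)[rep(1:3, each = 12), ]
  book <- build_codebook(pool, k = 3, seed = 11)
  expect_equal(utils::tail(book$objective, 1), 0)
  expect_equal(nrow(unique(book$centers)), 3)
})

test_that("quantization maps descriptors to their nearest center", {
  set.seed(904)
  centers <- matrix(runif(50 * 128), 50, 128)
  book <- structure(list(centers = centers, k = 50L, max_comparisons = Inf),
                    class = "bok_codebook")
  expect_equal(quantize(centers[7, , drop = FALSE], book)$words, 7L)

  x <- matrix(runif(500 * 128), 500, 128)
  ref <- as.integer(brute_nn(x, centers))
  expect_equal(quantize(x, book, engine = "kdtree")$words, ref)
  expect_equal(quantize(x, book, engine = "linear")$words, ref)

  # a finite budget still returns valid word ids
  approx <- quantize(x, book, max_comparisons = 10)$words
  expect_true(all(approx >= 1 & approx <= 50))

  expect_error(quantize(matrix(0.1, 2, 64), book), "dimension")
  empty <- dense_sift(matrix(0.5, 32, 32), bin_sizes = c(4))
  expect_equal(quantize(empty, book)$words, integer(0))
})

test_that("kd-tree exactness holds across random geometries", {
  set.seed(905)
  for (t in 1:5) {
    k <- sample(3:40, 1); d <- sample(c(2, 8, 32), 1)
    centers <- matrix(rnorm(k * d), k, d)
    book <- structure(list(centers = centers, k = k, max_comparisons = Inf),
                      class = "bok_codebook")
    x <- matrix(rnorm(200 * d), 200, d)
    expect_equal(quantize(x, book, engine = "kdtree")$words,
                 as.integer(brute_nn(x, centers)))
  }
})
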