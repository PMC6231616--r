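# Shared fixtures, generated in code and memoized for the session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, expr, envir = fixture_env)
  get(key, envir = fixture_env)
}

rand_img <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# a small, fast generator configuration: 8 classes, small canvases
micro_generator <- function(n = 40, seed = 7) {
  generator_config(n_images = n,
                   t_vocab = c("1121", "1124"),
                   d_vocab = c("127", "410"),
                   a_vocab = c("732", "620"),
                   b_vocab = "500",
                   height_range = c(64, 96), width_range = c(64, 96),
                   seed = seed)
}

micro_dataset <- function() {
  memo("micro_dataset", {
    dir <- file.path(tempdir(), "radannot-micro")
    res <- generate_dataset(micro_generator(), dir)
    res
  })
}

micro_config <- function(schemes = c("T", "IRMA"), ...) {
  run_config(k = 20, n_trees = 50, pca_dim = 20, bin_sizes = c(4, 6),
             pool_cap = 400, modes = "original", schemes = schemes,
             seed = 11, ...)
}
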