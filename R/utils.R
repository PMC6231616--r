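#' @useDynLib radannot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific random seed
#'
#' Hashes a master seed together with a stage label (32-bit FNV-1a) so that a
#' single user-supplied seed fans out into independent, reproducible seeds for
#' every stochastic stage (dataset generation, descriptor pooling, codebook
#' initialization, forest training, ...).
#'
#' @param seed Integer master seed.
#' @param stage Character label of the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "codebook")
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(stage),
            length(stage) == 1)
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), ":", stage))
  h <- 2166136261
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor2_(h, b)
    # exact (h * 16777619) mod 2^32 without losing double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% two32
  }
  as.integer(h %% 2147483645 + 1)
}

# xor for non-negative doubles < 2^32 (bitwXor is limited to 32-bit ints)
bitwXor2_ <- function(a, b) {
  hi_a <- a %/% 2147483648
  hi_b <- b %/% 2147483648
  lo <- bitwXor(as.integer(a %% 2147483648), as.integer(b %% 2147483648))
  (as.numeric(hi_a != hi_b)) * 2147483648 + lo
}

# short stable hash of an R object (used for config fingerprints in reports)
object_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  two32 <- 4294967296
  for (b in as.integer(raw)) {
    h <- bitwXor2_(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
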