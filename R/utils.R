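#' Derive a reproducible sub-seed from a master seed
#'
#' All randomized stages of the package fan out from one master seed via this
#' deterministic integer hash, so a whole cohort simulation is reproducible
#' from a single number. Indices identify the consumer (e.g. subject, run).
#'
#' @param seed master seed (integer).
#' @param ... further non-negative integer indices (subject, run, replicate,
#'   ...) distinguishing the consumer.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Fisher z transform of a correlation
#'
#' Correlations are clipped away from +/-1 before `atanh` so the score stays
#' finite, the convention used for decoding performance throughout.
#'
#' @param r Pearson correlation(s).
#' @param clip largest absolute correlation retained before transforming.
#' @return `atanh` of the clipped correlation.
#' @export
fisher_z <- function(r, clip = 1 - 1e-15) {
  atanh(pmin(pmax(r, -clip), clip))
}

# strict upper triangle of a square matrix, column-major order (45 values
# for the 10-condition design)
ut_vec <- function(m) m[upper.tri(m)]

# z-score a vector; error on zero variance unless allowed
zscore <- function(x, what = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a zero-variance ", what)
  }
  (x - mean(x)) / s
}

# run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
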