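#' @useDynLib smdfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd quantile prcomp hclust cutree dist as.dendrogram
#' @importFrom stats rnorm rlnorm rbinom median predict
#' @importFrom utils read.csv write.csv head
NULL

# run expr under a temporary R RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific child seed from a master seed
#'
#' Stochastic pipeline stages (data generation, each forest fit, the
#' shadow-variable refit) consume distinct child seeds derived
#' deterministically from one master seed, so any stage can be re-run in
#' isolation and reproduce its part of a pipeline run.  The map is a
#' Lehmer step modulo the Mersenne prime 2^31 - 1, offset by a small
#' per-stage index.
#'
#' @param seed master seed, a single integer.
#' @param stage stage index (non-negative integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) + 1
  x <- (x * 48271) %% m
  as.integer(((x + stage * 7919) %% (m - 1)) + 1)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
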