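#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm runif sd setNames predict t.test wilcox.test ks.test
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer mixing so that independent stages (fold shuffling per
#' repeat, per-dataset generation, triplet sampling) each get their own stream
#' while remaining reconstructible from one master seed. Results stay within
#' the 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param seed master seed (integer).
#' @param index stage index (integer, >= 0); distinct indices give distinct
#'   sub-seeds for any fixed master seed.
#' @return a single integer usable with `set.seed()`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index), length(index) == 1)
  # multiplicative hash mod a Mersenne prime keeps everything < 2^31
  m <- 2147483647
  x <- (as.double(seed) %% m) * 48271 + as.double(index) * 16807 + 1
  as.integer(x %% m)
}

# evaluate expr with a temporary RNG state seeded at `seed`; restores the
# caller's RNG so library calls do not perturb user simulations
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
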