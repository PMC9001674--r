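#' @keywords internal
"_PACKAGE"

## Quantile convention used throughout the package: linear interpolation
## between order statistics (stats::quantile type 7, the R default).
interp_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

#' Derive reproducible child seeds from a master seed
#'
#' Fans a single master seed out into `n` independent child seeds so that
#' each repetition of a stochastic procedure (e.g. one cross-validation of
#' the heterogeneity statistic) can be reproduced in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds required.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
fan_out_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 0)
  if (n == 0L) return(integer(0))
  ## counter-based splitting: a fixed multiplicative hash of (seed, counter),
  ## kept inside the 32-bit integer range
  m <- as.double(master_seed) %% 2147483647
  vapply(seq_len(n), function(i) {
    h <- (m * 48271 + i * 16807) %% 2147483629
    as.integer(h + 1)
  }, integer(1))
}

with_seed <- function(seed, code) {
  force(seed)  # evaluate caller-side RNG draws before snapshotting the state
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop("non-finite value in field '", name, "'", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
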