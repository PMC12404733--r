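#' Wilson score confidence interval for a binomial proportion
#'
#' Preferred over the Wald interval for proportions near 0 or 1, where Wald
#' intervals collapse or escape \[0, 1\].
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials (vectorized, `n >= 0`).
#' @param conf Confidence level, default 0.95.
#' @return A two-column matrix with columns `lo` and `hi`; rows with `n == 0`
#'   are `NA`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(length(x) == length(n), all(x >= 0 | is.na(x)), all(n >= 0 | is.na(n)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  lo <- pmax(0, centre - half)
  hi <- pmin(1, centre + half)
  # exact bounds at the boundaries (centre - half is 0 or 1 analytically at
  # x = 0 / x = n; avoid floating-point residue excluding the true value)
  lo[x == 0] <- 0
  hi[x == n] <- 1
  out <- cbind(lo = lo, hi = hi)
  out[is.na(n) | n == 0, ] <- NA_real_
  out
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @noRd
comp_base <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(unname(comp_base[ch])), collapse = ""), "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic local RNG scope: evaluates expr with the given seed, then
# restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a stream-specific child seed below 2^31
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1337) %% 2147483587
}
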