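#' Median-of-ratios size factors
#'
#' Per-library normalization constants: each library's factor is the median,
#' over units whose geometric mean across libraries is positive, of the ratio
#' of its count to that geometric mean.
#'
#' @param counts Unit x sample count matrix (fractional counts allowed).
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2, all(counts >= 0))
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    stop("no unit has positive counts in every replicate; ",
         "consider adding a pseudocount before normalization")
  }
  apply(counts[use, , drop = FALSE], 2L, function(cnt) {
    stats::median(exp(log(cnt) - log_gm[use]))
  })
}

#' Method-of-moments negative-binomial dispersion with trend shrinkage
#'
#' Per-unit dispersion alpha is estimated from within-condition variance of
#' size-factor-normalized counts (`alpha = max(0, (s^2 - m * c0) / m^2)` with
#' `c0 = mean(1/sf)` absorbing the Poisson part), then shrunk toward a fitted
#' mean-dispersion trend `a0 + a1/mean` by weight `shrink`. With fewer than
#' two replicates in every condition all units fall back to the prior.
#'
#' @param counts Unit x sample count matrix.
#' @param factors Size factors (default: [size_factors()]).
#' @param condition Character/factor per sample; variance is pooled within
#'   condition. Default: one condition.
#' @param shrink Shrinkage weight toward the trend (default 0.5).
#' @param prior Fallback dispersion when no trend can be fitted (default 0.1).
#' @return Named numeric vector of per-unit dispersions.
#' @export
estimate_dispersion <- function(counts, factors = size_factors(counts),
                                condition = NULL, shrink = 0.5, prior = 0.1) {
  counts <- as.matrix(counts)
  if (is.null(condition)) condition <- rep("all", ncol(counts))
  stopifnot(length(condition) == ncol(counts), shrink >= 0, shrink <= 1)
  x <- sweep(counts, 2L, factors, "/")
  conds <- split(seq_len(ncol(x)), condition)
  if (all(lengths(conds) < 2L)) {
    return(stats::setNames(rep(prior, nrow(x)), rownames(x)))
  }
  conds <- conds[lengths(conds) >= 2L]
  num <- 0; den <- 0
  for (jj in conds) {
    m <- rowMeans(x[, jj, drop = FALSE])
    v <- apply(x[, jj, drop = FALSE], 1L, stats::var)
    c0 <- mean(1 / factors[jj])
    raw <- ifelse(m > 0, (v - m * c0) / m^2, NA_real_)
    w <- length(jj) - 1L
    num <- num + w * ifelse(is.na(raw), 0, raw)
    den <- den + w * !is.na(raw)
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  mn <- rowMeans(x)
  fitok <- !is.na(raw) & mn > 0
  trend <- rep(prior, nrow(x))
  if (sum(fitok) >= 10) {
    fit <- stats::lm(raw[fitok] ~ I(1 / mn[fitok]))
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0  # singular fit (e.g. constant means): intercept only
    trend <- pmax(1e-8, cf[1] + cf[2] / mn)
  }
  alpha <- (1 - shrink) * pmax(0, ifelse(is.na(raw), trend, raw)) + shrink * trend
  stats::setNames(pmax(0, alpha), rownames(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Wald test for differential tRNA abundance
#'
#' Normalizes counts by median-of-ratios size factors, estimates
#' negative-binomial dispersion per unit, and tests the case-vs-control log2
#' fold change with a Wald statistic whose variance follows the NB
#' mean-variance relation. P-values are two-sided and BH-adjusted across
#' tested units; units with zero counts everywhere are excluded and listed in
#' the `dropped` attribute. Fractional counts (from tied assignments) are
#' kept exact for normalization and rounded to the nearest integer for
#' testing.
#'
#' @param counts Unit x sample count matrix (isodecoder level).
#' @param condition Character/factor per sample with levels `control` and
#'   `case` (or any two levels; the first is the baseline).
#' @param level `"isodecoder"` (default) or `"anticodon"`; the latter sums
#'   member counts per family before testing and requires `ref`.
#' @param ref A `trna_reference` (needed for `level = "anticodon"` and the
#'   ADAT-target flag).
#' @param shrink Dispersion shrinkage weight (see [estimate_dispersion()]).
#' @param sig Adjusted-p significance threshold for the `direction` call
#'   (default 0.05).
#' @return Data frame of class `differential_result`: `unit`, `baseMean`,
#'   `log2FC`, `SE`, `stat`, `p`, `padj`, `direction`, and `is_adat_target`
#'   when `ref` is given.
#' @export
test_differential <- function(counts, condition, level = c("isodecoder", "anticodon"),
                              ref = NULL, shrink = 0.5, sig = 0.05) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(counts))
  lv <- unique(condition)
  if (length(lv) != 2L) stop("a two-condition design is required")
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))
  if (any(table(condition) < 2L)) stop("need at least 2 replicates per condition")

  if (level == "anticodon") {
    if (is.null(ref)) stop("ref is required for anticodon-level testing")
    fam <- ref$records$family[match(rownames(counts), ref$records$id)]
    if (anyNA(fam)) stop("count rows not in reference: ",
                         paste(rownames(counts)[is.na(fam)], collapse = ", "))
    counts <- rowsum(counts, fam)
  }

  sf <- size_factors(counts)
  all_zero <- rowSums(counts) == 0
  dropped <- rownames(counts)[all_zero]
  m <- counts[!all_zero, , drop = FALSE]
  alpha <- estimate_dispersion(m, sf, condition, shrink = shrink)
  mi <- round(m)  # NB model wants integers; normalization used exact values
  x <- sweep(mi, 2L, sf, "/")
  j1 <- which(condition == lv[1]); j2 <- which(condition == lv[2])
  q1 <- rowMeans(x[, j1, drop = FALSE]); q2 <- rowMeans(x[, j2, drop = FALSE])
  ps <- ifelse(q1 == 0 | q2 == 0, 0.5, 0)  # pseudocount only for zero cells
  q1p <- q1 + ps; q2p <- q2 + ps
  c1 <- mean(1 / sf[j1]); c2 <- mean(1 / sf[j2])
  v1 <- (q1p * c1 + alpha * q1p^2) / length(j1)
  v2 <- (q2p * c2 + alpha * q2p^2) / length(j2)
  log2fc <- log2(q2p / q1p)
  se <- sqrt(v1 / q1p^2 + v2 / q2p^2) / log(2)
  stat <- log2fc / se
  # moderated-t reference: shrinking the dispersion toward the trend by
  # weight w scales down the variance of the variance estimate, inflating
  # the effective residual degrees of freedom by ~1/(1-w)
  df_eff <- if (shrink < 1) (length(j1) + length(j2) - 2L) / (1 - shrink) else Inf
  p <- 2 * stats::pt(-abs(stat), df = df_eff)
  padj <- bh_adjust(p)
  out <- data.frame(
    unit = rownames(m),
    baseMean = rowMeans(x),
    log2FC = log2fc,
    SE = se,
    stat = stat,
    p = p,
    padj = padj,
    direction = ifelse(padj < sig, ifelse(log2fc > 0, "up", "down"), "unchanged"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(ref)) {
    adat_fams <- ref$families$family[ref$families$is_adat_target]
    key <- if (level == "anticodon") out$unit else
      ref$records$family[match(out$unit, ref$records$id)]
    out$is_adat_target <- key %in% adat_fams
  }
  attr(out, "dropped") <- dropped
  attr(out, "conditions") <- lv
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Write differential results and a volcano-ready table
#'
#' @param result A `differential_result`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_differential <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "differential_results.tsv")
  utils::write.table(result, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  volcano <- data.frame(unit = result$unit, log2FC = result$log2FC,
                        neg_log10_padj = -log10(result$padj),
                        is_adat_target = result$is_adat_target %||% NA,
                        direction = result$direction, stringsAsFactors = FALSE)
  p2 <- file.path(dir, "volcano.tsv")
  utils::write.table(volcano, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
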