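#' Call I34 stoichiometry per isodecoder
#'
#' Because reverse transcriptase reads inosine as G, the fraction of G among
#' G+A reads at the wobble index of an ANN isodecoder estimates the I34
#' stoichiometry. C and T calls at the site are treated as sequencing error
#' and excluded from the denominator. A Wilson 95% confidence interval
#' accompanies each estimate; units with fewer than `min_coverage` informative
#' reads are flagged `low_coverage` and report no estimate.
#'
#' @param pileup Pooled pileup data frame (from [pool_pileups()]).
#' @param ref A `trna_reference`.
#' @param min_coverage Minimum G+A reads at the site (default 20).
#' @param units Optional subset of isodecoder ids; requesting a non-ANN unit
#'   is an error.
#' @return Data frame of class `mod_call`: `unit`, `family`, `g`, `a`,
#'   `coverage`, `theta`, `ci_lo`, `ci_hi`, `status`.
#' @export
call_i34 <- function(pileup, ref, min_coverage = 20, units = NULL) {
  stopifnot(inherits(ref, "trna_reference"))
  adat_fams <- ref$families$family[ref$families$is_adat_target]
  rec <- ref$records[ref$records$family %in% adat_fams &
                       ref$records$genome == "nuclear", , drop = FALSE]
  if (!is.null(units)) {
    bad <- setdiff(units, rec$id)
    if (length(bad)) {
      stop("not an ANN (ADAT-target) isodecoder: ", paste(bad, collapse = ", "))
    }
    rec <- rec[match(units, rec$id), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    wi <- rec$anticodon_start[i]
    hit <- pileup$id == rec$id[i] & pileup$pos == wi
    g <- if (any(hit)) sum(pileup$G[hit]) else 0
    a <- if (any(hit)) sum(pileup$A[hit]) else 0
    data.frame(unit = rec$id[i], family = rec$family[i], g = g, a = a,
               coverage = g + a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$theta <- ifelse(out$coverage >= min_coverage, out$g / out$coverage, NA_real_)
  ci <- wilson_ci(out$g, out$coverage)
  out$ci_lo <- ifelse(is.na(out$theta), NA_real_, ci[, "lo"])
  out$ci_hi <- ifelse(is.na(out$theta), NA_real_, ci[, "hi"])
  out$status <- ifelse(is.na(out$theta), "low_coverage", "called")
  class(out) <- c("mod_call", "data.frame")
  out
}

#' Aggregate I34 calls to anticodon pools
#'
#' Pool stoichiometry is the coverage-weighted mean of member stoichiometries,
#' identical to calling on the summed G and A counts; the confidence interval
#' comes from the pooled binomial counts.
#'
#' @param calls A `mod_call` data frame from [call_i34()].
#' @param min_coverage Minimum pooled coverage (default 20).
#' @return Data frame of class `mod_call` with one row per anticodon family.
#' @export
aggregate_anticodon <- function(calls, min_coverage = 20) {
  stopifnot(all(c("family", "g", "a") %in% names(calls)))
  called <- calls[calls$status == "called", , drop = FALSE]
  fams <- unique(calls$family)
  rows <- lapply(fams, function(f) {
    m <- called[called$family == f, , drop = FALSE]
    data.frame(unit = f, family = f, g = sum(m$g), a = sum(m$a),
               coverage = sum(m$coverage), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$theta <- ifelse(out$coverage >= min_coverage, out$g / out$coverage, NA_real_)
  ci <- wilson_ci(out$g, out$coverage)
  out$ci_lo <- ifelse(is.na(out$theta), NA_real_, ci[, "lo"])
  out$ci_hi <- ifelse(is.na(out$theta), NA_real_, ci[, "hi"])
  out$status <- ifelse(is.na(out$theta), "low_coverage", "called")
  class(out) <- c("mod_call", "data.frame")
  out
}

#' Misincorporation and truncation profile at non-I34 modification sites
#'
#' For every annotated modification site other than the wobble position,
#' reports the proportion of reads with a non-reference base call and the
#' proportion of truncation starts immediately 3' of the site.
#'
#' @param pileup Pooled pileup data frame.
#' @param ref A `trna_reference`.
#' @return Data frame: `unit`, `family`, `pos`, `label`, `coverage`,
#'   `misincorporation`, `truncation`.
#' @export
mod_profile <- function(pileup, ref) {
  stopifnot(inherits(ref, "trna_reference"))
  rec <- ref$records
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    ms <- rec$mod_sites[[i]]
    if (!nrow(ms)) next
    for (j in seq_len(nrow(ms))) {
      p0 <- ms$pos[j]
      if (p0 == rec$anticodon_start[i]) next
      hit <- pileup$id == rec$id[i] & pileup$pos == p0
      cov <- sum(pileup[hit, c("A", "C", "G", "T")])
      refbase <- substr(rec$sequence[i], p0 + 1L, p0 + 1L)
      mis <- if (cov > 0) (cov - sum(pileup[hit, refbase])) / cov else NA_real_
      dn <- pileup$id == rec$id[i] & pileup$pos == p0 + 1L
      trunc <- if (cov > 0) sum(pileup$trunc[dn]) / (cov + sum(pileup$trunc[dn])) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        unit = rec$id[i], family = rec$family[i], pos = p0, label = ms$label[j],
        coverage = cov, misincorporation = mis, truncation = trunc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Case-control change in modification stoichiometry
#'
#' Reports, per unit, the change in stoichiometry in percentage points
#' (case minus control) and the log2 ratio used by the coupling analysis.
#' Units with `low_coverage` on either side are excluded and listed in the
#' `excluded` attribute.
#'
#' @param case_calls,control_calls `mod_call` data frames with matching units.
#' @return Data frame: `unit`, `family`, `theta_case`, `theta_control`,
#'   `delta_pp` (percentage points), `log2_ratio`.
#' @export
delta_mod <- function(case_calls, control_calls) {
  common <- intersect(case_calls$unit, control_calls$unit)
  if (!length(common)) stop("no shared units between case and control calls")
  ca <- case_calls[match(common, case_calls$unit), ]
  co <- control_calls[match(common, control_calls$unit), ]
  ok <- ca$status == "called" & co$status == "called"
  out <- data.frame(
    unit = common[ok],
    family = ca$family[ok],
    theta_case = ca$theta[ok],
    theta_control = co$theta[ok],
    stringsAsFactors = FALSE
  )
  out$delta_pp <- 100 * (out$theta_case - out$theta_control)
  out$log2_ratio <- log2(pmax(out$theta_case, 1e-6) / pmax(out$theta_control, 1e-6))
  attr(out, "excluded") <- common[!ok]
  out
}

#' Quantify in vitro deamination curves from base counts
#'
#' Sequencing of an in vitro-transcribed cognate tRNA after incubation with
#' increasing amounts of deaminase complex yields G and A counts at the wobble
#' position; the editing fraction G/(G+A) per concentration traces the
#' enzyme's deamination curve. Relative activity compares each enzyme with a
#' reference enzyme at matched concentration.
#'
#' @param base_counts Data frame (or TSV path) with columns `enzyme`,
#'   `concentration`, `G`, `A`.
#' @param reference Reference enzyme label (default `"WT"`).
#' @return Data frame: `enzyme`, `concentration`, `fraction`,
#'   `relative_activity` (fraction over the reference's at the same
#'   concentration), `percent_change` (100 * (ratio - 1)). Rows with
#'   G + A = 0 are flagged `excluded` and carry no estimates.
#' @export
deamination_curve <- function(base_counts, reference = "WT") {
  if (is.character(base_counts)) {
    base_counts <- utils::read.delim(base_counts, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("enzyme", "concentration", "G", "A") %in% names(base_counts)))
  if (!reference %in% base_counts$enzyme) {
    stop("reference enzyme ", reference, " not present")
  }
  out <- base_counts
  tot <- out$G + out$A
  out$excluded <- tot == 0
  out$fraction <- ifelse(out$excluded, NA_real_, out$G / tot)
  ref_rows <- out[out$enzyme == reference & !out$excluded, ]
  ref_frac <- stats::setNames(ref_rows$fraction, format(ref_rows$concentration))
  key <- format(out$concentration)
  out$relative_activity <- out$fraction / unname(ref_frac[key])
  out$percent_change <- 100 * (out$relative_activity - 1)
  out
}

#' Write modification calls to TSV
#'
#' @param calls A `mod_call` data frame.
#' @param path Output TSV path.
#' @export
write_mod_calls <- function(calls, path) {
  utils::write.table(calls[, c("unit", "coverage", "theta", "ci_lo", "ci_hi", "status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
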