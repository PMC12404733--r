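#' Assign tRNA-seq reads to isodecoders with modification-aware scoring
#'
#' Each read is aligned to every candidate isodecoder with the 3' ends
#' anchored (tRNA-seq reads run from the 3' CCA toward the 5' end, so a
#' truncated read is a 3'-suffix of its transcript); the read's 5' side is
#' free. Mismatches at annotated modification sites — including the wobble
#' index of ANN families, where inosine is read as G — cost nothing when
#' `mod_site_free` is set, so modification signatures never penalize the true
#' origin. The best-scoring isodecoder wins; ties within one anticodon family
#' are split as equal fractional weights; ties across families are dropped as
#' `ambiguous_cross_family`; reads whose best score exceeds `max_mismatch`
#' non-exempt mismatches are `unassigned`. Reads that only align with a
#' single indel (`rescue_indel`) are counted but excluded from pileups.
#'
#' @param fastq Character vector of FASTQ paths (optionally gzipped); names
#'   are used as sample names (default: file base names).
#' @param ref A `trna_reference`.
#' @param max_mismatch Maximum tolerated non-exempt mismatches (default 3).
#' @param mod_site_free Zero-cost mismatches at modification sites and at the
#'   ANN wobble index (default `TRUE`).
#' @param rescue_indel Attempt a one-indel alignment (gap cost 1) for reads
#'   failing the ungapped pass (default `TRUE`).
#' @return An object of class `trna_assignment` with elements `counts`
#'   (isodecoder x sample, fractional), `anticodon_counts`, `pileups`
#'   (long data frame: sample, id, pos, A, C, G, T, trunc), `read_summary`
#'   (per-sample outcome tallies and QC tallies) and `params`.
#' @export
assign_reads <- function(fastq, ref, max_mismatch = 3, mod_site_free = TRUE,
                         rescue_indel = TRUE) {
  stopifnot(inherits(ref, "trna_reference"), max_mismatch >= 0)
  if (nrow(ref$records) == 0L) stop("empty reference")
  if (is.null(names(fastq))) {
    names(fastq) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  }
  missing_files <- fastq[!file.exists(fastq)]
  if (length(missing_files)) stop("FASTQ file not found: ", paste(missing_files, collapse = ", "))

  idx <- .ref_index(ref, mod_site_free)
  per_sample <- lapply(names(fastq), function(s) {
    .assign_one_sample(fastq[[s]], s, idx, max_mismatch, rescue_indel)
  })
  names(per_sample) <- names(fastq)

  ids <- ref$records$id
  counts <- vapply(per_sample, function(x) x$counts[ids], numeric(length(ids)))
  counts <- matrix(counts, nrow = length(ids),
                   dimnames = list(ids, names(fastq)))
  fam <- ref$records$family
  anticodon_counts <- rowsum(counts, fam)
  pileups <- do.call(rbind, lapply(per_sample, `[[`, "pileup"))
  rownames(pileups) <- NULL
  read_summary <- do.call(rbind, lapply(per_sample, `[[`, "summary"))
  rownames(read_summary) <- NULL
  structure(list(counts = counts, anticodon_counts = anticodon_counts,
                 pileups = pileups, read_summary = read_summary,
                 params = list(max_mismatch = max_mismatch,
                               mod_site_free = mod_site_free,
                               rescue_indel = rescue_indel)),
            class = "trna_assignment")
}

#' @export
print.trna_assignment <- function(x, ...) {
  cat("trna_assignment:", nrow(x$counts), "isodecoders x", ncol(x$counts),
      "sample(s);", sum(x$read_summary$total), "reads\n")
  invisible(x)
}

# precomputed per-reference structures for the aligner
.ref_index <- function(ref, mod_site_free) {
  rec <- ref$records
  adat_fams <- ref$families$family[ref$families$is_adat_target]
  chars <- strsplit(rec$sequence, "")
  exempt <- lapply(seq_len(nrow(rec)), function(i) {
    if (!mod_site_free) return(integer(0))
    e <- rec$mod_sites[[i]]$pos
    if (rec$family[i] %in% adat_fams && rec$genome[i] == "nuclear") {
      e <- c(e, rec$anticodon_start[i])
    }
    sort(unique(e)) + 1L  # 1-based
  })
  list(id = rec$id, family = rec$family, nuclear = rec$genome == "nuclear",
       len = nchar(rec$sequence), chars = chars, exempt = exempt)
}

.read_fastq_seqs <- function(path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                   error = function(e) stop("unreadable FASTQ ", path, ": ",
                                            conditionMessage(e)))
  toupper(as.character(seqs))
}

.assign_one_sample <- function(path, sample, idx, max_mismatch, rescue_indel) {
  reads <- .read_fastq_seqs(path)
  K <- length(idx$id)
  u <- unique(unname(reads))
  mult <- tabulate(match(reads, u), length(u))
  n_u <- length(u)
  ulen <- nchar(u)

  score <- matrix(Inf, n_u, K)
  for (m in sort(unique(ulen))) {
    rows <- which(ulen == m)
    M <- matrix(unlist(strsplit(u[rows], ""), use.names = FALSE),
                nrow = length(rows), byrow = TRUE)
    for (k in seq_len(K)) {
      Lk <- idx$len[k]
      if (m > Lk) next
      cols <- (Lk - m + 1L):Lk
      keep <- !(cols %in% idx$exempt[[k]])
      if (!any(keep)) { score[rows, k] <- 0; next }
      srow <- idx$chars[[k]][cols[keep]]
      score[rows, k] <- rowSums(M[, keep, drop = FALSE] !=
                                  matrix(srow, length(rows), sum(keep), byrow = TRUE))
    }
  }

  best <- apply(score, 1L, min)
  indel_assigned <- rep(FALSE, n_u)
  if (rescue_indel) {
    for (r in which(best > max_mismatch)) {
      s1 <- vapply(seq_len(K), function(k) {
        .one_indel_score(strsplit(u[r], "")[[1]], idx$chars[[k]], idx$exempt[[k]])
      }, 0)
      if (min(s1) <= max_mismatch && min(s1) < best[r]) {
        score[r, ] <- s1
        best[r] <- min(s1)
        indel_assigned[r] <- TRUE
      }
    }
  }

  winners <- lapply(seq_len(n_u), function(r) which(score[r, ] == best[r]))
  n_win <- lengths(winners)
  unassigned <- best > max_mismatch
  same_family <- vapply(winners, function(w) length(unique(idx$family[w])) == 1L, TRUE)
  outcome <- ifelse(unassigned, "unassigned",
                    ifelse(!same_family, "ambiguous_cross_family",
                           ifelse(n_win == 1L, "unique", "fractional")))
  assigned <- outcome %in% c("unique", "fractional")

  counts <- stats::setNames(numeric(K), idx$id)
  pile_rows <- vector("list", n_u)
  full_length <- rep(FALSE, n_u)
  nuclear <- rep(NA, n_u)
  for (r in which(assigned)) {
    w <- winners[[r]]
    wt <- mult[r] / length(w)
    counts[w] <- counts[w] + wt
    full_length[r] <- any(ulen[r] == idx$len[w] + (if (indel_assigned[r]) -1L else 0L))
    nuclear[r] <- idx$nuclear[w[1]]
    if (!indel_assigned[r]) {
      rchars <- strsplit(u[r], "")[[1]]
      pile_rows[[r]] <- do.call(rbind, lapply(w, function(k) {
        start0 <- idx$len[k] - ulen[r]  # 0-based start on the reference
        cbind(k = k, pos = start0 + seq_len(ulen[r]) - 1L,
              base = match(rchars, c("A", "C", "G", "T")),
              wt = wt, trunc_at = c(start0, rep(NA, ulen[r] - 1L)))
      }))
    }
  }

  pileup <- .aggregate_pileup(pile_rows, idx, sample)
  has_cca <- endsWith(u, "CCA")
  asg_reads <- sum(mult[assigned])
  fl_reads <- sum(mult[assigned & full_length])
  summary <- data.frame(
    sample = sample,
    total = sum(mult),
    unique = sum(mult[outcome == "unique"]),
    fractional = sum(mult[outcome == "fractional"]),
    ambiguous_cross_family = sum(mult[outcome == "ambiguous_cross_family"]),
    unassigned = sum(mult[outcome == "unassigned"]),
    assigned_nuclear = sum(mult[assigned & nuclear %in% TRUE]),
    full_length = fl_reads,
    full_length_cca = sum(mult[assigned & full_length & has_cca]),
    indel_rescued = sum(mult[assigned & indel_assigned]),
    stringsAsFactors = FALSE
  )
  stopifnot(summary$unique + summary$fractional + summary$ambiguous_cross_family +
              summary$unassigned == summary$total)
  list(counts = counts, pileup = pileup, summary = summary)
}

.aggregate_pileup <- function(pile_rows, idx, sample) {
  pile_rows <- pile_rows[!vapply(pile_rows, is.null, TRUE)]
  maxL <- max(idx$len)
  grid <- do.call(rbind, lapply(seq_along(idx$id), function(k) {
    data.frame(sample = sample, id = idx$id[k], pos = seq_len(idx$len[k]) - 1L,
               A = 0, C = 0, G = 0, T = 0, trunc = 0, stringsAsFactors = FALSE)
  }))
  if (!length(pile_rows)) return(grid)
  long <- do.call(rbind, pile_rows)
  key <- (long[, "k"] - 1L) * maxL + long[, "pos"]
  for (b in 1:4) {
    sel <- long[, "base"] == b
    if (!any(sel)) next
    agg <- rowsum(long[sel, "wt"], key[sel])
    kk <- as.integer(rownames(agg))
    grid[[c("A", "C", "G", "T")[b]]][match(kk, (match(grid$id, idx$id) - 1L) * maxL + grid$pos)] <- agg[, 1]
  }
  tr <- !is.na(long[, "trunc_at"])
  if (any(tr)) {
    keyt <- (long[tr, "k"] - 1L) * maxL + long[tr, "trunc_at"]
    agg <- rowsum(long[tr, "wt"], keyt)
    kk <- as.integer(rownames(agg))
    grid$trunc[match(kk, (match(grid$id, idx$id) - 1L) * maxL + grid$pos)] <- agg[, 1]
  }
  grid
}

# best alignment score allowing exactly one indel (gap cost 1), 3'-anchored
.one_indel_score <- function(rchars, ref_chars, exempt) {
  m <- length(rchars)
  Lk <- length(ref_chars)
  best <- Inf
  nonex <- function(cols) cols[!(cols %in% exempt)]
  # deletion in read: read covers a ref suffix of length m+1, one ref base skipped
  if (m + 1L <= Lk) {
    cols <- (Lk - m):Lk
    for (j in seq_len(m + 1L)) {
      ref_cols <- cols[-j]
      keep <- !(ref_cols %in% exempt)
      mm <- sum(rchars[keep] != ref_chars[ref_cols][keep]) + 1L
      best <- min(best, mm)
    }
  }
  # insertion in read: read covers a ref suffix of length m-1, one read base skipped
  if (m - 1L >= 1L && m - 1L <= Lk) {
    cols <- (Lk - m + 2L):Lk
    for (j in seq_len(m)) {
      rsub <- rchars[-j]
      keep <- !(cols %in% exempt)
      mm <- sum(rsub[keep] != ref_chars[cols][keep]) + 1L
      best <- min(best, mm)
    }
  }
  best
}

#' Quality-control metrics of a read assignment
#'
#' Reports, per sample and overall: the fraction of reads uniquely assigned,
#' the fraction of assigned reads mapping to nuclear-encoded tRNAs, the
#' fraction of assigned reads that are full length (reaching position 0 of
#' their reference), and the fraction of full-length reads carrying the
#' terminal 3' CCA — the mark of mature, translationally competent tRNAs.
#'
#' @param assignment A `trna_assignment`.
#' @return Data frame with columns `sample`, `unique_fraction`,
#'   `nuclear_mapped_fraction`, `full_length_fraction`, `cca_fraction`.
#' @export
qc_metrics <- function(assignment) {
  stopifnot(inherits(assignment, "trna_assignment"))
  rs <- assignment$read_summary
  tot <- rbind(rs, within(rs[1, ], sample <- "all"))
  tot[nrow(tot), -1] <- as.list(colSums(rs[, -1, drop = FALSE]))
  assigned <- tot$unique + tot$fractional
  data.frame(
    sample = tot$sample,
    unique_fraction = tot$unique / tot$total,
    nuclear_mapped_fraction = tot$assigned_nuclear / assigned,
    full_length_fraction = tot$full_length / assigned,
    cca_fraction = tot$full_length_cca / tot$full_length,
    stringsAsFactors = FALSE
  )
}

#' Write count matrices to TSV
#'
#' Writes isodecoder-level and anticodon-level count matrices (fractional
#' counts at full precision).
#'
#' @param assignment A `trna_assignment`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_counts <- function(assignment, dir) {
  stopifnot(inherits(assignment, "trna_assignment"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir)
  }
  paths <- c(isodecoder = file.path(dir, "isodecoder_counts.tsv"),
             anticodon = file.path(dir, "anticodon_counts.tsv"))
  for (lvl in names(paths)) {
    m <- if (lvl == "isodecoder") assignment$counts else assignment$anticodon_counts
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, paths[[lvl]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Pool pileups across samples
#'
#' Sums per-position base and truncation counts over the selected samples,
#' e.g. over the replicates of one condition before stoichiometry calling.
#'
#' @param assignment A `trna_assignment`.
#' @param samples Samples to pool (default: all).
#' @return Data frame with columns `id`, `pos`, `A`, `C`, `G`, `T`, `trunc`.
#' @export
pool_pileups <- function(assignment, samples = NULL) {
  p <- assignment$pileups
  if (!is.null(samples)) {
    missing <- setdiff(samples, unique(p$sample))
    if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
    p <- p[p$sample %in% samples, , drop = FALSE]
  }
  agg <- rowsum(p[, c("A", "C", "G", "T", "trunc")],
                group = paste(p$id, p$pos, sep = "\r"))
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(id = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    agg, row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$id, out$pos), , drop = FALSE]
}
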