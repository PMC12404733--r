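# Independent brute-force oracles. These deliberately re-derive results with
# naive enumeration, not by calling the package's optimized code paths.

# --- wobble pairing oracle -------------------------------------------------
# Which codons can an anticodon read? Explicit per-base allowed sets,
# enumerated over all 64 codons.
oracle_reads_codon <- function(anticodon, codon, edited) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ac <- strsplit(anticodon, "")[[1]]
  cd <- strsplit(codon, "")[[1]]
  if (cd[1] != comp[ac[3]]) return(FALSE)
  if (cd[2] != comp[ac[2]]) return(FALSE)
  allowed <- switch(ac[1],
                    G = c("C", "T"),
                    C = c("G"),
                    T = c("A", "G", "T"),
                    A = if (edited) c("T", "C", "A") else c("T"))
  cd[3] %in% allowed
}

oracle_dependent_codons <- function(amino_acid, anticodon, table) {
  all64 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                             c("A","C","G","T")), 1, paste, collapse = "")
  decoded <- all64[vapply(all64, function(cd) {
    oracle_reads_codon(anticodon, cd, edited = TRUE)
  }, TRUE)]
  dependent <- decoded[vapply(decoded, function(cd) {
    for (i in seq_len(nrow(table))) {
      other_ac <- table$anticodon[i]
      if (other_ac == anticodon && table$amino_acid[i] == amino_acid) next
      if (oracle_reads_codon(other_ac, cd, edited = substr(other_ac, 1, 1) == "A")) {
        return(FALSE)
      }
    }
    TRUE
  }, TRUE)]
  list(decoded = unname(decoded), dependent = unname(dependent))
}

# --- assignment oracle -----------------------------------------------------
# Exhaustive per-read aligner: 3'-anchored ungapped scoring against every
# isodecoder, mismatches at exempt sites free; if the best ungapped score
# exceeds max_mismatch, every single-indel alignment is tried (gap cost 1).
oracle_align_read <- function(read, ref, max_mismatch = 3, indel = TRUE) {
  rec <- ref$records
  adat <- ref$families$family[ref$families$is_adat_target]
  rchars <- strsplit(read, "")[[1]]
  m <- length(rchars)
  exempt_of <- function(i) {
    e <- rec$mod_sites[[i]]$pos
    if (rec$family[i] %in% adat && rec$genome[i] == "nuclear") {
      e <- c(e, rec$anticodon_start[i])
    }
    e + 1L
  }
  ungapped <- function(i) {
    s <- strsplit(rec$sequence[i], "")[[1]]
    L <- length(s)
    if (m > L) return(Inf)
    ex <- exempt_of(i)
    score <- 0
    for (j in seq_len(m)) {
      refpos <- L - m + j
      if (refpos %in% ex) next
      if (rchars[j] != s[refpos]) score <- score + 1
    }
    score
  }
  one_indel <- function(i) {
    s <- strsplit(rec$sequence[i], "")[[1]]
    L <- length(s)
    ex <- exempt_of(i)
    best <- Inf
    score_gapped <- function(qr, len) {
      # qr: read chars with "-" marking a gap; aligned to the L-len+1..L suffix
      sc <- 1
      for (j in seq_len(len)) {
        refpos <- L - len + j
        if (qr[j] == "-" || refpos %in% ex) next
        if (qr[j] != s[refpos]) sc <- sc + 1
      }
      sc
    }
    if (m + 1L <= L) {
      for (g in seq_len(m + 1L)) {
        best <- min(best, score_gapped(append(rchars, "-", after = g - 1L), m + 1L))
      }
    }
    if (m - 1L >= 1L && m - 1L <= L) {
      for (g in seq_len(m)) {
        best <- min(best, score_gapped(rchars[-g], m - 1L))
      }
    }
    best
  }
  scores <- vapply(seq_len(nrow(rec)), ungapped, 0)
  if (min(scores) > max_mismatch && indel) {
    s1 <- vapply(seq_len(nrow(rec)), one_indel, 0)
    if (min(s1) <= max_mismatch && min(s1) < min(scores)) scores <- s1
  }
  best <- min(scores)
  if (best > max_mismatch) return(list(outcome = "unassigned", winners = character(0)))
  w <- rec$id[scores == best]
  fams <- unique(rec$family[scores == best])
  if (length(fams) > 1L) return(list(outcome = "ambiguous_cross_family", winners = character(0)))
  list(outcome = if (length(w) == 1L) "unique" else "fractional", winners = w)
}

# --- normalization oracle --------------------------------------------------
oracle_size_factors <- function(counts) {
  gm <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) gm[i] <- prod(counts[i, ])^(1 / ncol(counts))
  out <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ratios <- c()
    for (i in seq_len(nrow(counts))) {
      if (gm[i] > 0) ratios <- c(ratios, counts[i, j] / gm[i])
    }
    out[j] <- stats::median(ratios)
  }
  out
}

# --- rank correlation oracle ----------------------------------------------
# O(n^2) average ranks, Pearson by the explicit sum formula.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, 0)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2); syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# --- tiny fixture builders -------------------------------------------------
write_mini_reference <- function(dir, records) {
  fasta <- file.path(dir, "ref.fasta")
  annot <- file.path(dir, "ref.tsv")
  writeLines(unlist(lapply(seq_len(nrow(records)), function(i) {
    c(paste0(">", records$id[i]), records$sequence[i])
  })), fasta)
  utils::write.table(
    records[, c("id", "amino_acid", "anticodon", "anticodon_start", "genome", "mod_sites")],
    annot, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fasta = fasta, annotation = annot)
}

# a hand-built 2-record reference: Ala-AGC (ANN) and Gly-GCC (non-ANN)
mini_records <- function(cca = TRUE) {
  base1 <- paste0(strrep("G", 10), "AGC", strrep("T", 10))  # anticodon at 10
  base2 <- paste0(strrep("A", 10), "GCC", strrep("C", 10))
  data.frame(
    id = c("Ala-AGC-1", "Gly-GCC-1"),
    sequence = paste0(c(base1, base2), if (cca) "CCA" else ""),
    amino_acid = c("Ala", "Gly"),
    anticodon = c("AGC", "GCC"),
    anticodon_start = c(10L, 10L),
    genome = c("nuclear", "nuclear"),
    mod_sites = c("5:m1G9", ""),
    stringsAsFactors = FALSE
  )
}

write_mini_fastq <- function(path, seqs, names = NULL) {
  if (is.null(names)) names <- sprintf("read%03d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", names), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}
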