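#' Rank correlation between I34 loss and abundance loss
#'
#' Tests whether isodecoders losing more wobble inosine also lose more
#' abundance. Both inputs are case-minus-control changes on the log2 scale,
#' so a positive correlation means greater I34 loss accompanies greater
#' abundance loss. Spearman correlation uses average ranks on ties; the
#' p-value comes from unit-label permutation with the add-one rule, so it is
#' never exactly zero.
#'
#' @param delta_i34,delta_abundance Matched numeric vectors (log2 changes),
#'   or data frames carrying `unit` plus the respective column.
#' @param B Number of permutations (default 10000).
#' @param seed Mandatory RNG seed.
#' @param units Optional unit labels for the per-unit table.
#' @return List of class `coupling_result`: `n`, `r`, `p`, `B`, `table`.
#' @export
spearman_coupling <- function(delta_i34, delta_abundance, B = 10000, seed,
                              units = NULL) {
  stopifnot(!missing(seed), B >= 1)
  x <- as.numeric(delta_i34)
  y <- as.numeric(delta_abundance)
  if (length(x) != length(y)) stop("delta vectors must be matched")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 matched units")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: rank correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)  # Pearson on average ranks == Spearman with ties
  perm_r <- with_seed(seed, {
    vapply(seq_len(B), function(b) stats::cor(rx, ry[sample.int(n)]), 0)
  })
  p <- (1 + sum(abs(perm_r) >= abs(r))) / (1 + B)
  tab <- data.frame(unit = (units[keep]) %||% seq_len(n),
                    delta_i34 = x, delta_abundance = y,
                    stringsAsFactors = FALSE)
  structure(list(n = n, r = r, p = p, B = B, table = tab),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("coupling: Spearman r = %.3f, permutation p = %.3g (n = %d, B = %d)\n",
              x$r, x$p, x$n, x$B))
  invisible(x)
}

#' Per-gene usage of ADAT-dependent codons
#'
#' For every coding sequence and every ANN family, counts the family's
#' dependent codon and all synonymous codons of that amino acid within the
#' family's codon box, and reports the usage share (dependent / synonymous).
#' Records whose length is not a multiple of three or that contain an
#' internal stop are skipped and listed in the `skipped` attribute; the
#' terminal stop codon is excluded from counts.
#'
#' @param cds Named character vector of CDS sequences, a `DNAStringSet`, or a
#'   FASTA path.
#' @param codon_sets Dependent-codon table from [dependent_codon_table()].
#' @return Long data frame: `gene`, `n_codons`, `family`, `dependent_count`,
#'   `synonymous_count`, `share` (`NA` when the gene has no synonymous codons
#'   of that box).
#' @export
codon_usage <- function(cds, codon_sets = dependent_codon_table()) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds)) {
    cds <- Biostrings::readDNAStringSet(cds)
  }
  if (inherits(cds, "DNAStringSet")) {
    cds <- stats::setNames(as.character(cds), names(cds))
  }
  cds <- toupper(rna_to_dna(cds))
  if (is.null(names(cds))) names(cds) <- sprintf("gene%05d", seq_along(cds))
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]

  skipped <- character(0)
  codon_list <- vector("list", length(cds))
  for (i in seq_along(cds)) {
    s <- cds[[i]]
    len <- nchar(s)
    if (len %% 3L != 0L) {
      skipped <- c(skipped, stats::setNames("length not a multiple of 3", names(cds)[i]))
      next
    }
    cod <- substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
    if (length(cod) && cod[length(cod)] %in% stops) cod <- cod[-length(cod)]
    if (any(cod %in% stops)) {
      skipped <- c(skipped, stats::setNames("internal stop codon", names(cds)[i]))
      next
    }
    codon_list[[i]] <- cod
  }
  kept <- which(!vapply(codon_list, is.null, TRUE))
  if (!length(kept)) stop("no valid coding sequences")
  gene_id <- rep.int(kept, lengths(codon_list[kept]))
  cod_all <- unlist(codon_list[kept], use.names = FALSE)

  aa3to1 <- c(Ala = "A", Arg = "R", Ile = "I", Leu = "L", Pro = "P", Ser = "S",
              Thr = "T", Val = "V")
  rows <- lapply(seq_len(nrow(codon_sets)), function(f) {
    dep <- rna_to_dna(codon_sets$dependent[f])
    box <- rna_to_dna(strsplit(codon_sets$decoded[f], ",")[[1]])
    # synonymous box: the family's four-codon box restricted to its amino acid
    box4 <- paste0(substr(dep, 1, 2), c("T", "C", "A", "G"))
    aa <- aa3to1[codon_sets$amino_acid[f]]
    syn <- box4[gc[box4] == aa]
    dcount <- rowsum((cod_all == dep) * 1, gene_id)
    scount <- rowsum((cod_all %in% syn) * 1, gene_id)
    data.frame(gene = names(cds)[as.integer(rownames(dcount))],
               n_codons = as.vector(rowsum(rep(1, length(gene_id)), gene_id)),
               family = codon_sets$family[f],
               dependent_count = as.vector(dcount),
               synonymous_count = as.vector(scount),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$share <- ifelse(out$synonymous_count > 0,
                      out$dependent_count / out$synonymous_count, NA_real_)
  attr(out, "skipped") <- skipped
  out
}

#' Permutation test for ADAT-dependent codon enrichment in a gene set
#'
#' The statistic is the mean dependent-codon usage share over the gene set;
#' the null distribution comes from `B` random same-size gene sets drawn from
#' the background universe (optionally matched on CDS-length decile). The
#' one-sided alternative is higher usage in the set; p-values use the add-one
#' rule and are never zero.
#'
#' @param usage Usage table from [codon_usage()] over the background universe
#'   (which must contain the gene set).
#' @param geneset Character vector of gene ids (>= 5 eligible genes).
#' @param family Family key, e.g. `"Ala-AGC"`.
#' @param B Number of null sets (default 10000).
#' @param seed Mandatory RNG seed.
#' @param length_match Match null sets to the gene set's CDS-length decile
#'   composition?
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List of class `enrichment_result`: `family`, `dependent_codon`,
#'   `n_set`, `observed_share`, `background_share`, `p`, `B`.
#' @export
enrichment_test <- function(usage, geneset, family, B = 10000, seed,
                            length_match = FALSE,
                            alternative = c("greater", "two.sided")) {
  stopifnot(!missing(seed), B >= 1)
  alternative <- match.arg(alternative)
  u <- usage[usage$family == family, , drop = FALSE]
  if (!nrow(u)) stop("family ", family, " not present in usage table")
  u <- u[!duplicated(u$gene), , drop = FALSE]
  eligible <- u[!is.na(u$share), , drop = FALSE]
  geneset <- unique(geneset)
  outside <- setdiff(geneset, u$gene)
  if (length(outside)) stop("gene set contains ids outside the background universe: ",
                            paste(utils::head(outside, 5), collapse = ", "))
  in_set <- eligible$gene %in% geneset
  n_set <- sum(in_set)
  if (n_set < 5) stop("gene set has fewer than 5 eligible genes for ", family)
  shares <- eligible$share
  obs <- mean(shares[in_set])

  null_means <- with_seed(seed, {
    if (length_match) {
      br <- unique(stats::quantile(eligible$n_codons, 0:10 / 10))
      dec <- cut(eligible$n_codons, br, include.lowest = TRUE, labels = FALSE)
      want <- table(dec[in_set])
      pools <- split(seq_along(shares), dec)
      vapply(seq_len(B), function(b) {
        pick <- unlist(lapply(names(want), function(d) {
          sample(pools[[d]], want[[d]])
        }), use.names = FALSE)
        mean(shares[pick])
      }, 0)
    } else {
      N <- length(shares)
      vapply(seq_len(B), function(b) mean(shares[sample.int(N, n_set)]), 0)
    }
  })
  p <- if (alternative == "greater") {
    (1 + sum(null_means >= obs)) / (1 + B)
  } else {
    ctr <- mean(null_means)
    (1 + sum(abs(null_means - ctr) >= abs(obs - ctr))) / (1 + B)
  }
  dep_tab <- tryCatch(dependent_codon_table(), error = function(e) NULL)
  dep_codon <- if (!is.null(dep_tab) && family %in% dep_tab$family) {
    dep_tab$dependent[dep_tab$family == family]
  } else NA_character_
  structure(list(family = family,
                 dependent_codon = dep_codon,
                 n_set = n_set,
                 observed_share = obs,
                 background_share = mean(shares),
                 p = p, B = B, alternative = alternative),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: set share %.4f vs background %.4f, p = %.4g (n_set = %d, B = %d)\n",
              x$family, x$observed_share, x$background_share, x$p, x$n_set, x$B))
  invisible(x)
}
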