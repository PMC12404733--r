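#' Load and validate a mature tRNA reference
#'
#' Reads mature tRNA transcript sequences (FASTA) together with a per-isodecoder
#' annotation table and returns a validated reference set. Isodecoders are tRNA
#' transcripts that share an anticodon but differ elsewhere in their sequence;
#' they are grouped into anticodon families (isoacceptor pools) for family-level
#' statistics. Sequences are normalized to the DNA alphabet internally (U -> T);
#' reported codons use RNA letters.
#'
#' The annotation TSV must have columns `id`, `amino_acid`, `anticodon`,
#' `anticodon_start` (0-based index of the first anticodon base, i.e. the
#' wobble position 34), `genome` (`nuclear` or `mitochondrial`) and
#' `mod_sites` (semicolon-separated `pos:label` pairs, 0-based; may be empty).
#'
#' @param fasta_source Path to a FASTA file of mature tRNA sequences.
#' @param annotation_source Path to the annotation TSV (one row per FASTA record).
#' @param append_cca If `TRUE` (default), a terminal CCA is appended to records
#'   that lack it, mirroring reference preparation for mature tRNAs.
#' @return An object of class `trna_reference`: a list with `records` (one row
#'   per isodecoder, `mod_sites` as a list column) and `families` (one row per
#'   anticodon family with member counts and the ADAT-target flag).
#' @export
load_reference <- function(fasta_source, annotation_source, append_cca = TRUE) {
  # read as plain strings first: the FASTA may use RNA letters (U)
  seqs <- Biostrings::readBStringSet(fasta_source)
  if (length(seqs) == 0L) stop("no sequences in ", fasta_source)
  annot <- utils::read.delim(annotation_source, stringsAsFactors = FALSE,
                             colClasses = "character")
  required <- c("id", "amino_acid", "anticodon", "anticodon_start", "genome", "mod_sites")
  missing_cols <- setdiff(required, names(annot))
  if (length(missing_cols)) stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  annot$anticodon_start <- as.integer(annot$anticodon_start)

  ids <- names(seqs)
  dup <- annot$id[duplicated(annot$id)]
  if (length(dup)) stop("duplicated annotation rows for: ", paste(unique(dup), collapse = ", "))
  no_annot <- setdiff(ids, annot$id)
  if (length(no_annot)) stop("missing annotation row for record(s): ",
                             paste(no_annot, collapse = ", "))
  annot <- annot[match(ids, annot$id), ]

  sequence <- toupper(rna_to_dna(as.character(seqs)))
  if (any(!grepl("^[ACGT]+$", sequence))) {
    stop("non-ACGT(U) characters in sequence(s): ",
         paste(ids[!grepl("^[ACGT]+$", sequence)], collapse = ", "))
  }
  anticodon <- toupper(rna_to_dna(annot$anticodon))

  records <- data.frame(
    id = ids,
    sequence = unname(sequence),
    amino_acid = annot$amino_acid,
    anticodon = anticodon,
    anticodon_start = annot$anticodon_start,
    genome = match.arg_vec(annot$genome, c("nuclear", "mitochondrial")),
    stringsAsFactors = FALSE
  )
  records$mod_sites <- lapply(annot$mod_sites, parse_mod_sites)

  if (append_cca) {
    lacks <- !endsWith(records$sequence, "CCA")
    records$sequence[lacks] <- paste0(records$sequence[lacks], "CCA")
  }
  validate_records(records)
  build_reference(records)
}

match.arg_vec <- function(x, choices) {
  x <- tolower(x)
  bad <- !(x %in% choices)
  if (any(bad)) stop("invalid genome flag(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

parse_mod_sites <- function(x) {
  x <- trimws(x %||% "")
  if (is.na(x) || x == "" || x == "NA") {
    return(data.frame(pos = integer(0), label = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";")[[1]], ":")
  data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
             label = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

validate_records <- function(records) {
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    len <- nchar(r$sequence)
    if (r$anticodon_start + 3L >= len) {
      stop("record ", r$id, ": anticodon does not fit before the 3' end")
    }
    found <- substr(r$sequence, r$anticodon_start + 1L, r$anticodon_start + 3L)
    if (found != r$anticodon) {
      stop("record ", r$id, ": annotated anticodon ", dna_to_rna(r$anticodon),
           " not found at anticodon_start (", r$anticodon_start, "); sequence has ",
           dna_to_rna(found))
    }
    ms <- records$mod_sites[[i]]
    if (nrow(ms) && any(ms$pos < 0 | ms$pos >= len)) {
      stop("record ", r$id, ": modification site outside sequence")
    }
  }
  invisible(records)
}

build_reference <- function(records) {
  fam_key <- paste(records$amino_acid, dna_to_rna(records$anticodon), sep = "-")
  records$family <- fam_key
  fam <- unique(records[, c("family", "amino_acid", "anticodon", "genome")])
  # a family key is (amino_acid, anticodon, genome origin); mitochondrial
  # records never enter ADAT-target classification
  fam <- fam[order(fam$amino_acid, fam$anticodon, fam$genome), ]
  fam$n_members <- vapply(fam$family, function(f) sum(records$family == f), 0L)
  fam$is_adat_target <- substr(fam$anticodon, 1, 1) == "A" & fam$genome == "nuclear"
  rownames(fam) <- NULL
  structure(list(records = records, families = fam), class = "trna_reference")
}

#' @export
print.trna_reference <- function(x, ...) {
  cat("trna_reference:", nrow(x$records), "isodecoders in", nrow(x$families),
      "anticodon families (", sum(x$families$is_adat_target), "ADAT targets )\n")
  invisible(x)
}

#' Wobble (position 34) index of each isodecoder
#'
#' Returns the 0-based linear index of the first anticodon base, the position
#' deaminated from A to I in ANN tRNAs. The index is taken from the annotation
#' rather than inferred from secondary structure.
#'
#' @param ref A `trna_reference`.
#' @param ids Optional subset of record ids.
#' @return Named integer vector of 0-based wobble indices.
#' @export
wobble_index <- function(ref, ids = NULL) {
  stopifnot(inherits(ref, "trna_reference"))
  rec <- ref$records
  if (!is.null(ids)) {
    missing <- setdiff(ids, rec$id)
    if (length(missing)) stop("unknown record id(s): ", paste(missing, collapse = ", "))
    rec <- rec[match(ids, rec$id), ]
  }
  validate_records(rec)
  stats::setNames(rec$anticodon_start, rec$id)
}

#' Identify ADAT-target (ANN) anticodon families
#'
#' ADAT2/ADAT3 deaminates A34 to inosine in nuclear-encoded tRNAs whose
#' anticodon starts with A. On the standard eukaryotic cytoplasmic anticodon
#' repertoire these are the eight families Ala-AGC, Arg-ACG, Ile-AAU, Leu-AAG,
#' Pro-AGG, Ser-AGA, Thr-AGU and Val-AAC.
#'
#' @param ref A `trna_reference`, or a data frame with columns `amino_acid`
#'   and `anticodon` (an anticodon table).
#' @return Data frame of families with `is_adat_target = TRUE`, ordered by
#'   (amino_acid, anticodon).
#' @export
classify_adat_targets <- function(ref) {
  fam <- if (inherits(ref, "trna_reference")) {
    ref$families
  } else {
    stopifnot(is.data.frame(ref), all(c("amino_acid", "anticodon") %in% names(ref)))
    f <- unique(ref[, c("amino_acid", "anticodon")])
    f$anticodon <- toupper(rna_to_dna(f$anticodon))
    f$family <- paste(f$amino_acid, dna_to_rna(f$anticodon), sep = "-")
    f$genome <- "nuclear"
    f$is_adat_target <- substr(f$anticodon, 1, 1) == "A"
    f
  }
  out <- fam[fam$is_adat_target, , drop = FALSE]
  out <- out[order(out$amino_acid, out$anticodon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged eukaryotic cytoplasmic anticodon table
#'
#' The standard set of cytoplasmic tRNA anticodons present in eukaryotic
#' genomes (one row per amino acid/anticodon pair). Users may supply their own
#' table of the same shape to [enumerate_dependent_codons()].
#'
#' @param path Optional path to an alternative table (TSV with columns
#'   `amino_acid`, `anticodon`).
#' @return Data frame with columns `amino_acid` and `anticodon` (DNA letters).
#' @export
load_anticodon_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "anticodon_table.tsv", package = "wobbleseq",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("amino_acid", "anticodon") %in% names(tab)))
  tab$anticodon <- toupper(rna_to_dna(tab$anticodon))
  tab
}
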