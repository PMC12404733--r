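#' Codons read by one anticodon under wobble rules
#'
#' Watson-Crick pairing is required between codon bases 1-2 and anticodon bases
#' 36-35; pairing of the codon's third base with the anticodon's wobble base
#' (position 34) follows the wobble rules used throughout this package:
#' G34 reads C- and U-ending codons, C34 reads G-ending codons, U34 reads A-,
#' G- and U-ending codons (modified-U34 superwobble), unedited A34 reads only
#' U-ending codons, and I34 (deaminated A34 in ANN tRNAs) reads U-, C- and
#' A-ending codons.
#'
#' @param anticodon 3-mer, 5'->3' (DNA or RNA letters).
#' @param edited Treat an A34 anticodon as carrying inosine (I34)?
#' @return Character vector of codons (DNA letters, 5'->3').
#' @export
codons_read_by <- function(anticodon, edited = FALSE) {
  ac <- strsplit(toupper(rna_to_dna(anticodon)), "")[[1]]
  stopifnot(length(ac) == 3L, all(ac %in% names(comp_base)))
  first2 <- paste0(comp_base[ac[3]], comp_base[ac[2]])
  third <- switch(ac[1],
    G = c("C", "T"),
    C = "G",
    T = c("A", "G", "T"),
    A = if (edited) c("T", "C", "A") else "T"
  )
  paste0(first2, third)
}

#' Enumerate codons decoded by and dependent on an I34-edited family
#'
#' For an ADAT-target (ANN) anticodon family, the I34-edited anticodon decodes
#' the three codons ending in U, C or A of its codon box. Codons decodable by
#' no other anticodon in the organism's repertoire are ADAT-dependent; because
#' GNN anticodons are absent from eukaryotic genomes for these families, each
#' family has exactly one dependent codon and it ends in C.
#'
#' @param family Family key such as `"Ala-AGC"`, or a one-row data frame with
#'   `amino_acid` and `anticodon`.
#' @param anticodon_table Full anticodon repertoire of the organism, as from
#'   [load_anticodon_table()].
#' @return A list of class `codon_set` with elements `family`, `anticodon`,
#'   `decoded_codons` and `dependent_codons` (RNA letters).
#' @export
enumerate_dependent_codons <- function(family, anticodon_table = load_anticodon_table()) {
  if (is.character(family) && length(family) == 1L) {
    parts <- strsplit(family, "-")[[1]]
    stopifnot(length(parts) == 2L)
    family <- data.frame(amino_acid = parts[1],
                         anticodon = toupper(rna_to_dna(parts[2])),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(family), nrow(family) == 1L)
  ac <- toupper(rna_to_dna(family$anticodon))
  if (substr(ac, 1, 1) != "A") {
    stop("family ", family$amino_acid, "-", dna_to_rna(ac),
         " is not an ADAT target (anticodon does not start with A)")
  }
  decoded <- codons_read_by(ac, edited = TRUE)
  others <- anticodon_table[toupper(rna_to_dna(anticodon_table$anticodon)) != ac |
                              anticodon_table$amino_acid != family$amino_acid, ,
                            drop = FALSE]
  read_by_other <- unique(unlist(lapply(others$anticodon, function(a) {
    codons_read_by(a, edited = substr(toupper(rna_to_dna(a)), 1, 1) == "A")
  })))
  dependent <- setdiff(decoded, read_by_other)
  structure(list(family = paste(family$amino_acid, dna_to_rna(ac), sep = "-"),
                 anticodon = dna_to_rna(ac),
                 decoded_codons = dna_to_rna(decoded),
                 dependent_codons = dna_to_rna(dependent)),
            class = "codon_set")
}

#' @export
print.codon_set <- function(x, ...) {
  cat(x$family, ": decodes {", paste(x$decoded_codons, collapse = ", "),
      "}; ADAT-dependent {", paste(x$dependent_codons, collapse = ", "), "}\n")
  invisible(x)
}

#' Dependent-codon table for all ADAT-target families
#'
#' @param anticodon_table Anticodon repertoire; defaults to the packaged table.
#' @return Data frame with columns `family`, `anticodon`, `decoded`
#'   (comma-separated) and `dependent` (RNA letters).
#' @export
dependent_codon_table <- function(anticodon_table = load_anticodon_table()) {
  targets <- classify_adat_targets(anticodon_table)
  sets <- lapply(seq_len(nrow(targets)), function(i) {
    enumerate_dependent_codons(targets[i, c("amino_acid", "anticodon")], anticodon_table)
  })
  data.frame(
    family = vapply(sets, `[[`, "", "family"),
    anticodon = vapply(sets, `[[`, "", "anticodon"),
    amino_acid = targets$amino_acid,
    decoded = vapply(sets, function(s) paste(s$decoded_codons, collapse = ","), ""),
    dependent = vapply(sets, function(s) paste(s$dependent_codons, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

#' Write a codon-set table to TSV
#'
#' @param codon_sets Data frame from [dependent_codon_table()].
#' @param path Output TSV path.
#' @export
write_codon_sets <- function(codon_sets, path) {
  utils::write.table(codon_sets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
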