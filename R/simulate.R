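#' Simulate a tRNA isodecoder reference
#'
#' Builds a synthetic mature-tRNA reference with the canonical layout of a
#' 76-nt tRNA: anticodon at linear positions 33-35 (0-based; position 34 of
#' tRNA numbering is index 33), terminal CCA, and annotated modification sites
#' at the positions commonly carrying misincorporation-inducing modifications
#' (m1G9, m2,2G26, m1I37/yW37, m1A58). Every requested family receives
#' `n_per_family` isodecoders differing outside the anticodon.
#'
#' @param n_per_family Isodecoders per family.
#' @param adat_families ADAT-target families to include (family keys).
#' @param other_families Non-ANN families to include.
#' @param length Transcript length in nt (default 76).
#' @param anticodon_start 0-based wobble index (default 33).
#' @param mod_sites 0-based positions and labels of non-I34 modification sites.
#' @param member_divergence Number of substitutions separating each isodecoder
#'   from its family consensus (default 6), mimicking the small sequence
#'   differences between real isodecoders; truncated reads may therefore tie
#'   within a family.
#' @param seed Mandatory RNG seed.
#' @return A `trna_reference`.
#' @export
simulate_reference <- function(n_per_family = 2,
                               adat_families = c("Ala-AGC", "Arg-ACG", "Ile-AAT",
                                                 "Leu-AAG", "Pro-AGG", "Ser-AGA",
                                                 "Thr-AGT", "Val-AAC"),
                               other_families = c("Gly-GCC", "Asp-GTC", "Glu-CTC",
                                                  "Lys-TTT", "Phe-GAA", "His-GTG"),
                               length = 76, anticodon_start = 33,
                               mod_sites = data.frame(
                                 pos = c(8L, 25L, 36L, 57L),
                                 label = c("m1G9", "m22G26", "m1I37", "m1A58")),
                               member_divergence = 6, seed) {
  stopifnot(!missing(seed), length > anticodon_start + 6L)
  fams <- c(adat_families, other_families)
  with_seed(seed, {
    fixed <- c(anticodon_start + 1:3, (length - 2):length, mod_sites$pos + 1L)
    mutable <- setdiff(seq_len(length), fixed)
    rows <- lapply(fams, function(f) {
      parts <- strsplit(f, "-")[[1]]
      ac <- toupper(rna_to_dna(parts[2]))
      consensus <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      consensus[anticodon_start + 1:3] <- strsplit(ac, "")[[1]]
      consensus[(length - 2):length] <- c("C", "C", "A")
      lapply(seq_len(n_per_family), function(k) {
        s <- consensus
        div <- sample(mutable, min(member_divergence, base::length(mutable)))
        for (p in div) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        list(id = sprintf("%s-%s-%d", parts[1], parts[2], k),
             sequence = paste(s, collapse = ""),
             amino_acid = parts[1], anticodon = ac)
      })
    })
    rows <- unlist(rows, recursive = FALSE)
    records <- data.frame(
      id = vapply(rows, `[[`, "", "id"),
      sequence = vapply(rows, `[[`, "", "sequence"),
      amino_acid = vapply(rows, `[[`, "", "amino_acid"),
      anticodon = vapply(rows, `[[`, "", "anticodon"),
      anticodon_start = anticodon_start,
      genome = "nuclear",
      stringsAsFactors = FALSE
    )
    records$mod_sites <- rep(list(mod_sites), nrow(records))
    validate_records(records)
    build_reference(records)
  })
}

#' Write a reference to FASTA + annotation TSV
#'
#' @param ref A `trna_reference`.
#' @param fasta,annotation Output paths.
#' @export
write_reference <- function(ref, fasta, annotation) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(ref$records$sequence, ref$records$id))
  Biostrings::writeXStringSet(seqs, fasta)
  annot <- ref$records[, c("id", "amino_acid", "anticodon", "anticodon_start", "genome")]
  annot$mod_sites <- vapply(ref$records$mod_sites, function(ms) {
    paste(sprintf("%d:%s", ms$pos, ms$label), collapse = ";")
  }, "")
  utils::write.table(annot, annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, annotation = annotation))
}

#' Simulation configuration
#'
#' Collects and validates every knob of the tRNA-seq simulator. All
#' stochastic outputs downstream are pure functions of `(config, seed)`.
#'
#' @param ref A `trna_reference` the configuration refers to.
#' @param mean_abundance Named per-isodecoder expected read counts per
#'   replicate at size factor 1; `NULL` draws log-normal relative abundances
#'   summing to `reads_per_replicate`.
#' @param dispersion Negative-binomial dispersion alpha (scalar or named per
#'   isodecoder); 0 gives Poisson counts.
#' @param n_replicates Named vector, e.g. `c(control = 2, case = 2)`.
#' @param theta_control,theta_case I34 stoichiometry (probability that a read
#'   shows G at the wobble index) per condition; scalar or named per ANN
#'   isodecoder. Values given for non-ANN isodecoders are ignored with a
#'   warning. Control tRNAs are fully deaminated by default (`theta = 1`).
#' @param log2fc Planted case-vs-control log2 fold change (scalar or named).
#' @param coupling Optional `list(units=, slope=, sd=)`: for the listed
#'   isodecoders the planted log2 fold change is `slope * log2(theta_case /
#'   theta_control)` plus Gaussian noise, planting a monotone coupling between
#'   I34 loss and abundance loss.
#' @param mis_rate Misincorporation probability at each non-I34 modification
#'   site covered by a read.
#' @param trunc_prob Probability that reverse transcription stops at a
#'   modification site (the read then starts just 3' of the site).
#' @param error_rate Uniform per-base substitution sequencing error rate.
#' @param reads_per_replicate Target library depth.
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(ref,
                       mean_abundance = NULL,
                       dispersion = 0.1,
                       n_replicates = c(control = 2, case = 2),
                       theta_control = 1,
                       theta_case = NULL,
                       log2fc = 0,
                       coupling = NULL,
                       mis_rate = 0.08,
                       trunc_prob = 0.05,
                       error_rate = 0.001,
                       reads_per_replicate = 1e4,
                       seed) {
  stopifnot(inherits(ref, "trna_reference"), !missing(seed))
  ids <- ref$records$id
  probs <- c(mis_rate, trunc_prob, error_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("mis_rate, trunc_prob and error_rate must lie in [0, 1]")
  }
  # scalar -> recycled to all isodecoders; named partial -> others get `fill`
  expand <- function(x, fill, what) {
    if (is.null(names(x))) {
      if (length(x) != 1L) stop(what, " must be scalar or named per isodecoder")
      x <- stats::setNames(rep(x, length(ids)), ids)
    } else {
      full <- stats::setNames(rep(fill, length(ids)), ids)
      extra <- setdiff(names(x), ids)
      if (length(extra)) stop(what, " names not in reference: ", paste(extra, collapse = ", "))
      full[names(x)] <- x
      x <- full
    }
    x
  }
  if (is.null(mean_abundance)) {
    rel <- with_seed(child_seed(seed, 1), stats::rlnorm(length(ids), 0, 0.5))
    mean_abundance <- stats::setNames(reads_per_replicate * rel / sum(rel), ids)
  } else {
    mean_abundance <- expand(mean_abundance, mean(mean_abundance), "mean_abundance")
  }
  if (any(!is.finite(mean_abundance)) || any(mean_abundance < 0)) {
    stop("mean abundances must be finite and non-negative")
  }
  dispersion <- expand(dispersion, mean(dispersion), "dispersion")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (is.null(names(n_replicates)) || length(n_replicates) < 1L ||
      !all(names(n_replicates) %in% c("control", "case"))) {
    stop("n_replicates must be named with conditions 'control' and/or 'case'")
  }
  ann <- ref$records$id[ref$records$family %in%
                          ref$families$family[ref$families$is_adat_target]]
  check_theta <- function(th, what) {
    if (!is.null(names(th))) {
      stray <- setdiff(names(th), ids)
      if (length(stray)) stop(what, " names not in reference: ", paste(stray, collapse = ", "))
      non_ann <- setdiff(names(th), ann)
      if (length(non_ann)) {
        warning(what, " given for non-ANN isodecoder(s) ",
                paste(non_ann, collapse = ", "), "; ignored")
        th <- th[setdiff(names(th), non_ann)]
      }
    }
    if (any(th < 0 | th > 1)) stop(what, " must lie in [0, 1]")
    th
  }
  theta_control <- check_theta(theta_control, "theta_control")
  theta_case <- check_theta(theta_case %||% theta_control, "theta_case")
  expand_theta <- function(th) {
    full <- stats::setNames(rep(if (is.null(names(th))) th[1] else 1, length(ann)), ann)
    if (!is.null(names(th))) full[intersect(names(th), ann)] <- th[intersect(names(th), ann)]
    full
  }
  theta <- list(control = expand_theta(theta_control), case = expand_theta(theta_case))
  log2fc <- expand(log2fc, 0, "log2fc")
  if (!is.null(coupling)) {
    stopifnot(is.list(coupling), all(coupling$units %in% ann))
    coupling$slope <- coupling$slope %||% 1
    coupling$sd <- coupling$sd %||% 0.2
  }
  structure(list(ids = ids, mean_abundance = mean_abundance, dispersion = dispersion,
                 n_replicates = n_replicates, theta = theta, log2fc = log2fc,
                 coupling = coupling, mis_rate = mis_rate, trunc_prob = trunc_prob,
                 error_rate = error_rate, reads_per_replicate = reads_per_replicate,
                 seed = seed),
            class = "sim_config")
}

#' Simulate per-isodecoder counts under a negative-binomial model
#'
#' Counts for isodecoder i in replicate j of condition c are drawn
#' NB(mean = mu_i * fc_ic * sf_j, dispersion = alpha_i); alpha = 0 degenerates
#' to Poisson. Replicate size factors are log-normal. The planted fold change
#' applies to the case condition; coupled isodecoders derive their fold change
#' from the planted I34 loss.
#'
#' @param ref A `trna_reference`.
#' @param config A `sim_config`.
#' @return List with `counts` (isodecoder x sample matrix), `truth` (a
#'   ground-truth record of every planted parameter) and `config`.
#' @export
simulate_counts <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- config$ids
  log2fc <- config$log2fc
  coupling_noise <- NULL
  if (!is.null(config$coupling)) {
    cu <- config$coupling$units
    dtheta <- log2(pmax(config$theta$case[cu], 1e-6) /
                     pmax(config$theta$control[cu], 1e-6))
    coupling_noise <- with_seed(child_seed(config$seed, 2),
                                stats::rnorm(length(cu), 0, config$coupling$sd))
    log2fc[cu] <- config$coupling$slope * dtheta + coupling_noise
  }
  conditions <- names(config$n_replicates)
  samples <- unlist(lapply(conditions, function(cn) {
    paste(cn, seq_len(config$n_replicates[[cn]]), sep = "_")
  }))
  sf <- with_seed(child_seed(config$seed, 3),
                  stats::setNames(stats::rlnorm(length(samples), 0, 0.15), samples))
  counts <- with_seed(child_seed(config$seed, 4), {
    m <- matrix(0, length(ids), length(samples), dimnames = list(ids, samples))
    for (s in samples) {
      cond <- sub("_[0-9]+$", "", s)
      fc <- if (cond == "case") 2^log2fc else rep(1, length(ids))
      mu <- config$mean_abundance * fc * sf[[s]]
      if (any(!is.finite(mu))) stop("non-finite simulated means")
      alpha <- config$dispersion
      pois <- alpha == 0
      m[pois, s] <- stats::rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        m[!pois, s] <- stats::rnbinom(sum(!pois), mu = mu[!pois], size = 1 / alpha[!pois])
      }
    }
    m
  })
  truth <- list(mean_abundance = config$mean_abundance,
                dispersion = config$dispersion,
                size_factors = sf,
                log2fc = log2fc,
                theta = config$theta,
                coupled_units = config$coupling$units,
                seed = config$seed)
  list(counts = counts, truth = truth, config = config)
}

#' Simulate tRNA-seq reads carrying modification signatures
#'
#' Reads are full-length-biased: each starts at the 3' CCA end of its
#' transcript and extends toward the 5' end; reverse transcription stops at a
#' modification site with probability `trunc_prob`, producing a read starting
#' just 3' of the site. At the wobble index of ANN isodecoders the read shows
#' G with probability theta (inosine is read as G by reverse transcriptase)
#' and A otherwise. Covered non-I34 modification sites misincorporate at
#' `mis_rate`; a uniform substitution-only sequencing error applies elsewhere.
#' Reads are written 5'->3', adapter-free, with constant quality.
#'
#' @param ref A `trna_reference`.
#' @param counts Isodecoder x sample count matrix (e.g. from
#'   [simulate_counts()]).
#' @param config A `sim_config`.
#' @param dir Output directory for FASTQ files (one per sample,
#'   `{condition}_{rep}.fastq[.gz]`).
#' @param gzip Compress outputs?
#' @return List with `files` (named FASTQ paths) and `truth` (theta and read
#'   counts actually simulated).
#' @export
simulate_reads <- function(ref, counts, config, dir, gzip = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- ref$records
  stopifnot(all(rownames(counts) %in% rec$id))
  adat <- rec$family %in% ref$families$family[ref$families$is_adat_target] &
    rec$genome == "nuclear"
  files <- character(0)
  for (s in colnames(counts)) {
    path <- file.path(dir, paste0(s, ".fastq", if (gzip) ".gz" else ""))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    with_seed(child_seed(config$seed, 10 + match(s, colnames(counts))), {
      for (i in seq_len(nrow(rec))) {
        if (!rec$id[i] %in% rownames(counts)) next
        n <- counts[rec$id[i], s]
        if (n == 0) next
        reads <- .simulate_reads_one(rec[i, ], rec$mod_sites[[i]], n,
                                     theta = if (adat[i]) config$theta[[sub("_[0-9]+$", "", s)]][[rec$id[i]]] else NA,
                                     config = config)
        names <- sprintf("@%s|%s|%d|start=%d", s, rec$id[i], seq_len(n), reads$start)
        writeLines(rbind(names, reads$seq, "+", strrep("I", nchar(reads$seq))), con)
      }
    })
    close(con)
    files[s] <- path
  }
  list(files = files,
       truth = list(theta = config$theta, reads_per_isodecoder = counts,
                    seed = config$seed))
}

.simulate_reads_one <- function(rec, mod_sites, n, theta, config) {
  L <- nchar(rec$sequence)
  wob <- rec$anticodon_start  # 0-based
  sites <- mod_sites$pos
  # truncation: read starts just 3' of the most 3' truncating site
  start <- rep(0L, n)
  if (length(sites) && config$trunc_prob > 0) {
    for (sp in sort(sites)) {
      hit <- stats::runif(n) < config$trunc_prob
      start[hit] <- sp + 1L
    }
  }
  seqs <- substring(rec$sequence, start + 1L, L)
  # wobble signature of inosine: G with probability theta, else A
  if (!is.na(theta)) {
    covered <- which(start <= wob)
    g <- stats::runif(n) < theta
    rel <- wob - start + 1L
    substring(seqs[covered], rel[covered], rel[covered]) <-
      ifelse(g[covered], "G", "A")
  }
  # misincorporation at covered non-I34 modification sites
  if (length(sites) && config$mis_rate > 0) {
    for (sp in sites) {
      hit <- which(start <= sp & stats::runif(n) < config$mis_rate)
      if (length(hit)) {
        rel <- sp - start[hit] + 1L
        cur <- substr(seqs[hit], rel, rel)
        u <- ceiling(stats::runif(length(hit)) * 3)
        alt <- vapply(seq_along(hit), function(k) {
          setdiff(c("A", "C", "G", "T"), cur[k])[u[k]]
        }, "")
        substring(seqs[hit], rel, rel) <- alt
      }
    }
  }
  # uniform substitution errors
  if (config$error_rate > 0) {
    len <- nchar(seqs)
    nerr <- stats::rbinom(n, len, config$error_rate)
    for (idx in which(nerr > 0)) {
      pos <- sample.int(len[idx], nerr[idx])
      for (p in pos) {
        cur <- substr(seqs[idx], p, p)
        others <- setdiff(c("A", "C", "G", "T"), cur)
        substr(seqs[idx], p, p) <- sample(others, 1L)
      }
    }
  }
  list(seq = seqs, start = start)
}

#' Simulate CDS gene sets with planted ADAT-dependent codon enrichment
#'
#' Background genes draw codons uniformly within each synonymous family from
#' amino acid sequences sampled at human-like frequencies; target-set genes
#' multiply the odds of each ADAT-dependent codon within its synonymous family
#' by `multiplier` (renormalized). `multiplier = 1` makes the two groups
#' exchangeable.
#'
#' @param dependent_tab Dependent-codon table, as from
#'   [dependent_codon_table()].
#' @param n_background,n_target Numbers of background and target genes.
#' @param multiplier Odds multiplier (> 0) for dependent codons in the target
#'   set.
#' @param gene_length Mean CDS length in codons (Poisson, floor 30).
#' @param seed Mandatory RNG seed.
#' @param dir Optional directory; when given, writes `cds_synthetic.fasta`.
#' @return List with `cds` (named character vector of CDS sequences, frame 0,
#'   terminal stop included), `gene_sets` (target gene ids) and `truth`.
#' @export
simulate_gene_sets <- function(dependent_tab = dependent_codon_table(),
                               n_background = 5000, n_target = 200,
                               multiplier = 1.5, gene_length = 150,
                               seed, dir = NULL) {
  stopifnot(!missing(seed))
  if (!is.finite(multiplier) || multiplier <= 0) stop("multiplier must be > 0")
  gc <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(gc), gc)
  codons_by_aa[["*"]] <- NULL
  aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
              Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
              Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
              Tyr = "Y", Val = "V")
  aa_freq <- c(A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.047,
               E = 0.071, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057,
               M = 0.022, F = 0.036, P = 0.063, S = 0.083, T = 0.054, W = 0.012,
               Y = 0.027, V = 0.060)
  aa_freq <- aa_freq / sum(aa_freq)
  dep <- stats::setNames(rna_to_dna(dependent_tab$dependent),
                         aa3to1[dependent_tab$amino_acid])

  codon_probs <- function(boost) {
    lapply(stats::setNames(names(codons_by_aa), names(codons_by_aa)), function(aa) {
      cods <- codons_by_aa[[aa]]
      w <- rep(1, length(cods))
      if (boost != 1 && aa %in% names(dep)) w[cods == dep[[aa]]] <- boost
      stats::setNames(w / sum(w), cods)
    })
  }
  bg_probs <- codon_probs(1)
  tg_probs <- codon_probs(multiplier)

  n_total <- n_background + n_target
  ids <- sprintf("g%05d", seq_len(n_total))
  is_target <- c(rep(FALSE, n_background), rep(TRUE, n_target))
  cds <- with_seed(seed, {
    len <- pmax(30L, stats::rpois(n_total, gene_length))
    gene_id <- rep.int(seq_len(n_total), len)
    aa_all <- sample(names(aa_freq), sum(len), replace = TRUE, prob = aa_freq)
    cod_all <- character(length(aa_all))
    for (grp in c(FALSE, TRUE)) {
      probs <- if (grp) tg_probs else bg_probs
      in_grp <- is_target[gene_id]
      for (aa in names(codons_by_aa)) {
        sel <- which(aa_all == aa & in_grp == grp)
        if (length(sel)) {
          cod_all[sel] <- sample(names(probs[[aa]]), length(sel), replace = TRUE,
                                 prob = probs[[aa]])
        }
      }
    }
    body <- vapply(split(cod_all, gene_id), paste, "", collapse = "")
    stats::setNames(paste0("ATG", unname(body), "TAA"), ids)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds),
                                file.path(dir, "cds_synthetic.fasta"))
  }
  list(cds = cds,
       gene_sets = list(target = ids[is_target]),
       truth = list(multiplier = multiplier, target_ids = ids[is_target],
                    seed = seed))
}

#' Simulate coupled I34 and abundance changes
#'
#' Draws per-isodecoder (delta I34, delta abundance) pairs, both case-minus-
#' control on the log2 scale, from a Gaussian copula calibrated so that the
#' population Spearman correlation equals `rho`. Both margins are centred
#' below zero: loss of editing accompanies loss of abundance.
#'
#' @param n Number of units.
#' @param rho Target Spearman correlation.
#' @param seed Mandatory RNG seed.
#' @return Data frame with columns `unit`, `delta_i34`, `delta_abundance`.
#' @export
simulate_coupled_deltas <- function(n = 60, rho = 0.5, seed) {
  stopifnot(!missing(seed), abs(rho) < 1)
  r_pearson <- 2 * sin(pi * rho / 6)  # Spearman -> Pearson for a Gaussian copula
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- r_pearson * z1 + sqrt(1 - r_pearson^2) * stats::rnorm(n)
    data.frame(unit = sprintf("u%03d", seq_len(n)),
               delta_i34 = -0.5 + 0.4 * z1,
               delta_abundance = -0.3 + 0.35 * z2,
               stringsAsFactors = FALSE)
  })
}

#' Serialize a ground-truth record as JSON
#'
#' @param truth Ground-truth list (from the simulators).
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
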