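#' Demo pipeline configuration
#'
#' A small, fully simulated two-condition study: eight ANN and six non-ANN
#' families with two isodecoders each, fully deaminated controls, planted I34
#' loss in the Ala-AGC and Val-AAC families coupled to abundance loss, and a
#' gene set with planted dependent-codon enrichment.
#'
#' @param seed RNG seed (default 7).
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 7) {
  list(
    seed = seed,
    reference = list(mode = "simulate", n_per_family = 2),
    simulation = list(
      n_replicates = list(control = 2, case = 2),
      reads_per_replicate = 4000,
      dispersion = 0.05,
      theta_case = list(`Ala-AGC-1` = 0.43, `Ala-AGC-2` = 0.25,
                        `Val-AAC-1` = 0.6, `Val-AAC-2` = 0.8,
                        `Ile-AAT-1` = 0.7, `Leu-AAG-1` = 0.85,
                        `Thr-AGT-1` = 0.75),
      coupling = list(slope = 1, sd = 0.15),
      mis_rate = 0.08, trunc_prob = 0.05, error_rate = 0.001
    ),
    assign = list(max_mismatch = 3, mod_site_free = TRUE),
    quantify = list(min_coverage = 20),
    differential = list(sig = 0.05, shrink = 0.5),
    coupling = list(B = 2000),
    enrichment = list(enabled = TRUE, n_background = 600, n_target = 60,
                      multiplier = 1.6, gene_length = 120, B = 2000,
                      families = "Ala-AGC")
  )
}

.allowed_keys <- list(
  top = c("seed", "output_dir", "reference", "simulation", "fastq", "assign",
          "quantify", "differential", "coupling", "enrichment"),
  reference = c("mode", "n_per_family", "fasta", "annotation", "append_cca"),
  simulation = c("n_replicates", "reads_per_replicate", "dispersion",
                 "mean_abundance", "theta_control", "theta_case", "log2fc",
                 "coupling", "mis_rate", "trunc_prob", "error_rate"),
  assign = c("max_mismatch", "mod_site_free", "rescue_indel"),
  quantify = c("min_coverage"),
  differential = c("sig", "shrink"),
  coupling = c("B"),
  enrichment = c("enabled", "n_background", "n_target", "multiplier",
                 "gene_length", "B", "families", "cds", "geneset",
                 "length_match")
)

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration list before any work is done: unknown keys
#' at any level are rejected, a seed is mandatory, and either a simulation
#' block or FASTQ paths must be present.
#'
#' @param config Configuration list.
#' @return The configuration, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  check <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  check(config, .allowed_keys$top, "top level")
  for (sec in intersect(names(config), names(.allowed_keys)[-1])) {
    check(config[[sec]], .allowed_keys[[sec]], sec)
  }
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$reference)) stop("config must have a reference block")
  if (is.null(config$simulation) && is.null(config$fastq)) {
    stop("config needs either a simulation block or fastq paths")
  }
  invisible(config)
}

#' Run the full wobble-inosine analysis pipeline
#'
#' Executes reference preparation, read simulation or ingestion, assignment,
#' QC, I34 stoichiometry calling, differential abundance, coupling, and codon
#' enrichment, writing every intermediate artifact, a stage log, the resolved
#' configuration, the simulator's ground truth, and a summary JSON. With a
#' fixed configuration and seed the summary is byte-identical across reruns.
#'
#' @param config Configuration list (see [demo_config()]) or a YAML path.
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @return The summary list, invisibly; artifacts under `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  out <- output_dir %||% config$output_dir %||% stop("no output directory given")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_path <- file.path(out, "pipeline_log.txt")
  cat("", file = log_path)
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      cat(sprintf("stage=%s status=FAILED error=%s\n", name, conditionMessage(e)),
          file = log_path, append = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    cat(sprintf("stage=%s status=ok elapsed_s=%.2f\n", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        file = log_path, append = TRUE)
    res
  }
  seed <- config$seed
  summary <- list(seed = seed)

  ref <- stage("reference", {
    rb <- config$reference
    if ((rb$mode %||% "files") == "simulate") {
      r <- simulate_reference(n_per_family = rb$n_per_family %||% 2,
                              seed = child_seed(seed, 100))
      write_reference(r, file.path(out, "reference.fasta"),
                      file.path(out, "reference_annotation.tsv"))
      r
    } else {
      for (f in c(rb$fasta, rb$annotation)) {
        if (!file.exists(f)) stop("reference input not found: ", f)
      }
      load_reference(rb$fasta, rb$annotation, append_cca = rb$append_cca %||% TRUE)
    }
  })

  sim <- NULL
  fastq <- stage("reads", {
    if (!is.null(config$simulation)) {
      sb <- config$simulation
      cfg <- sim_config(
        ref,
        mean_abundance = unlist(sb$mean_abundance),
        dispersion = sb$dispersion %||% 0.1,
        n_replicates = unlist(sb$n_replicates %||% list(control = 2, case = 2)),
        theta_control = unlist(sb$theta_control) %||% 1,
        theta_case = unlist(sb$theta_case),
        log2fc = unlist(sb$log2fc) %||% 0,
        coupling = if (!is.null(sb$coupling)) {
          list(units = sb$coupling$units %||% names(unlist(sb$theta_case)),
               slope = sb$coupling$slope, sd = sb$coupling$sd)
        },
        mis_rate = sb$mis_rate %||% 0.08,
        trunc_prob = sb$trunc_prob %||% 0.05,
        error_rate = sb$error_rate %||% 0.001,
        reads_per_replicate = sb$reads_per_replicate %||% 1e4,
        seed = child_seed(seed, 200)
      )
      counts <- simulate_counts(ref, cfg)
      rd <- simulate_reads(ref, counts$counts, cfg, file.path(out, "fastq"))
      sim <- list(config = cfg, truth = counts$truth)
      write_ground_truth(counts$truth, file.path(out, "ground_truth.json"))
      rd$files
    } else {
      files <- unlist(lapply(names(config$fastq), function(cond) {
        fs <- unlist(config$fastq[[cond]])
        stats::setNames(fs, paste(cond, seq_along(fs), sep = "_"))
      }))
      missing_f <- files[!file.exists(files)]
      if (length(missing_f)) stop("FASTQ not found: ", paste(missing_f, collapse = ", "))
      files
    }
  })

  assignment <- stage("assign", {
    ab <- config$assign %||% list()
    assign_reads(fastq, ref, max_mismatch = ab$max_mismatch %||% 3,
                 mod_site_free = ab$mod_site_free %||% TRUE,
                 rescue_indel = ab$rescue_indel %||% TRUE)
  })
  stage("counts_qc", {
    write_counts(assignment, out)
    qc <- qc_metrics(assignment)
    utils::write.table(qc, file.path(out, "qc_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$qc <- as.list(qc[qc$sample == "all", -1])
  })

  conds <- unique(sub("_[0-9]+$", "", colnames(assignment$counts)))
  calls <- stage("quantify", {
    minc <- config$quantify$min_coverage %||% 20
    per_cond <- lapply(stats::setNames(conds, conds), function(cn) {
      pooled <- pool_pileups(assignment,
                             grep(paste0("^", cn, "_"), colnames(assignment$counts),
                                  value = TRUE))
      iso <- call_i34(pooled, ref, min_coverage = minc)
      fam <- aggregate_anticodon(iso, min_coverage = minc)
      write_mod_calls(iso, file.path(out, paste0("i34_isodecoder_", cn, ".tsv")))
      write_mod_calls(fam, file.path(out, paste0("i34_anticodon_", cn, ".tsv")))
      list(iso = iso, fam = fam)
    })
    summary$i34_per_family <- lapply(per_cond, function(x) {
      stats::setNames(as.list(round(x$fam$theta, 6)), x$fam$unit)
    })
    per_cond
  })

  deltas <- NULL
  if (all(c("control", "case") %in% conds)) {
    deltas <- stage("delta", {
      d <- delta_mod(calls$case$iso, calls$control$iso)
      utils::write.table(d, file.path(out, "delta_i34_isodecoder.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      d
    })
  }

  diff_res <- NULL
  cond_vec <- sub("_[0-9]+$", "", colnames(assignment$counts))
  if (length(conds) == 2 && all(table(cond_vec) >= 2)) {
    diff_res <- stage("differential", {
      db <- config$differential %||% list()
      res_iso <- test_differential(assignment$counts, cond_vec, "isodecoder",
                                   ref = ref, shrink = db$shrink %||% 0.5,
                                   sig = db$sig %||% 0.05)
      res_fam <- test_differential(assignment$counts, cond_vec, "anticodon",
                                   ref = ref, shrink = db$shrink %||% 0.5,
                                   sig = db$sig %||% 0.05)
      write_differential(res_iso, file.path(out, "differential_isodecoder"))
      write_differential(res_fam, file.path(out, "differential_anticodon"))
      summary$differential <- list(
        n_tested = nrow(res_iso),
        n_down = sum(res_iso$direction == "down"),
        n_up = sum(res_iso$direction == "up"),
        anticodon_down = res_fam$unit[res_fam$direction == "down"]
      )
      list(iso = res_iso, fam = res_fam)
    })
  }

  if (!is.null(deltas) && !is.null(diff_res)) {
    stage("coupling", {
      merged <- merge(deltas[, c("unit", "log2_ratio")],
                      diff_res$iso[, c("unit", "log2FC")], by = "unit")
      if (nrow(merged) >= 5 && stats::sd(merged$log2_ratio) > 0) {
        cp <- spearman_coupling(merged$log2_ratio, merged$log2FC,
                                B = config$coupling$B %||% 10000,
                                seed = child_seed(seed, 300),
                                units = merged$unit)
        utils::write.table(cp$table, file.path(out, "coupling_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$coupling <- list(n = cp$n, spearman_r = cp$r, permutation_p = cp$p)
      } else {
        summary$coupling <- list(n = nrow(merged), spearman_r = NA, permutation_p = NA)
      }
    })
  }

  eb <- config$enrichment
  if (!is.null(eb) && isTRUE(eb$enabled %||% TRUE)) {
    stage("enrichment", {
      if (!is.null(eb$cds)) {
        cds <- eb$cds
        geneset <- readLines(eb$geneset)
      } else {
        gs <- simulate_gene_sets(n_background = eb$n_background %||% 5000,
                                 n_target = eb$n_target %||% 200,
                                 multiplier = eb$multiplier %||% 1.5,
                                 gene_length = eb$gene_length %||% 150,
                                 seed = child_seed(seed, 400),
                                 dir = out)
        cds <- gs$cds
        geneset <- gs$gene_sets$target
        writeLines(geneset, file.path(out, "geneset_target.txt"))
      }
      usage <- codon_usage(cds)
      fams <- eb$families %||% unique(usage$family)
      enr <- lapply(stats::setNames(fams, fams), function(f) {
        enrichment_test(usage, geneset, f, B = eb$B %||% 10000,
                        seed = child_seed(seed, 500 + match(f, fams)),
                        length_match = isTRUE(eb$length_match))
      })
      enr_tab <- data.frame(
        family = fams,
        observed_share = vapply(enr, `[[`, 0, "observed_share"),
        background_share = vapply(enr, `[[`, 0, "background_share"),
        p = vapply(enr, `[[`, 0, "p"), row.names = NULL)
      utils::write.table(enr_tab, file.path(out, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$enrichment <- stats::setNames(as.list(enr_tab$p), enr_tab$family)
    })
  }

  stage("summary", {
    yaml::write_yaml(config, file.path(out, "resolved_config.yaml"))
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  cat(sprintf("stage=done status=ok total_elapsed_s=%.2f\n",
              as.numeric(difftime(Sys.time(), t_all, units = "secs"))),
      file = log_path, append = TRUE)
  invisible(summary)
}
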