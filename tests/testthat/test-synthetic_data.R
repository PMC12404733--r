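test_that("simulated counts are negative-binomial with recorded truth", {
  ref <- simulate_reference(n_per_family = 1, seed = 5)
  ids <- ref$records$id
  # alpha = 0 degenerates to Poisson: sample mean within 3 SE of mu at n = 200
  mu <- stats::setNames(rep(50, length(ids)), ids)
  cfg <- sim_config(ref, mean_abundance = mu, dispersion = 0,
                    n_replicates = c(control = 200), theta_control = 1, seed = 77)
  sc <- simulate_counts(ref, cfg)
  sf <- sc$truth$size_factors
  norm <- sweep(sc$counts, 2, sf, "/")
  se <- sqrt(50 / 200)
  expect_true(all(abs(rowMeans(norm) - 50) < 3 * se))
  # same seed twice -> identical draws
  sc2 <- simulate_counts(ref, cfg)
  expect_identical(sc$counts, sc2$counts)
  # planted fold change is recorded in the truth for the right members
  ala <- ref$records$id[ref$records$family == "Ala-AGC"]
  cfg3 <- sim_config(ref, n_replicates = c(control = 2, case = 2),
                     log2fc = stats::setNames(rep(-1, length(ala)), ala), seed = 9)
  sc3 <- simulate_counts(ref, cfg3)
  expect_true(all(sc3$truth$log2fc[ala] == -1))
  expect_true(all(sc3$truth$log2fc[setdiff(ids, ala)] == 0))
})

test_that("config validation rejects invalid probabilities and units", {
  ref <- simulate_reference(n_per_family = 1, seed = 5)
  expect_error(sim_config(ref, mis_rate = 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(sim_config(ref, theta_case = c(`Ala-AGC-1` = 2), seed = 1), "\\[0, 1\\]")
  expect_error(sim_config(ref, mean_abundance = c(x = 5), seed = 1), "not in reference")
  # theta on a non-ANN isodecoder is ignored with a warning
  expect_warning(sim_config(ref, theta_case = c(`Gly-GCC-1` = 0.5), seed = 1),
                 "non-ANN")
  expect_error(sim_config(ref, mean_abundance = Inf, seed = 1), "finite")
})

test_that("simulated reads carry the wobble-inosine signature", {
  ref <- simulate_reference(n_per_family = 1, other_families = character(0),
                            seed = 6)
  dir <- withr::local_tempdir()
  ids <- ref$records$id
  counts <- matrix(400, length(ids), 1, dimnames = list(ids, "case_1"))
  # theta = 1, no error, no truncation: every wobble-covering read shows G
  cfg1 <- sim_config(ref, n_replicates = c(case = 1), theta_case = 1,
                     mis_rate = 0, trunc_prob = 0, error_rate = 0, seed = 3)
  rd1 <- simulate_reads(ref, counts, cfg1, file.path(dir, "t1"))
  seqs <- as.character(Biostrings::readDNAStringSet(rd1$files[[1]], format = "fastq"))
  expect_true(all(substr(seqs, 34, 34) == "G"))
  # theta = 0: every such read shows A
  cfg0 <- sim_config(ref, n_replicates = c(case = 1), theta_case = 0,
                     mis_rate = 0, trunc_prob = 0, error_rate = 0, seed = 3)
  rd0 <- simulate_reads(ref, counts, cfg0, file.path(dir, "t0"))
  seqs0 <- as.character(Biostrings::readDNAStringSet(rd0$files[[1]], format = "fastq"))
  expect_true(all(substr(seqs0, 34, 34) == "A"))
  # intermediate theta: G fraction within 3 binomial SE at 10,000 covering reads
  counts_big <- matrix(10000, 1, 1, dimnames = list("Ala-AGC-1", "case_1"))
  cfg43 <- sim_config(ref, n_replicates = c(case = 1),
                      theta_case = c(`Ala-AGC-1` = 0.43),
                      mis_rate = 0, trunc_prob = 0, error_rate = 0, seed = 8)
  rd43 <- simulate_reads(ref, counts_big, cfg43, file.path(dir, "t43"))
  s43 <- as.character(Biostrings::readDNAStringSet(rd43$files[[1]], format = "fastq"))
  gfrac <- mean(substr(s43, 34, 34) == "G")
  expect_lt(abs(gfrac - 0.43), 3 * sqrt(0.43 * 0.57 / 10000))
})

test_that("truncation never lets a read extend 5' of its stop and is reproducible", {
  ref <- simulate_reference(n_per_family = 1, seed = 10)
  dir <- withr::local_tempdir()
  ids <- ref$records$id
  counts <- matrix(300, length(ids), 1, dimnames = list(ids, "control_1"))
  cfg <- sim_config(ref, n_replicates = c(control = 1), trunc_prob = 0.3, seed = 12)
  rd <- simulate_reads(ref, counts, cfg, file.path(dir, "a"))
  fq <- readLines(rd$files[[1]])
  heads <- fq[seq(1, length(fq), 4)]
  seqs <- fq[seq(2, length(fq), 4)]
  starts <- as.integer(sub(".*start=", "", heads))
  # read length + start always equals the transcript length
  expect_true(all(nchar(seqs) + starts == 76L))
  # allowed starts are 0 or one past a modification site
  expect_true(all(starts %in% c(0L, ref$records$mod_sites[[1]]$pos + 1L)))
  # byte-identical on rerun with the same seed
  rd2 <- simulate_reads(ref, counts, cfg, file.path(dir, "b"))
  expect_identical(readLines(rd2$files[[1]]), fq)
})

test_that("gene-set simulator plants dependent-codon enrichment", {
  expect_error(simulate_gene_sets(multiplier = 0, seed = 1), "multiplier")
  # multiplier 1: target and background shares agree closely at large n
  gs1 <- simulate_gene_sets(n_background = 400, n_target = 400, multiplier = 1,
                            gene_length = 200, seed = 31)
  u1 <- codon_usage(gs1$cds)
  ala <- u1[u1$family == "Ala-AGC" & !is.na(u1$share), ]
  tgt <- ala$gene %in% gs1$gene_sets$target
  expect_lt(abs(mean(ala$share[tgt]) - mean(ala$share[!tgt])), 0.02)
  # multiplier 1.5: target share exceeds background share
  gs <- simulate_gene_sets(n_background = 400, n_target = 400, multiplier = 1.5,
                           gene_length = 200, seed = 32)
  u <- codon_usage(gs$cds)
  ala <- u[u$family == "Ala-AGC" & !is.na(u$share), ]
  tgt <- ala$gene %in% gs$gene_sets$target
  expect_gt(mean(ala$share[tgt]), mean(ala$share[!tgt]) + 0.03)
  expect_equal(gs$truth$multiplier, 1.5)
  # fixed seed -> identical sequences
  gs2 <- simulate_gene_sets(n_background = 400, n_target = 400, multiplier = 1.5,
                            gene_length = 200, seed = 32)
  expect_identical(gs$cds, gs2$cds)
})

test_that("coupled-delta generator hits its target rank correlation", {
  d <- simulate_coupled_deltas(n = 5000, rho = 0.5, seed = 4)
  expect_lt(abs(cor(d$delta_i34, d$delta_abundance, method = "spearman") - 0.5),
            0.05)
  # both margins centred below zero: losses, not gains
  expect_lt(mean(d$delta_i34), 0)
  expect_lt(mean(d$delta_abundance), 0)
  expect_identical(d, simulate_coupled_deltas(n = 5000, rho = 0.5, seed = 4))
})
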