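test_that("exact suffixes assign uniquely; family ties split fractionally", {
  # two same-family isodecoders sharing their 3' half, plus a distinct family
  seq_a1 <- paste0("GATTACAGAT", "AGC", "GGGGCTTCGA", "CCA")  # anticodon at 10
  seq_a2 <- paste0("CCGGTTAAGT", "AGC", "GGGGCTTCGA", "CCA")  # same 3' suffix
  seq_g  <- paste0("TTTTTTTTTT", "GCC", "AAAAAAAAAA", "CCA")
  rec <- data.frame(
    id = c("Ala-AGC-1", "Ala-AGC-2", "Gly-GCC-1"),
    sequence = c(seq_a1, seq_a2, seq_g),
    amino_acid = c("Ala", "Ala", "Gly"),
    anticodon = c("AGC", "AGC", "GCC"),
    anticodon_start = 10L,
    genome = "nuclear",
    mod_sites = "",
    stringsAsFactors = FALSE
  )
  dir <- withr::local_tempdir()
  paths <- write_mini_reference(dir, rec)
  ref <- load_reference(paths["fasta"], paths["annotation"])
  fq <- write_mini_fastq(file.path(dir, "t.fastq"), c(
    seq_a1,                          # full length, unique to Ala-AGC-1
    substr(seq_a1, 12, 26),          # shared suffix: ties Ala-AGC-1 / Ala-AGC-2
    seq_g,                           # unique to Gly-GCC-1
    paste0("GATTACAGAT", "GGC", "GGGGCTTCGA", "CCA")  # G at wobble: exempt
  ))
  asg <- assign_reads(fq, ref)
  expect_equal(asg$counts["Ala-AGC-1", 1], 1 + 0.5 + 1)  # incl. exempt-mismatch read
  expect_equal(asg$counts["Ala-AGC-2", 1], 0.5)
  expect_equal(asg$counts["Gly-GCC-1", 1], 1)
  expect_equal(asg$anticodon_counts["Ala-AGC", 1], 3)
  expect_equal(asg$read_summary$fractional, 1)
  # count conservation
  rs <- asg$read_summary
  expect_equal(rs$unique + rs$fractional + rs$ambiguous_cross_family + rs$unassigned,
               rs$total)
})

test_that("mismatch budget and exemptions behave per contract", {
  rec <- mini_records()
  dir <- withr::local_tempdir()
  paths <- write_mini_reference(dir, rec)
  ref <- load_reference(paths["fasta"], paths["annotation"])
  s <- ref$records$sequence[1]
  mutate_at <- function(x, i, b) { substr(x, i, i) <- b; x }
  reads <- c(
    mutate_at(s, 11, "G"),                      # wobble A->G: exempt, assigned
    mutate_at(mutate_at(s, 2, "C"), 3, "C"),    # 2 mismatches <= 3: assigned
    Reduce(function(x, i) mutate_at(x, i, "C"), c(2, 3, 4, 5), s)  # 4: unassigned
  )
  fq <- write_mini_fastq(file.path(dir, "m.fastq"), reads)
  asg <- assign_reads(fq, ref, max_mismatch = 3, rescue_indel = FALSE)
  expect_equal(unname(asg$counts["Ala-AGC-1", 1]), 2)
  expect_equal(asg$read_summary$unassigned, 1)
  # with mod_site_free off, the wobble mismatch costs 1 but stays within budget
  asg2 <- assign_reads(fq, ref, max_mismatch = 0, mod_site_free = FALSE)
  expect_equal(unname(asg2$counts["Ala-AGC-1", 1]), 0)
  # empty reference and unreadable FASTQ are hard errors
  expect_error(assign_reads(file.path(dir, "nope.fastq"), ref), "not found")
})

test_that("a single-indel read is rescued into counts but not pileups", {
  # non-repetitive sequence so a deletion cannot be absorbed as a shift
  rec <- data.frame(
    id = "Ala-AGC-1",
    sequence = paste0("GATTACAGAT", "AGC", "GGGGCTTCGA", "CCA"),
    amino_acid = "Ala", anticodon = "AGC", anticodon_start = 10L,
    genome = "nuclear", mod_sites = "5:m1G9", stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_mini_reference(dir, rec)
  ref <- load_reference(paths["fasta"], paths["annotation"])
  s <- ref$records$sequence[1]
  del_read <- paste0(substr(s, 1, 19), substr(s, 21, nchar(s)))  # one deletion
  fq <- write_mini_fastq(file.path(dir, "i.fastq"), del_read)
  asg <- assign_reads(fq, ref, max_mismatch = 3, rescue_indel = TRUE)
  expect_equal(unname(asg$counts["Ala-AGC-1", 1]), 1)
  expect_equal(asg$read_summary$indel_rescued, 1)
  expect_equal(sum(asg$pileups[, c("A", "C", "G", "T")]), 0)
  asg_no <- assign_reads(fq, ref, max_mismatch = 3, rescue_indel = FALSE)
  expect_equal(asg_no$read_summary$unassigned, 1)
})

test_that("assignment matches the exhaustive brute-force oracle on random reads", {
  ref <- simulate_reference(n_per_family = 2, seed = 19)
  cfg <- sim_config(ref, reads_per_replicate = 500, mis_rate = 0.15,
                    trunc_prob = 0.15, error_rate = 0.01,
                    n_replicates = c(case = 1),
                    theta_case = stats::setNames(
                      seq(0.05, 0.95, length.out = 16),
                      ref$records$id[ref$records$family %in%
                                       ref$families$family[ref$families$is_adat_target]]),
                    seed = 23)
  sc <- simulate_counts(ref, cfg)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(ref, sc$counts, cfg, dir)
  asg <- assign_reads(rd$files, ref)
  reads <- as.character(Biostrings::readDNAStringSet(rd$files[[1]], format = "fastq"))
  oracle_counts <- stats::setNames(numeric(nrow(ref$records)), ref$records$id)
  tallies <- c(unique = 0, fractional = 0, ambiguous_cross_family = 0, unassigned = 0)
  for (rd1 in reads) {
    o <- oracle_align_read(rd1, ref, max_mismatch = 3)
    tallies[o$outcome] <- tallies[o$outcome] + 1
    if (length(o$winners)) {
      oracle_counts[o$winners] <- oracle_counts[o$winners] + 1 / length(o$winners)
    }
  }
  expect_equal(asg$counts[, 1], oracle_counts)
  expect_equal(asg$read_summary$unique, unname(tallies["unique"]))
  expect_equal(asg$read_summary$fractional, unname(tallies["fractional"]))
  expect_equal(asg$read_summary$ambiguous_cross_family,
               unname(tallies["ambiguous_cross_family"]))
  expect_equal(asg$read_summary$unassigned, unname(tallies["unassigned"]))
})

test_that("pileup base counts never exceed coverage and respect truncation", {
  ref <- simulate_reference(n_per_family = 1, seed = 4)
  cfg <- sim_config(ref, reads_per_replicate = 2000, trunc_prob = 0.3,
                    n_replicates = c(control = 1), seed = 6)
  sc <- simulate_counts(ref, cfg)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(ref, sc$counts, cfg, dir)
  asg <- assign_reads(rd$files, ref)
  p <- pool_pileups(asg)
  cover <- rowSums(p[, c("A", "C", "G", "T")])
  # coverage is non-increasing toward the 5' end (reads anchored at 3')
  for (id in unique(p$id)) {
    cv <- cover[p$id == id]
    expect_true(all(diff(cv) >= 0))
  }
  # truncation starts sum to the number of assigned reads
  expect_equal(sum(p$trunc), asg$read_summary$unique + asg$read_summary$fractional)
})

test_that("qc metrics reflect planted truncation and CCA", {
  ref <- simulate_reference(n_per_family = 1, seed = 9)
  # single truncating site: full-length fraction ~ 1 - trunc_prob per site
  ms <- data.frame(pos = 57L, label = "m1A58")
  ref2 <- simulate_reference(n_per_family = 1, mod_sites = ms, seed = 9)
  cfg <- sim_config(ref2, reads_per_replicate = 4000, trunc_prob = 0.3,
                    error_rate = 0, n_replicates = c(control = 1), seed = 2)
  sc <- simulate_counts(ref2, cfg)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(ref2, sc$counts, cfg, dir)
  asg <- assign_reads(rd$files, ref2)
  qc <- qc_metrics(asg)
  overall <- qc[qc$sample == "all", ]
  expect_lt(abs(overall$full_length_fraction - 0.7), 0.03)
  expect_equal(overall$cca_fraction, 1)
  expect_equal(overall$nuclear_mapped_fraction, 1)
  expect_true(all(unlist(qc[, -1]) >= 0 & unlist(qc[, -1]) <= 1))
})

test_that("count TSVs round-trip fractional counts at full precision", {
  rec <- mini_records()
  dir <- withr::local_tempdir()
  paths <- write_mini_reference(dir, rec)
  ref <- load_reference(paths["fasta"], paths["annotation"])
  fq <- write_mini_fastq(file.path(dir, "w.fastq"), ref$records$sequence[1])
  asg <- assign_reads(c(s1 = fq), ref)
  out <- file.path(dir, "counts")
  pths <- write_counts(asg, out)
  iso <- read.delim(pths["isodecoder"], check.names = FALSE)
  expect_equal(names(iso), c("id", "s1"))
  expect_equal(iso$s1[iso$id == "Ala-AGC-1"], 1)
  ac <- read.delim(pths["anticodon"], check.names = FALSE)
  expect_equal(nrow(ac), 2L)
})
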