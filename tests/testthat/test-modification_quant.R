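make_wobble_pileup <- function(units, g, a, ref) {
  wi <- wobble_index(ref, units)
  data.frame(id = units, pos = unname(wi), A = a, C = 0, G = g, T = 0,
             trunc = 0, stringsAsFactors = FALSE)
}

test_that("I34 stoichiometry is G/(G+A) with Wilson interval and coverage gate", {
  ref <- simulate_reference(n_per_family = 1, seed = 2)
  ann <- ref$records$id[ref$records$family %in%
                          ref$families$family[ref$families$is_adat_target]]
  p <- make_wobble_pileup(ann[1:3], g = c(43, 5, 0), a = c(57, 0, 100), ref)
  calls <- call_i34(p, ref, min_coverage = 20, units = ann[1:3])
  expect_equal(calls$theta[1], 0.43)
  expect_equal(calls$status[2], "low_coverage")  # 5 reads < 20
  expect_true(is.na(calls$theta[2]))
  expect_equal(calls$theta[3], 0)
  # theta always inside its CI
  ok <- calls$status == "called"
  expect_true(all(calls$ci_lo[ok] <= calls$theta[ok] &
                    calls$theta[ok] <= calls$ci_hi[ok]))
  # C/T at the site are excluded from the denominator
  p2 <- make_wobble_pileup(ann[1], g = 40, a = 40, ref)
  p2$C <- 10; p2$T <- 10
  expect_equal(call_i34(p2, ref, units = ann[1])$theta, 0.5)
  # non-ANN unit requested -> error
  non_ann <- setdiff(ref$records$id, ann)[1]
  expect_error(call_i34(p, ref, units = non_ann), "not an ANN")
})

test_that("CI width shrinks monotonically with coverage", {
  ref <- simulate_reference(n_per_family = 1, seed = 2)
  ann <- ref$records$id[ref$records$family %in%
                          ref$families$family[ref$families$is_adat_target]]
  widths <- vapply(c(50, 200, 1000, 5000), function(n) {
    p <- make_wobble_pileup(ann[1], g = round(0.4 * n), a = n - round(0.4 * n), ref)
    cl <- call_i34(p, ref, units = ann[1])
    cl$ci_hi - cl$ci_lo
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("anticodon pooling equals calling on summed counts", {
  ref <- simulate_reference(n_per_family = 2, seed = 3)
  ala <- ref$records$id[ref$records$family == "Ala-AGC"]
  p <- make_wobble_pileup(ala, g = c(20, 240), a = c(80, 60), ref)
  calls <- call_i34(p, ref, units = ala)
  pool <- aggregate_anticodon(calls)
  ala_pool <- pool[pool$family == "Ala-AGC", ]
  # coverage-weighted mean: (0.2*100 + 0.8*300) / 400 = 0.65
  expect_equal(ala_pool$theta, 0.65)
  # identical to a direct call on the summed pileup
  psum <- make_wobble_pileup(ala[1], g = 260, a = 140, ref)
  direct <- call_i34(psum, ref, units = ala[1])
  expect_equal(ala_pool$theta, direct$theta)
  expect_equal(ala_pool$ci_lo, direct$ci_lo)
  expect_equal(ala_pool$ci_hi, direct$ci_hi)
  # single member pools to itself
  single <- aggregate_anticodon(calls[1, ])
  expect_equal(single$theta, calls$theta[1])
  # no called members -> low-coverage pool
  lowp <- make_wobble_pileup(ala, g = c(1, 2), a = c(1, 1), ref)
  low_calls <- call_i34(lowp, ref, units = ala)
  expect_equal(aggregate_anticodon(low_calls)$status, "low_coverage")
})

test_that("theta is invariant to splitting reads across replicates", {
  ref <- simulate_reference(n_per_family = 1, seed = 21)
  cfg <- sim_config(ref, reads_per_replicate = 3000,
                    n_replicates = c(control = 2),
                    theta_control = stats::setNames(
                      rep(0.6, 8),
                      ref$records$id[ref$records$family %in%
                                       ref$families$family[ref$families$is_adat_target]]),
                    seed = 13)
  sc <- simulate_counts(ref, cfg)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(ref, sc$counts, cfg, dir)
  asg <- assign_reads(rd$files, ref)
  pooled <- call_i34(pool_pileups(asg), ref)
  per_rep <- lapply(colnames(asg$counts), function(s) {
    call_i34(pool_pileups(asg, s), ref)
  })
  g_sum <- per_rep[[1]]$g + per_rep[[2]]$g
  cov_sum <- per_rep[[1]]$coverage + per_rep[[2]]$coverage
  expect_equal(pooled$g, g_sum)
  expect_equal(pooled$theta, g_sum / cov_sum)
})

test_that("delta_mod reports percentage points and excludes low coverage", {
  ref <- simulate_reference(n_per_family = 1, seed = 2)
  ann <- ref$records$id[ref$records$family %in%
                          ref$families$family[ref$families$is_adat_target]]
  ctrl <- call_i34(make_wobble_pileup(ann[1:3], g = c(1000, 500, 3), a = c(0, 500, 2), ref),
                   ref, units = ann[1:3])
  case <- call_i34(make_wobble_pileup(ann[1:3], g = c(430, 500, 400), a = c(570, 500, 600), ref),
                   ref, units = ann[1:3])
  d <- delta_mod(case, ctrl)
  expect_equal(d$delta_pp[d$unit == ann[1]], -57)
  expect_equal(d$delta_pp[d$unit == ann[2]], 0)
  expect_false(ann[3] %in% d$unit)  # low coverage on the control side
  expect_equal(attr(d, "excluded"), ann[3])
  # identical inputs -> all-zero deltas
  d0 <- delta_mod(ctrl, ctrl)
  expect_true(all(d0$delta_pp == 0))
  expect_error(delta_mod(case[0, ], ctrl), "no shared units")
})

test_that("mod_profile quantifies misincorporation and truncation at other sites", {
  ref <- simulate_reference(n_per_family = 1, seed = 17)
  cfg <- sim_config(ref, reads_per_replicate = 6000, mis_rate = 0.2,
                    trunc_prob = 0.1, error_rate = 0,
                    n_replicates = c(control = 1), seed = 5)
  sc <- simulate_counts(ref, cfg)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(ref, sc$counts, cfg, dir)
  asg <- assign_reads(rd$files, ref)
  prof <- mod_profile(pool_pileups(asg), ref)
  expect_true(all(prof$pos %in% c(8, 25, 36, 57)))
  agg <- tapply(prof$misincorporation, prof$pos, mean)
  expect_true(all(abs(agg - 0.2) < 0.05))
})

test_that("deamination curves reproduce the relative-activity arithmetic", {
  tab <- data.frame(enzyme = c("WT", "WT", "mut", "mut"),
                    concentration = c(0.1, 1, 0.1, 1),
                    G = c(500, 1000, 160, 600), A = c(500, 0, 840, 400))
  dc <- deamination_curve(tab)
  expect_equal(dc$fraction[dc$enzyme == "WT" & dc$concentration == 1], 1)
  # mutant at 0.32x the WT fraction: -68 percent relative activity
  expect_equal(dc$percent_change[dc$enzyme == "mut" & dc$concentration == 0.1], -68)
  # reference enzyme is always at 0 percent change
  expect_true(all(dc$percent_change[dc$enzyme == "WT"] == 0))
  # identical enzymes -> all zero
  tab2 <- tab; tab2$G[3:4] <- tab$G[1:2]; tab2$A[3:4] <- tab$A[1:2]
  expect_true(all(deamination_curve(tab2)$percent_change == 0))
  # zero-total rows are flagged and excluded
  tab3 <- rbind(tab, data.frame(enzyme = "mut", concentration = 5, G = 0, A = 0))
  dc3 <- deamination_curve(tab3)
  expect_true(dc3$excluded[nrow(dc3)])
  expect_true(is.na(dc3$fraction[nrow(dc3)]))
  expect_error(deamination_curve(tab, reference = "nope"), "not present")
})

test_that("packaged synthetic assay table reports the printed activity losses", {
  path <- system.file("extdata", "deamination_assay_synthetic.tsv",
                      package = "wobbleseq")
  dc <- deamination_curve(path)
  lowest <- dc[dc$concentration == min(dc$concentration), ]
  expect_equal(lowest$percent_change[lowest$enzyme == "V128M"], -68)
  expect_equal(lowest$percent_change[lowest$enzyme == "A180L"], -76)
  # A180V retains near-WT activity across the series
  expect_true(all(abs(dc$percent_change[dc$enzyme == "A180V"]) < 5))
})
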