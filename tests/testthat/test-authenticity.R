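test_that("every ancient body passes the researcher contamination screen", {
  mt <- read_mt_haplotypes(palaeokin_file("mt_haplotypes.tsv"))
  bodies <- unique(mt$table$sample[mt$table$role == "body"])
  refs <- mt$haplotypes[unique(mt$table$sample[mt$table$role == "researcher"])]
  expect_length(refs, 5)
  for (b in bodies) {
    hits <- screen_contamination(mt$haplotypes[[b]], refs)
    expect_equal(nrow(hits), 0, label = b)
  }
})

test_that("a matching or near-matching reference is flagged at the set radius", {
  mt <- read_mt_haplotypes(palaeokin_file("mt_haplotypes.tsv"))
  refs <- mt$haplotypes[c("LabWorker1", "LabWorker2")]
  # identical to a reference
  clone <- mt$haplotypes$LabWorker1
  clone$sample_id <- "suspect"
  hits <- screen_contamination(clone, refs)
  expect_equal(hits$reference, "LabWorker1")
  expect_equal(hits$distance, 0L)
  # one substitution away: invisible at radius 0, flagged at radius 1
  near <- mt_haplotype("near", hvr1 = "16223T 16362C 16311C",
                       hvr2 = "73G 195C 198T 263G 315+C")
  expect_equal(nrow(screen_contamination(near, refs, max_distance = 0)), 0)
  hits1 <- screen_contamination(near, refs, max_distance = 1)
  expect_equal(hits1$reference, "LabWorker1")
  expect_equal(hits1$distance, 1L)
  expect_error(screen_contamination(clone, list()), "empty")
})

make_clone_sets <- function(direct, damaged, n_in = 5, n_act = 4) {
  list(inactive = clone_set(direct$sample_id, "inactive_udg",
                            replicate(n_in, damaged, simplify = FALSE)),
       active = clone_set(direct$sample_id, "active_udg",
                          replicate(n_act, direct, simplify = FALSE)))
}

test_that("a UDG-reverted C-to-T transition is called at 16,250 and only there", {
  ref <- hvr_ref()$HVR1_synthetic
  r1 <- hvr1_region()
  direct <- mt_haplotype("MN0376", hvr1 = "16223T 16234T 16299G 16362C")
  damaged <- mt_haplotype("MN0376", hvr1 = "16223T 16234T 16250T 16299G 16362C")
  cs <- make_clone_sets(direct, damaged)
  calls <- detect_damage(direct, cs$active, cs$inactive, ref, r1)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 16250L)
  expect_equal(calls$change, "C>T")
  expect_true(calls$reverted_by_udg)
  expect_equal(attr(calls, "clone_fractions"), 1)
  expect_equal(nrow(attr(calls, "anomalies")), 0)
})

test_that("identical treatment arms yield no damage calls", {
  ref <- hvr_ref()$HVR1_synthetic
  r1 <- hvr1_region()
  direct <- mt_haplotype("s", hvr1 = "16223T 16362C")
  cs <- make_clone_sets(direct, direct)
  expect_equal(nrow(detect_damage(direct, cs$active, cs$inactive, ref, r1)), 0)
})

test_that("swapping the treatment arms produces no reverted calls", {
  ref <- hvr_ref()$HVR1_synthetic
  r1 <- hvr1_region()
  direct <- mt_haplotype("MN0376", hvr1 = "16223T 16234T 16299G 16362C")
  damaged <- mt_haplotype("MN0376", hvr1 = "16223T 16234T 16250T 16299G 16362C")
  cs <- make_clone_sets(direct, damaged)
  swapped <- detect_damage(direct, active = cs$inactive, inactive = cs$active,
                           ref, r1)
  expect_false(any(swapped$reverted_by_udg))
})

test_that("non-deamination discrepancies are anomalies, not damage calls", {
  ref <- hvr_ref()$HVR1_synthetic
  r1 <- hvr1_region()
  direct <- mt_haplotype("s", hvr1 = "16223T")
  # reference at 16249 is A in the synthetic segment: an A-to-G change is not
  # deamination-consistent
  odd <- mt_haplotype("s", hvr1 = "16223T 16249G")
  cs <- make_clone_sets(direct, odd)
  calls <- detect_damage(direct, cs$active, cs$inactive, ref, r1)
  expect_equal(nrow(calls), 0)
  anom <- attr(calls, "anomalies")
  expect_equal(anom$position, 16249L)
})

test_that("planted simulated damage is recovered exactly at consensus level", {
  ref <- hvr_ref()$HVR1_synthetic
  r1 <- hvr1_region()
  direct <- mt_haplotype("sim", hvr1 = "16223T 16299G")
  sim <- simulate_deamination(direct, ref, r1, damage_rate = 0.6,
                              n_inactive = 5, n_active = 4, seed = 77)
  calls <- detect_damage(direct, sim$active, sim$inactive, ref, r1)
  # expected: positions damaged in a strict majority of the 5 clones
  planted_major <- as.integer(names(which(
    table(sim$planted$position) / 5 > 0.5)))
  expect_setequal(calls$position, planted_major)
  expect_true(all(calls$change %in% c("C>T", "G>A")))
  expect_true(all(calls$reverted_by_udg))
  # rate 0 leaves the arms identical; rate 1 damages every eligible base
  sim0 <- simulate_deamination(direct, ref, r1, damage_rate = 0, seed = 1)
  expect_equal(nrow(sim0$planted), 0)
  calls0 <- detect_damage(direct, sim0$active, sim0$inactive, ref, r1)
  expect_equal(nrow(calls0), 0)
})

test_that("simulated per-position damage fractions match the binomial rate", {
  ref <- hvr_ref()$HVR1_synthetic
  r1 <- hvr1_region()
  direct <- mt_haplotype("sim", hvr1 = "")
  rate <- 0.3
  depth <- 20
  sim <- simulate_deamination(direct, ref, r1, damage_rate = rate,
                              n_inactive = depth, n_active = 4, seed = 11)
  n_eligible <- sum(strsplit(ref$seq, "")[[1]] %in% c("C", "G"))
  trials <- n_eligible * depth
  est <- nrow(sim$planted) / trials
  se <- sqrt(rate * (1 - rate) / trials)
  expect_lt(abs(est - rate), 3 * se)
})
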