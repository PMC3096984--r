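test_that("greedy start picks the highest-probability candidate per bin", {
  cfg <- panel_config(min_score = NULL, prob_map = step_map(0.85, 0.95),
                      time_limit_s = 5)
  snps <- mk_snps(c("hi", "lo"), score = c(0.9, 0.1))
  bins <- mk_bins(list(c("hi", "lo")))
  panel <- pick_panel(bins, snps, cfg)
  expect_equal(panel$selected, "hi")
})

test_that("multi-population greedy prefers tags covering more populations (NPtag)", {
  cfg <- base_cfg()
  bins <- tibble::tibble(
    bin_id = c("b1", "b1"), population = c("CEU", "YRI"),
    n_snps_in_bin = 2L,
    candidates = list(c("shared", "ceuOnly"), c("shared", "yriOnly"))
  )
  snps <- mk_snps(c("shared", "ceuOnly", "yriOnly"), pos = c(1e3, 5e3, 9e3))
  panel <- pick_panel(bins, snps, cfg)
  # equal probabilities: the NPtag-2 shared tag covers both bins alone
  expect_equal(panel$selected, "shared")
  expect_equal(panel$summary$n_tagged, 2)
})

test_that("phase 2 rescues bins whose only candidates were deferred by phase 1", {
  # infinium mode: bin b2's only candidate is A/T (two beads, skipped in
  # phase 1); coverage dominates bead cost so phase 2 must add it
  cfg <- base_cfg(infinium = TRUE, time_limit_s = 0)  # stop after phase 2
  snps <- snp_table(c("rs1", "rsAT"), "chr1", c(1e3, 5e3),
                    c("A", "A"), c("G", "T"), 0.9, "validated", "other")
  bins <- mk_bins(list("rs1", "rsAT"))
  panel <- pick_panel(bins, snps, cfg)
  expect_setequal(panel$selected, c("rs1", "rsAT"))
  expect_equal(panel$summary$bead_type_total, 3L)
  expect_true(all(panel$run_log$phase_reached == "phase2"))
})

test_that("of a conflicting pair the selection with the better objective wins", {
  # rsX (bin weight 3) conflicts with rsY (bin weight 1): only one of the two
  # bins can be tagged and the optimizer must keep the heavier bin
  cfg <- base_cfg()
  snps <- mk_snps(c("rsX", "rsY"), pos = c(1000, 1030))
  bins <- tibble::tibble(
    bin_id = c("bBig", "bSmall"), population = "CEU",
    n_snps_in_bin = c(9L, 2L),
    candidates = list(c("rsX"), c("rsY"))
  )
  cfg_w <- panel_config(min_score = NULL, prob_map = flat_map(0.9),
                        bin_weight = "bin_members", time_limit_s = 5)
  panel <- pick_panel(bins, snps, cfg_w)
  expect_equal(panel$selected, "rsX")
  expect_equal(panel$summary$n_tagged, 1)
  un <- panel$untagged
  expect_equal(un$reason[un$snp_id == "rsY"], "proximity_conflict")
})

test_that("two runs on identical input produce identical panels", {
  inst <- fuzz_instance(5, n_bins = 10)
  cfg <- fuzz_config(inst)
  p1 <- pick_panel(inst$bins, inst$snps, cfg)
  p2 <- pick_panel(inst$bins, inst$snps, cfg)
  expect_identical(tidy(p1), tidy(p2))
  expect_identical(p1$untagged, p2$untagged)
})

test_that("permuting bin order leaves the selected panel unchanged", {
  inst <- fuzz_instance(9, n_bins = 10)
  cfg <- fuzz_config(inst)
  p1 <- pick_panel(inst$bins, inst$snps, cfg)
  set.seed(1)
  p2 <- pick_panel(inst$bins[sample.int(nrow(inst$bins)), ], inst$snps, cfg)
  expect_setequal(p1$selected, p2$selected)
  expect_equal(p1$summary$panel_score, p2$summary$panel_score,
               tolerance = 1e-9)
})

test_that("a zero time budget returns the phase-2 solution and never exceeds a longer run", {
  for (seed in c(3, 14, 27)) {
    inst <- fuzz_instance(seed, n_bins = 8)
    cfg0 <- fuzz_config(inst, time_limit_s = 0)
    cfg_full <- fuzz_config(inst, time_limit_s = 30)
    p0 <- pick_panel(inst$bins, inst$snps, cfg0)
    pf <- pick_panel(inst$bins, inst$snps, cfg_full)
    expect_true(all(p0$run_log$phase_reached == "phase2"))
    expect_false(any(p0$run_log$exhausted))
    expect_true(all(pf$run_log$exhausted | pf$run_log$approximate))
    for (k in seq_len(nrow(p0$run_log))) {
      cmp <- compare_objectives(obj_from_log(p0$run_log, k),
                                obj_from_log(pf$run_log, k))
      expect_lte(cmp, 0)  # a longer budget never returns a worse objective
    }
  }
})

test_that("clusters with more than 31 candidates use the approximate search", {
  ids <- sprintf("t%02d", 1:32)
  snps <- mk_snps(ids, pos = (1:32) * 1e4, score = stats::runif(32, 0.5, 1))
  bins <- mk_bins(list(ids), n_snps_in_bin = 40L)
  cfg <- base_cfg()
  panel <- pick_panel(bins, snps, cfg)
  expect_equal(panel$run_log$phase_reached, "approximate")
  expect_false(panel$run_log$exhausted)
  expect_equal(panel$summary$n_tagged, 1)
  check_hard_constraints(panel, cfg)
})

test_that("forced approximate mode respects constraints and never beats the oracle", {
  for (seed in c(2, 8, 21)) {
    inst <- fuzz_instance(seed, n_bins = 8)
    cfg <- fuzz_config(inst, force_approximate = TRUE)
    panel <- pick_panel(inst$bins, inst$snps, cfg)
    check_hard_constraints(panel, cfg)
    expect_true(all(panel$run_log$phase_reached == "approximate"))
    or <- brute_force_optimum(inst$bins, inst$snps, cfg)
    for (k in seq_len(nrow(panel$run_log))) {
      cmp <- compare_objectives(obj_from_log(panel$run_log, k),
                                obj_from_oracle(or$clusters, k))
      expect_lte(cmp, 0)
    }
  }
})

test_that("obligates are seeded first; conflicting obligates resolve by objective", {
  cfg <- panel_config(min_score = NULL, prob_map = step_map(0.5, 0.95),
                      bin_weight = "bin_members", time_limit_s = 5)
  # obligate with a terrible score still enters the panel
  snps <- mk_snps(c("ob", "good"), score = c(0.1, 0.9))
  bins <- mk_bins(list(c("ob", "good")))
  panel <- pick_panel(bins, snps, cfg, obligates = "ob")
  expect_equal(panel$selected, "ob")

  # two obligates in proximity conflict: the one tagging the heavier bin wins
  snps2 <- mk_snps(c("obA", "obB"), pos = c(1000, 1030), score = 0.9)
  bins2 <- tibble::tibble(
    bin_id = c("big", "small"), population = "CEU",
    n_snps_in_bin = c(8L, 2L), candidates = list("obA", "obB")
  )
  panel2 <- pick_panel(bins2, snps2, cfg, obligates = c("obA", "obB"))
  expect_equal(panel2$selected, "obA")
  expect_equal(panel2$summary$dropped_obligates, "obB")
  expect_equal(panel2$untagged$reason[panel2$untagged$snp_id == "obB"],
               "proximity_conflict")
})

test_that("emitted solutions always satisfy the hard-constraint suite", {
  for (seed in 31:40) {
    inst <- fuzz_instance(seed, n_bins = 8, at_cg_fraction = 0.3)
    for (infinium in c(FALSE, TRUE)) {
      cfg <- fuzz_config(inst, infinium = infinium)
      panel <- pick_panel(inst$bins, inst$snps, cfg)
      check_hard_constraints(panel, cfg)
    }
  }
})

test_that("disjoint clusters are optimized independently of each other", {
  cfg <- base_cfg()
  snps <- mk_snps(paste0("rs", 1:4), pos = c(1e3, 2e6, 4e6, 6e6))
  bins_a <- mk_bins(list("rs1", "rs2"), bin_id = c("a1", "a2"))
  bins_b <- mk_bins(list("rs3", "rs4"), bin_id = c("b1", "b2"))
  joint <- pick_panel(dplyr::bind_rows(bins_a, bins_b), snps, cfg)
  pa <- pick_panel(bins_a, snps[1:2, ], cfg)
  pb <- pick_panel(bins_b, snps[3:4, ], cfg)
  expect_setequal(joint$selected, c(pa$selected, pb$selected))
  expect_equal(joint$summary$panel_score,
               pa$summary$panel_score + pb$summary$panel_score,
               tolerance = 1e-12)
})
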