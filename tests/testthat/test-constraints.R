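test_that("probability mapping is a deterministic discrete table lookup", {
  pm <- tibble::tibble(
    score_low = c(0, 0.5, 0, 0.5),
    score_high = c(0.5, Inf, 0.5, Inf),
    confidence_class = rep(c("validated", "unvalidated"), each = 2),
    probability = c(0.7, 0.95, 0.5, 0.85)
  )
  cfg <- panel_config(prob_map = pm)
  snps <- mk_snps(c("a", "b", "c", "d"),
                  score = c(0.9, 0.9, 0.2, NA),
                  conf = c("validated", "validated", "unvalidated",
                           "validated"))
  out <- snp_probability(snps, cfg)
  expect_equal(out$probability[1], 0.95)
  # two SNPs in the same cell share the same discrete probability
  expect_identical(out$probability[1], out$probability[2])
  expect_equal(out$probability[3], 0.5)
  # missing score (-99 sentinel) clamps to the lowest interval
  expect_equal(out$probability[4], 0.7)
})

test_that("interval boundaries are left-closed and uncovered cells error", {
  pm <- tibble::tibble(score_low = c(0.2, 0.5), score_high = c(0.5, 1),
                       confidence_class = "validated",
                       probability = c(0.6, 0.9))
  cfg <- panel_config(prob_map = pm)
  lk <- function(s) {
    snp_probability(mk_snps("x", score = s), cfg)$probability
  }
  expect_equal(lk(0.5), 0.9)    # left-closed at the boundary
  expect_equal(lk(0.499), 0.6)
  expect_equal(lk(0.05), 0.6)   # below lowest bound: lowest interval
  expect_error(lk(1.5), "not covered", class = "tagpanel_bad_input")
  expect_error(
    snp_probability(mk_snps("x", conf = "weird"), cfg),
    "weird", class = "tagpanel_bad_input"
  )
})

test_that("bead typing is total over the six allele pairs", {
  pairs <- utils::combn(c("A", "C", "G", "T"), 2)
  beads <- bead_types(pairs[1, ], pairs[2, ])
  two <- (pairs[1, ] == "A" & pairs[2, ] == "T") |
    (pairs[1, ] == "C" & pairs[2, ] == "G")
  expect_identical(beads, ifelse(two, 2L, 1L))
  expect_identical(sum(beads == 2L), 2L)       # exactly {A,T} and {C,G}
  # order and case invariance
  expect_identical(bead_types("T", "a"), 2L)
  expect_identical(bead_types("g", "A"), 1L)
})

test_that("conflict edges follow the bp cutoff definition exactly", {
  snps <- mk_snps(c("a", "b", "c", "d"),
                  pos = c(100, 160, 161, 100),
                  chrom = c("chr1", "chr1", "chr1", "chr2"))
  cfg <- panel_config(distance_cutoff_bp = 60)
  e <- build_conflict_graph(snps, cfg)
  # 100 vs 160: separated by exactly 60 bp => conflict (closer than 61 bp)
  expect_true(any(e$snp_a == "a" & e$snp_b == "b"))
  # 100 vs 161: more than 60 bp apart => allowed
  expect_false(any(e$snp_a == "a" & e$snp_b == "c"))
  # same positions on different chromosomes never conflict
  expect_false(any(e$snp_a == "a" & e$snp_b == "d"))
})

test_that("sweep-built conflict graph matches the quadratic pair scan on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:40, 1)
    snps <- mk_snps(sprintf("s%02d", 1:n),
                    pos = sample.int(2000, n),
                    chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    cutoff <- sample(c(0, 10, 60, 150), 1)
    got <- build_conflict_graph(snps, panel_config(distance_cutoff_bp = cutoff))
    want <- scan_conflicts(snps, cutoff)
    expect_equal(as.data.frame(got), as.data.frame(want))
    # input order invariance
    perm <- snps[sample.int(n), ]
    got2 <- build_conflict_graph(perm, panel_config(distance_cutoff_bp = cutoff))
    expect_equal(as.data.frame(got2), as.data.frame(got))
  }
})

test_that("filtering removes low-score and excluded candidates and is idempotent", {
  snps <- mk_snps(c("rs1", "rs2", "rs3", "rs4"),
                  score = c(0.39, 0.9, 0.9, NA))
  snps <- flag_snps(snps, excluded = "rs3")
  bins <- mk_bins(list(c("rs1", "rs2"), c("rs3", "rs4")))
  cfg <- panel_config(min_score = 0.4, prob_map = flat_map(0.9))
  snps <- snp_probability(snps, cfg)
  snps <- snp_functional_rank(snps, cfg)
  filt <- filter_candidates(bins, snps, cfg)
  expect_equal(filt$bins$candidates[[1]], "rs2")
  expect_equal(filt$bins$candidates[[2]], character())  # retained, untagged
  expect_setequal(filt$exclusions$reason[filt$exclusions$snp_id == "rs1"],
                  "below_min_score")
  expect_setequal(filt$exclusions$reason[filt$exclusions$snp_id == "rs3"],
                  "user_excluded")
  expect_setequal(filt$exclusions$reason[filt$exclusions$snp_id == "rs4"],
                  "below_min_score")   # missing score fails the filter
  again <- filter_candidates(filt$bins, snps, cfg)
  expect_equal(again$bins$candidates, filt$bins$candidates)
  expect_equal(again$bins$n_candidates_prefilter,
               filt$bins$n_candidates_prefilter)
  expect_equal(nrow(again$exclusions), 0)
})

test_that("previously genotyped tag SNPs cover their bins", {
  snps <- mk_snps(c("rs1", "rs2", "rs9"), score = 0.9)
  snps <- flag_snps(snps, pregenotyped = "rs9")
  bins <- mk_bins(list(c("rs1", "rs9"), "rs2"))
  cfg <- base_cfg()
  panel <- pick_panel(bins, snps, cfg, pregenotyped = "rs9")
  # the covered bin needs zero new tags and counts as tagged
  expect_equal(panel$summary$n_tagged, 2)
  expect_false("rs9" %in% panel$selected)
  expect_false("rs1" %in% panel$selected)
  expect_equal(panel$selected, "rs2")
  expect_equal(panel$summary$tag_deficit, 0)
})

test_that("an obligate SNP removed by a filter is a contradiction", {
  snps <- mk_snps(c("rs1", "rs2"), score = c(0.2, 0.9))
  bins <- mk_bins(list(c("rs1", "rs2")))
  cfg <- panel_config(min_score = 0.4, prob_map = flat_map(0.9))
  expect_error(pick_panel(bins, snps, cfg, obligates = "rs1"),
               "rs1", class = "tagpanel_bad_input")
  expect_error(pick_panel(bins, snps, cfg, obligates = "rs2",
                          excluded = "rs2"),
               class = "tagpanel_bad_input")
})

test_that("conflict_all_snps removes candidates near annotated non-candidates", {
  snps <- mk_snps(c("rs1", "rs2", "bg"), pos = c(100, 5000, 130))
  bins <- mk_bins(list(c("rs1", "rs2")))
  cfg <- base_cfg(conflict_all_snps = TRUE)
  panel <- pick_panel(bins, snps, cfg)
  expect_false("rs1" %in% panel$selected)  # within 60 bp of background SNP
  expect_equal(panel$selected, "rs2")
  expect_true(any(panel$exclusions$snp_id == "rs1" &
                    panel$exclusions$reason == "proximity_conflict"))
})
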