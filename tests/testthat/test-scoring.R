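test_that("p_tagged_bin equals the outcome-enumeration oracle", {
  expect_equal(p_tagged_bin(0.9), 0.9)
  expect_equal(p_tagged_bin(numeric()), 0)
  expect_equal(p_tagged_bin(c(0.9, 0.8)), enumerate_p_any(c(0.9, 0.8)))
  expect_equal(p_tagged_bin(c(0.9, 0.8)), 0.98)
  expect_equal(p_tagged_bin(numeric(), covered = TRUE), 1)
  set.seed(7)
  for (k in 1:10) {
    p <- round(stats::runif(k, 0.05, 1), 3)
    expect_equal(p_tagged_bin(p), enumerate_p_any(p), tolerance = 1e-12)
  }
  # monotone non-decreasing in the selected set
  set.seed(8)
  for (i in 1:20) {
    p <- stats::runif(sample(1:6, 1))
    extra <- stats::runif(1)
    expect_gte(p_tagged_bin(c(p, extra)) + 1e-15, p_tagged_bin(p))
  }
})

test_that("the cluster score matches hand-evaluated cases exactly", {
  cfg <- panel_config(min_score = NULL, prob_map = flat_map(0.9))
  # one bin weighted 3 (three candidates), one selected tag p = 0.9
  bins <- mk_bins(list(c("rs1", "rs2", "rs3")), n_snps_in_bin = 5L)
  snps <- mk_snps(c("rs1", "rs2", "rs3"), pos = c(1e3, 5e3, 9e3))
  expect_equal(cluster_score(bins, snps, "rs1", cfg), 2.7,
               tolerance = 1e-12)
  # same selection, Infinium mode, the tag is A/T: bead denominator 2
  cfg_inf <- panel_config(min_score = NULL, prob_map = flat_map(0.9),
                          infinium = TRUE)
  snps_at <- mk_snps(c("rs1", "rs2", "rs3"), pos = c(1e3, 5e3, 9e3),
                     allele1 = c("A", "A", "A"), allele2 = c("T", "G", "G"))
  expect_equal(cluster_score(bins, snps_at, "rs1", cfg_inf), 1.35,
               tolerance = 1e-12)
})

test_that("a tag shared across populations counts once in the denominator", {
  cfg <- panel_config(min_score = NULL, prob_map = flat_map(0.8))
  bins <- tibble::tibble(
    bin_id = c("b1", "b1"), population = c("CEU", "YRI"),
    n_snps_in_bin = 3L,
    candidates = list(c("rsS", "rsA"), c("rsS", "rsB"))
  )
  snps <- mk_snps(c("rsS", "rsA", "rsB"), pos = c(1e3, 5e3, 9e3))
  # both bins weighted 2 (two candidates each), shared tag assayed once:
  # (2 * 0.8 + 2 * 0.8) / 1
  expect_equal(cluster_score(bins, snps, "rsS", cfg), 3.2, tolerance = 1e-12)
})

test_that("with unit probabilities and one tag per bin the score is the mean bin weight", {
  cfg <- panel_config(min_score = NULL, prob_map = flat_map(1))
  bins <- mk_bins(list(c("rs1", "rs2"), c("rs3", "rs4", "rs5"), "rs6"))
  snps <- mk_snps(paste0("rs", 1:6), pos = (1:6) * 1e4)
  sel <- c("rs1", "rs3", "rs6")
  expect_equal(cluster_score(bins, snps, sel, cfg), (2 + 3 + 1) / 3,
               tolerance = 1e-12)
})

test_that("tag deficit applies the too-few-candidates and probability-cap exemptions", {
  snps <- mk_snps(paste0("rs", 1:4), pos = (1:4) * 1e4)
  cfg2 <- panel_config(min_score = NULL, prob_map = flat_map(0.9),
                       max_tags_per_bin = 2)
  # bin with a single candidate: expected tags capped at 1, no deficit
  bins1 <- mk_bins(list("rs1"))
  ct <- coverage_tuple(bins1, snps, "rs1", cfg2)
  expect_equal(unname(ct["deficit"]), 0)
  # probability cap reached with one tag exempts the second
  cfg_cap <- panel_config(min_score = NULL, prob_map = flat_map(0.995),
                          max_tags_per_bin = 2, max_bin_probability = 0.99)
  bins2 <- mk_bins(list(c("rs1", "rs2", "rs3")))
  ct2 <- coverage_tuple(bins2, snps, "rs1", cfg_cap)
  expect_equal(unname(ct2["deficit"]), 0)
  # three candidates, cap 1.0, only one of two expected tags selected
  ct3 <- coverage_tuple(bins2, snps, "rs1", cfg2)
  expect_equal(unname(ct3["deficit"]), 1)
})

test_that("the lexicographic comparator is a strict weak order", {
  set.seed(42)
  tuples <- replicate(60, c(
    tagged = sample(0:3, 1), obligates = sample(0:2, 1),
    neg_deficit = -sample(0:2, 1),
    score = sample(c(0, 0.5, 1.25, 1.25 + 1e-12, 2.7), 1),
    functional = sample(0:5, 1)
  ), simplify = FALSE)
  for (a in tuples) {
    expect_identical(compare_objectives(a, a), 0L)  # irreflexive strictness
  }
  for (i in seq_along(tuples)) {
    for (j in seq_along(tuples)) {
      cij <- compare_objectives(tuples[[i]], tuples[[j]])
      expect_identical(cij, -compare_objectives(tuples[[j]], tuples[[i]]))
    }
  }
  # transitivity of "better or equivalent"
  idx <- sample(seq_along(tuples), 12)
  for (i in idx) {
    for (j in idx) {
      for (k in idx) {
        if (compare_objectives(tuples[[i]], tuples[[j]]) >= 0 &&
            compare_objectives(tuples[[j]], tuples[[k]]) >= 0) {
          expect_gte(compare_objectives(tuples[[i]], tuples[[k]]), 0)
        }
      }
    }
  }
})

test_that("incremental contributions reflect removing each tag from the panel score", {
  cfg <- base_cfg()
  # singleton cluster: the sole tag's contribution is the whole cluster score
  snps <- mk_snps(c("rs1", "rs2", "rs3"), pos = c(1e3, 2e6, 4e6))
  bins <- mk_bins(list("rs1", "rs2", "rs3"))
  panel <- pick_panel(bins, snps, cfg)
  rep <- tidy(panel)
  for (i in seq_len(nrow(rep))) {
    k <- rep$cluster_id[i]
    expect_equal(rep$incremental_score[i],
                 panel$run_log$cluster_score[panel$run_log$cluster_id == k],
                 tolerance = 1e-12)
  }
  # removing one of two tags in a bin can increase the score (denominator
  # shrinks): the signed delta is reported
  cfg2 <- panel_config(min_score = NULL, prob_map = step_map(0.3, 0.9),
                       max_tags_per_bin = 2, time_limit_s = 5)
  snps2 <- mk_snps(c("hi", "lo"), pos = c(1e3, 5e3), score = c(0.9, 0.1))
  bins2 <- mk_bins(list(c("hi", "lo")))
  panel2 <- pick_panel(bins2, snps2, cfg2)
  rep2 <- tidy(panel2)
  if (nrow(rep2) == 2) {
    expect_true(any(rep2$incremental_score < 0))
  }
  # panel score is the sum of cluster scores regardless of order
  expect_equal(panel$summary$panel_score,
               sum(panel$run_log$cluster_score), tolerance = 1e-12)
})
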