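# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data.

# flat probability map: every score maps to `prob` for the given classes
flat_map <- function(prob = 0.9, classes = c("validated", "unvalidated")) {
  tibble::tibble(score_low = 0, score_high = Inf,
                 confidence_class = rep(classes, each = length(prob)),
                 probability = rep(prob, length(classes)))
}

# two-level map: score < 0.5 -> lo, score >= 0.5 -> hi (both classes)
step_map <- function(lo = 0.7, hi = 0.9) {
  tibble::tibble(score_low = c(0, 0.5, 0, 0.5),
                 score_high = c(0.5, Inf, 0.5, Inf),
                 confidence_class = rep(c("validated", "unvalidated"),
                                        each = 2),
                 probability = c(lo, hi, lo, hi))
}

mk_snps <- function(ids, pos = NULL, score = 0.9, chrom = "chr1",
                    allele1 = "A", allele2 = "G", conf = "validated",
                    func = "other") {
  n <- length(ids)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  snp_table(ids, rep_len(chrom, n), pos,
            rep_len(allele1, n), rep_len(allele2, n),
            rep_len(score, n), rep_len(conf, n), rep_len(func, n))
}

mk_bins <- function(candidates, population = "CEU", bin_id = NULL,
                    n_snps_in_bin = NULL) {
  nb <- length(candidates)
  if (is.null(bin_id)) bin_id <- paste0("b", seq_len(nb))
  if (is.null(n_snps_in_bin)) n_snps_in_bin <- lengths(candidates) + 1L
  tibble::tibble(bin_id = bin_id,
                 population = rep_len(population, nb),
                 n_snps_in_bin = as.integer(n_snps_in_bin),
                 candidates = candidates)
}

base_cfg <- function(...) {
  args <- list(min_score = NULL, prob_map = flat_map(0.9), time_limit_s = 10)
  over <- list(...)
  for (nm in names(over)) args[nm] <- list(over[[nm]])
  do.call(panel_config, args)
}

# objective vector (internal convention) from a run-log row
obj_from_log <- function(log, k) {
  c(tagged = log$n_tagged[k], obligates = log$n_obligates[k],
    neg_deficit = -log$tag_deficit[k], score = log$cluster_score[k],
    functional = log$functional_sum[k])
}

obj_from_oracle <- function(oc, k) {
  c(tagged = oc$tagged[k], obligates = oc$obligates[k],
    neg_deficit = -oc$deficit[k], score = oc$score[k],
    functional = oc$functional[k])
}

expect_obj_equal <- function(a, b, label = "") {
  expect_equal(unname(a[c(1, 2, 3, 5)]), unname(b[c(1, 2, 3, 5)]),
               info = label)
  expect_lt(abs(a[4] - b[4]), 1e-9)
}

# independent O(n^2) conflict-pair scan
scan_conflicts <- function(snps, cutoff) {
  n <- nrow(snps)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (snps$chrom[i] == snps$chrom[j] &&
            abs(snps$pos[i] - snps$pos[j]) <= cutoff) {
          a <- min(snps$snp_id[i], snps$snp_id[j])
          b <- max(snps$snp_id[i], snps$snp_id[j])
          out[[length(out) + 1]] <- c(a, b)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(snp_a = character(), snp_b = character()))
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(snp_a = m[, 1], snp_b = m[, 2])
  res <- dplyr::distinct(res)
  res[order(res$snp_a, res$snp_b), ]
}

# independent union-find for the cluster-partition property
uf_components <- function(n, links) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(links)) {
    for (e in seq_len(nrow(links))) {
      ra <- find(links$a[e])
      rb <- find(links$b[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force enumeration of the probability that >= 1 of k independent
# events succeeds (outcome enumeration, the oracle for p_tagged_bin)
enumerate_p_any <- function(p) {
  k <- length(p)
  if (k == 0) return(0)
  total <- 0
  for (mask in 0:(2^k - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L))
    if (!any(bits)) next
    total <- total + prod(ifelse(bits, p, 1 - p))
  }
  total
}

# hard-constraint audit of a finished panel
check_hard_constraints <- function(panel, config) {
  sel <- panel$selected
  # no same-panel proximity conflicts
  expect_identical(panel$summary$same_panel_conflicts, 0L)
  if (nrow(panel$conflict_edges)) {
    pan <- stats::setNames(panel$report$panel, panel$report$snp_id)
    e <- panel$conflict_edges
    both <- e$snp_a %in% sel & e$snp_b %in% sel
    if (any(both)) {
      expect_true(all(pan[e$snp_a[both]] != pan[e$snp_b[both]]))
    }
  }
  # per-bin caps
  fb <- panel$bins_filtered
  mt <- if (is.function(config$max_tags_per_bin)) {
    vapply(fb$n_snps_in_bin, config$max_tags_per_bin, numeric(1))
  } else {
    rep(config$max_tags_per_bin, nrow(fb))
  }
  per_bin <- vapply(fb$candidates, function(x) sum(x %in% sel), integer(1))
  expect_true(all(per_bin <= mt))
  # no excluded SNP selected
  expect_length(intersect(sel, panel$snps$snp_id[panel$snps$is_excluded]), 0)
  # all non-dropped obligates selected
  ob <- panel$snps$snp_id[panel$snps$is_obligate]
  expect_setequal(setdiff(ob, panel$summary$dropped_obligates),
                  intersect(ob, sel))
  # bead accounting
  beads <- panel$snps$beads[match(sel, panel$snps$snp_id)]
  expect_identical(panel$summary$bead_type_total,
                   if (length(sel)) sum(beads) else 0L)
  invisible(TRUE)
}

# scaled-down seeded instance for fuzz tests
fuzz_instance <- function(seed, n_bins = 6, conflict_density = 0.3,
                          n_populations = 2, ...) {
  generate_instance(synth_spec(n_bins = n_bins,
                               n_populations = n_populations,
                               conflict_density = conflict_density,
                               seed = seed, ...))
}

fuzz_config <- function(inst, ...) {
  args <- list(min_score = inst$config$min_score,
               prob_map = inst$config$prob_map,
               time_limit_s = 20)
  over <- list(...)
  for (nm in names(over)) args[nm] <- list(over[[nm]])
  do.call(panel_config, args)
}
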