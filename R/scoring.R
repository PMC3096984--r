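#' Probability that a bin is successfully tagged
#'
#' A bin is tagged when at least one of its selected tag SNPs genotypes
#' successfully; treating per-SNP successes as independent this is
#' `1 - prod(1 - p)` over the selected tags' discrete genotyping
#' probabilities. An empty selection gives 0; bins covered by a previously
#' genotyped tag SNP have probability 1 by definition.
#'
#' @param p Numeric vector of per-tag genotyping probabilities in (0, 1].
#' @param covered Logical; the bin is covered by an existing genotype.
#' @return A single probability.
#' @examples
#' p_tagged_bin(c(0.9, 0.8)) # 0.98
#' @export
p_tagged_bin <- function(p, covered = FALSE) {
  if (covered) return(1)
  if (length(p) == 0) return(0)
  stopifnot(all(p > 0), all(p <= 1))
  1 - prod(1 - p)
}

# ---- internal objective machinery -----------------------------------------
#
# An objective is the numeric vector
#   c(tagged, obligates, -deficit, score, functional)
# compared lexicographically (all maximized). `score` is the bin-cluster
# score: sum_i w_i * P_i(tagged) / denom, with denom the number of selected
# tags (GoldenGate) or the bead-type total (Infinium).

OBJ_EPS <- c(1e-9, 1e-9, 1e-9, 1e-9, 1e-9)

# strict lexicographic "a better than b"
obj_better <- function(a, b) {
  if (is.null(a)) return(FALSE)
  if (is.null(b)) return(TRUE)
  for (i in seq_along(a)) {
    d <- a[i] - b[i]
    if (d > OBJ_EPS[i]) return(TRUE)
    if (d < -OBJ_EPS[i]) return(FALSE)
  }
  FALSE
}

obj_equal <- function(a, b) {
  !obj_better(a, b) && !obj_better(b, a)
}

# Evaluate a selection (logical over the cluster pool, in ranked order).
# Returns NULL when the selection violates a hard constraint (per-bin cap or
# conflict/colorability), otherwise the objective vector.
cl_obj <- function(cc, sel) {
  counts <- cand_counts(cc, sel)
  if (any(counts > cc$max_tags)) return(NULL)
  if (length(cc$e1)) {
    both <- sel[cc$e1] & sel[cc$e2]
    if (any(both)) {
      if (cc$n_panels == 1L) return(NULL)
      if (is.null(color_selection(cc, sel))) return(NULL)
    }
  }
  obj_from_counts(cc, sel, counts)
}

cand_counts <- function(cc, sel) {
  vapply(cc$cand, function(cb) sum(sel[cb]), integer(1))
}

obj_from_counts <- function(cc, sel, counts) {
  nb <- length(cc$cand)
  P <- numeric(nb)
  for (b in seq_len(nb)) {
    if (cc$covered[b]) {
      P[b] <- 1
    } else {
      cb <- cc$cand[[b]]
      scb <- cb[sel[cb]]
      if (length(scb)) P[b] <- 1 - prod(1 - cc$p[scb])
    }
  }
  ntags <- sum(sel)
  denom <- if (cc$infinium) sum(cc$beads[sel]) else ntags
  score <- if (denom > 0) sum(cc$w * P) / denom else 0
  c(tagged = sum(counts > 0L | cc$covered),
    obligates = sum(sel & cc$obligate),
    neg_deficit = -sum(pmax(0, cc$expected - counts)),
    score = score,
    functional = sum(cc$frank[sel]))
}

# Expected number of tags for a bin: min(max_tags, n candidates, tags needed
# for the cumulative bin probability to reach the configured maximum). Bins
# covered by existing genotypes expect 0.
expected_tags <- function(p_sorted_desc, max_tags, cap) {
  n <- length(p_sorted_desc)
  if (n == 0) return(0L)
  cum <- 1 - cumprod(1 - p_sorted_desc)
  m_cap <- match(TRUE, cum >= cap - 1e-12)
  if (is.na(m_cap)) m_cap <- Inf
  as.integer(min(max_tags, n, m_cap))
}

#' Score one bin cluster
#'
#' The cluster score is `sum_i w_i * P_i / n_tags`, where `P_i` is the
#' probability that bin *i* is tagged ([p_tagged_bin()]), `w_i` weights the
#' bin by its number of tag SNPs (so large bins, which represent more genetic
#' variation, dominate), and the denominator is the number of distinct
#' selected tag SNPs in the cluster -- favoring solutions with fewer tags. In
#' Infinium mode the denominator is the bead-type total instead. A tag shared
#' by bins of several populations is assayed once: it counts once in the
#' denominator but contributes to every bin containing it. A cluster with no
#' selected tags scores 0.
#'
#' @param cluster_bins A tibble of the cluster's bins with list column
#'   `candidates`, plus `pregenotyped_covered` (optional) and the weight
#'   source columns.
#' @param snps A SNP tibble with `probability` (and `allele1`/`allele2` for
#'   Infinium mode).
#' @param selected Character vector of selected SNP ids in the cluster.
#' @param config A [panel_config()].
#' @return A single numeric score.
#' @examples
#' bins <- tibble::tibble(bin_id = "b1", population = "CEU",
#'                        n_snps_in_bin = 3L, candidates = list("rs1"))
#' snps <- snp_table("rs1", "chr1", 100, "A", "G", 0.9, "validated", "other")
#' snps <- snp_probability(snps, panel_config(prob_map = tibble::tibble(
#'   score_low = 0, score_high = Inf, confidence_class = "validated",
#'   probability = 0.9)))
#' cluster_score(dplyr::mutate(bins, n_candidates_prefilter = 3L),
#'               snps, "rs1",
#'               panel_config(bin_weight = "bin_members"))  # 3 * 0.9 / 1
#' @export
cluster_score <- function(cluster_bins, snps, selected,
                          config = panel_config()) {
  snps <- annotate_snps(tibble::as_tibble(snps), config)
  cc <- compile_cluster(cluster_bins, snps,
                        conflict_edges = tibble::tibble(snp_a = character(),
                                                        snp_b = character()),
                        config)
  sel <- cc$ids %in% selected
  obj <- obj_from_counts(cc, sel, cand_counts(cc, sel))
  unname(obj["score"])
}

#' Total panel score
#'
#' The panel score is the sum of the independent bin-cluster scores, so
#' per-cluster optimization composes additively.
#'
#' @param cluster_scores Numeric vector of per-cluster scores.
#' @return Their sum (0 for an empty panel).
#' @export
panel_score <- function(cluster_scores) {
  sum(cluster_scores)
}

#' Coverage tuple for a cluster selection
#'
#' The lexicographic pre-score criteria: number of bins tagged by at least
#' one selected tag SNP (or covered by an existing genotype), number of
#' obligates included, and the tag deficit -- the difference between the
#' expected and actual number of tags, where a bin is exempt when it simply
#' has too few candidates or when its probability already reaches the
#' configured maximum.
#'
#' @inheritParams cluster_score
#' @return A named numeric vector `c(tagged, obligates, deficit)`.
#' @export
coverage_tuple <- function(cluster_bins, snps, selected,
                           config = panel_config()) {
  snps <- annotate_snps(tibble::as_tibble(snps), config)
  cc <- compile_cluster(cluster_bins, snps,
                        conflict_edges = tibble::tibble(snp_a = character(),
                                                        snp_b = character()),
                        config)
  sel <- cc$ids %in% selected
  obj <- obj_from_counts(cc, sel, cand_counts(cc, sel))
  c(tagged = unname(obj["tagged"]),
    obligates = unname(obj["obligates"]),
    deficit = -unname(obj["neg_deficit"]))
}

#' Compare two objectives lexicographically
#'
#' Order of criteria: bins tagged (more is better), obligates included (more),
#' tag deficit (less), cluster score (more), functional-rank sum (more).
#'
#' @param a,b Named numeric vectors as returned by the internal objective
#'   evaluator: `(tagged, obligates, neg_deficit, score, functional)`.
#' @return `-1`, `0` or `1` as `a` is worse than, equivalent to, or better
#'   than `b`.
#' @export
compare_objectives <- function(a, b) {
  if (obj_better(a, b)) return(1L)
  if (obj_better(b, a)) return(-1L)
  0L
}
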