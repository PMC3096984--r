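#' Randomization check of panel quality
#'
#' The validation used to assess an optimized panel: generate many random
#' constrained solutions and count how often randomness beats the optimizer.
#' Each random solution is built by repeatedly picking a bin uniformly at
#' random among bins that can still take a tag (randomized bin order avoids
#' bias about which bins go untagged under conflicts), then assigning it a
#' random conflict-free candidate, stopping when the random panel has as many
#' tags as the reference panel or no tag can be added. A solution "beats" the
#' reference when it tags more bins, or tags the same number with a higher
#' panel score. Single-panel mode only.
#'
#' @inheritParams pick_panel
#' @param reference A `tag_panel` from [pick_panel()], or a character vector
#'   of selected SNP ids.
#' @param n Number of random solutions.
#' @param seed RNG seed for reproducibility.
#' @return A one-row tibble: `n`, `better_coverage` (random solutions tagging
#'   more bins), `equal_coverage`, `better_score_at_equal_coverage`,
#'   `reference_tagged`, `reference_score`, `reference_tags`.
#' @export
random_solutions <- function(bins, snps, config = panel_config(),
                             reference, n = 10000, seed = 1) {
  stopifnot(inherits(config, "panel_config"))
  if (config$n_panels > 1L) {
    bad_input("random_solutions validates single-panel designs only.")
  }
  bins <- check_bins(bins)
  snps <- validate_snps(tibble::as_tibble(snps))
  snps <- annotate_snps(snps, config)
  filt <- filter_candidates(bins, snps, config)
  surviving <- unique(unlist(filt$bins$candidates))
  edges <- build_conflict_graph(snps, config, nodes = surviving)
  pr <- compile_problem(filt$bins, snps, edges, config)

  ref_ids <- if (inherits(reference, "tag_panel")) {
    reference$selected
  } else {
    as.character(reference)
  }
  ref <- eval_selection_ids(pr, ref_ids)
  n_ref <- length(ref_ids)

  # flatten the compiled clusters into one instance-level structure
  flat <- flatten_problem(pr)
  nb <- length(flat$cand)
  np <- length(flat$ids)

  better_cov <- 0L
  equal_cov <- 0L
  better_score <- 0L
  withr_seed(seed, {
    for (r in seq_len(n)) {
      sel <- logical(np)
      blocked <- logical(np)
      counts <- integer(nb)
      total <- 0L
      while (total < n_ref) {
        open <- which(counts < flat$max_tags & !flat$covered)
        open <- open[vapply(open, function(b) {
          any(addable(flat, b, sel, blocked, counts))
        }, logical(1))]
        if (length(open) == 0) break
        b <- open[sample.int(length(open), 1)]
        ch <- flat$cand[[b]][addable(flat, b, sel, blocked, counts)]
        s <- ch[sample.int(length(ch), 1)]
        sel[s] <- TRUE
        counts[flat$bins_of[[s]]] <- counts[flat$bins_of[[s]]] + 1L
        blocked[flat$adj[[s]]] <- TRUE
        total <- total + 1L
      }
      sc <- flat_score(flat, sel, counts)
      if (sc$tagged > ref$tagged) {
        better_cov <- better_cov + 1L
      } else if (sc$tagged == ref$tagged) {
        equal_cov <- equal_cov + 1L
        if (sc$score > ref$score + 1e-9) better_score <- better_score + 1L
      }
    }
  })
  tibble::tibble(
    n = n,
    better_coverage = better_cov,
    equal_coverage = equal_cov,
    better_score_at_equal_coverage = better_score,
    reference_tagged = ref$tagged,
    reference_score = ref$score,
    reference_tags = n_ref
  )
}

# candidates of bin b that can be added: unselected, not conflict-blocked,
# and not capping any other bin they belong to
addable <- function(flat, b, sel, blocked, counts) {
  vapply(flat$cand[[b]], function(s) {
    if (sel[s] || blocked[s]) return(FALSE)
    bs <- flat$bins_of[[s]]
    all(counts[bs] < flat$max_tags[bs])
  }, logical(1))
}

flatten_problem <- function(pr) {
  ids <- character()
  p <- numeric()
  beads <- integer()
  cand <- list()
  w <- numeric()
  max_tags <- integer()
  covered <- logical()
  cluster_of_bin <- integer()
  adj_ids <- list()
  for (k in seq_along(pr$clusters)) {
    cc <- pr$clusters[[k]]
    off <- length(ids)
    ids <- c(ids, cc$ids)
    p <- c(p, cc$p)
    beads <- c(beads, cc$beads)
    w <- c(w, cc$w)
    max_tags <- c(max_tags, cc$max_tags)
    covered <- c(covered, cc$covered)
    cluster_of_bin <- c(cluster_of_bin, rep(k, length(cc$cand)))
    cand <- c(cand, lapply(cc$cand, function(x) x + off))
    adj_ids <- c(adj_ids, lapply(cc$adj, function(x) x + off))
  }
  np <- length(ids)
  bins_of <- vector("list", np)
  for (b in seq_along(cand)) {
    for (s in cand[[b]]) bins_of[[s]] <- c(bins_of[[s]], b)
  }
  cluster_of_snp <- integer(np)
  for (b in seq_along(cand)) cluster_of_snp[cand[[b]]] <- cluster_of_bin[b]
  list(ids = ids, p = p, beads = beads, cand = cand, w = w,
       max_tags = max_tags, covered = covered, adj = adj_ids,
       bins_of = bins_of, cluster_of_bin = cluster_of_bin,
       cluster_of_snp = cluster_of_snp,
       infinium = pr$config$infinium)
}

# coverage and summed per-cluster score of a flat selection
flat_score <- function(flat, sel, counts) {
  nb <- length(flat$cand)
  P <- numeric(nb)
  for (b in seq_len(nb)) {
    if (flat$covered[b]) {
      P[b] <- 1
      next
    }
    cb <- flat$cand[[b]]
    scb <- cb[sel[cb]]
    if (length(scb)) P[b] <- 1 - prod(1 - flat$p[scb])
  }
  tagged <- sum(counts > 0L | flat$covered)
  score <- 0
  for (k in unique(flat$cluster_of_bin)) {
    kb <- flat$cluster_of_bin == k
    ks <- flat$cluster_of_snp == k & sel
    denom <- if (flat$infinium) sum(flat$beads[ks]) else sum(ks)
    if (denom > 0) score <- score + sum(flat$w[kb] * P[kb]) / denom
  }
  list(tagged = tagged, score = score)
}

# evaluate a set of selected ids on a compiled problem (coverage + score)
eval_selection_ids <- function(pr, ids) {
  tagged <- 0L
  score <- 0
  for (cc in pr$clusters) {
    sel <- cc$ids %in% ids
    obj <- obj_from_counts(cc, sel, cand_counts(cc, sel))
    tagged <- tagged + as.integer(obj["tagged"])
    score <- score + unname(obj["score"])
  }
  list(tagged = tagged, score = score)
}
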