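#' Group non-independent bins into bin clusters
#'
#' Two bins are non-independent when they share at least one candidate tag
#' SNP (which happens when bins from different populations tag overlapping
#' variation) or when each contains a member of a conflicting candidate pair.
#' Bin clusters are the connected components of that bin-level graph
#' (single-linkage transitive closure); isolated bins form singleton
#' clusters. Each cluster is an independent unit of optimization.
#'
#' Conflicts involving SNPs that were filtered out do not link bins: filtered
#' SNPs can never be co-selected.
#'
#' @param bins A filtered bin tibble (see [filter_candidates()]).
#' @param conflict_edges Conflict edge tibble from [build_conflict_graph()],
#'   restricted implicitly to candidate SNPs still present in `bins`.
#' @return `bins` with an integer `cluster_id` column (1-based, ordered by
#'   first bin appearance).
#' @export
build_clusters <- function(bins, conflict_edges) {
  nb <- nrow(bins)
  if (nb == 0) {
    bins$cluster_id <- integer()
    return(bins)
  }
  # bin pairs linked by a shared candidate
  snp2bins <- list()
  for (b in seq_len(nb)) {
    for (s in bins$candidates[[b]]) snp2bins[[s]] <- c(snp2bins[[s]], b)
  }
  from <- integer()
  to <- integer()
  for (bs in snp2bins) {
    if (length(bs) > 1) {
      pr <- utils::combn(bs, 2)
      from <- c(from, pr[1, ])
      to <- c(to, pr[2, ])
    }
  }
  # bin pairs linked by a conflicting candidate pair
  if (nrow(conflict_edges) > 0) {
    for (e in seq_len(nrow(conflict_edges))) {
      ba <- snp2bins[[conflict_edges$snp_a[e]]]
      bb <- snp2bins[[conflict_edges$snp_b[e]]]
      if (is.null(ba) || is.null(bb)) next
      pairs <- expand.grid(a = ba, b = bb)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      from <- c(from, pairs$a)
      to <- c(to, pairs$b)
    }
  }
  g <- igraph::make_empty_graph(n = nb, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  # renumber components in order of first appearance for determinism
  bins$cluster_id <- as.integer(match(comp, unique(comp)))
  bins
}

#' Rank a cluster's candidate tag SNPs
#'
#' Pre-processing order used by every search phase: descending genotyping
#' probability, then descending functional rank (probabilities are discrete,
#' so ties are common), then ascending SNP id as a final deterministic
#' tie-break.
#'
#' @param pool A tibble with columns `snp_id`, `probability`,
#'   `functional_rank`.
#' @return `pool` reordered.
#' @export
rank_tag_pool <- function(pool) {
  pool[order(-pool$probability, -pool$functional_rank, pool$snp_id), ]
}
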