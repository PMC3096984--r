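# Internal compiled representations used by the search. User-facing inputs
# are tibbles; the optimizer works on index-based lists for speed.

# Ensure probability / functional_rank / bead columns exist on the SNP table.
annotate_snps <- function(snps, config) {
  if (!"probability" %in% names(snps)) snps <- snp_probability(snps, config)
  if (!"functional_rank" %in% names(snps)) {
    snps <- snp_functional_rank(snps, config)
  }
  if (!"beads" %in% names(snps)) {
    snps$beads <- bead_types(snps$allele1, snps$allele2)
  }
  for (fl in c("is_obligate", "is_excluded", "is_pregenotyped")) {
    if (is.null(snps[[fl]])) snps[[fl]] <- FALSE
  }
  snps
}

resolve_max_tags <- function(config, n_snps_in_bin) {
  if (is.function(config$max_tags_per_bin)) {
    mt <- vapply(n_snps_in_bin, function(n) {
      as.integer(config$max_tags_per_bin(n))
    }, integer(1))
    if (any(is.na(mt) | mt < 1)) {
      bad_input("`max_tags_per_bin` function must return integers >= 1.")
    }
    mt
  } else {
    rep(as.integer(config$max_tags_per_bin), length(n_snps_in_bin))
  }
}

bin_weights <- function(bins, config) {
  if (config$bin_weight == "bin_members") {
    as.numeric(bins$n_snps_in_bin)
  } else if (config$candidate_count == "before_filter") {
    n <- if ("n_candidates_prefilter" %in% names(bins)) {
      bins$n_candidates_prefilter
    } else {
      lengths(bins$candidates)
    }
    as.numeric(n)
  } else {
    as.numeric(lengths(bins$candidates))
  }
}

# Compile one cluster into the structure consumed by the search and scorer.
compile_cluster <- function(cluster_bins, snps, conflict_edges, config) {
  pool_ids <- unique(unlist(cluster_bins$candidates))
  rows <- snps[match(pool_ids, snps$snp_id), ]
  if (length(pool_ids)) {
    ranked <- rank_tag_pool(tibble::tibble(
      snp_id = rows$snp_id, probability = rows$probability,
      functional_rank = rows$functional_rank
    ))
    pool_ids <- ranked$snp_id
    rows <- snps[match(pool_ids, snps$snp_id), ]
  }
  idx <- stats::setNames(seq_along(pool_ids), pool_ids)
  nb <- nrow(cluster_bins)
  cand <- lapply(cluster_bins$candidates, function(x) unname(idx[x]))
  covered <- if ("pregenotyped_covered" %in% names(cluster_bins)) {
    cluster_bins$pregenotyped_covered
  } else {
    rep(FALSE, nb)
  }
  max_tags <- resolve_max_tags(config, cluster_bins$n_snps_in_bin)
  cap <- config$max_bin_probability
  p <- rows$probability
  expected <- integer(nb)
  for (b in seq_len(nb)) {
    expected[b] <- if (covered[b]) 0L else {
      expected_tags(sort(p[cand[[b]]], decreasing = TRUE), max_tags[b], cap)
    }
  }
  keep <- conflict_edges$snp_a %in% pool_ids &
    conflict_edges$snp_b %in% pool_ids
  e1 <- unname(idx[conflict_edges$snp_a[keep]])
  e2 <- unname(idx[conflict_edges$snp_b[keep]])
  n <- length(pool_ids)
  adj <- vector("list", n)
  mates <- vector("list", n)
  if (length(e1)) {
    for (k in seq_along(e1)) {
      adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
      adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
    }
  }
  for (b in seq_len(nb)) {
    cb <- cand[[b]]
    for (s in cb) mates[[s]] <- c(mates[[s]], setdiff(cb, s))
  }
  bins_of <- vector("list", n)
  for (b in seq_len(nb)) {
    for (s in cand[[b]]) bins_of[[s]] <- c(bins_of[[s]], b)
  }
  list(
    ids = pool_ids,
    n = n,
    p = p,
    frank = rows$functional_rank,
    beads = rows$beads,
    obligate = rows$is_obligate,
    cand = cand,
    bins_of = bins_of,
    w = bin_weights(cluster_bins, config),
    max_tags = max_tags,
    covered = covered,
    expected = expected,
    e1 = e1, e2 = e2,
    adj = lapply(adj, function(x) sort(unique(x))),
    mates = lapply(mates, function(x) sort(unique(x))),
    bin_id = cluster_bins$bin_id,
    population = cluster_bins$population,
    n_panels = config$n_panels,
    infinium = config$infinium,
    cap = cap
  )
}

# Compile a whole (filtered) instance: clusters in first-appearance order.
compile_problem <- function(bins, snps, conflict_edges, config) {
  snps <- annotate_snps(snps, config)
  bins <- build_clusters(bins, conflict_edges)
  clusters <- lapply(sort(unique(bins$cluster_id)), function(k) {
    compile_cluster(bins[bins$cluster_id == k, , drop = FALSE], snps,
                    conflict_edges, config)
  })
  list(bins = bins, snps = snps, clusters = clusters, config = config)
}

# ---- graph coloring (multi-panel distribution) -----------------------------

# Color the conflict subgraph induced by `nodes` (local indices) with at most
# k colors. Exact for k = 2 (bipartite BFS); greedy with a backtracking
# rescue for small graphs otherwise. Returns an integer color per node (named
# by node index) or NULL when not colorable.
color_nodes <- function(nodes, adj, k) {
  if (length(nodes) == 0) return(integer())
  color <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  nset <- nodes
  if (k == 2L) {
    for (start in nodes) {
      if (!is.na(color[as.character(start)])) next
      color[as.character(start)] <- 1L
      queue <- start
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        cv <- color[as.character(v)]
        for (u in intersect(adj[[v]], nset)) {
          cu <- color[as.character(u)]
          if (is.na(cu)) {
            color[as.character(u)] <- 3L - cv
            queue <- c(queue, u)
          } else if (cu == cv) {
            return(NULL)
          }
        }
      }
    }
    return(color)
  }
  # greedy in index order
  greedy <- color
  ok <- TRUE
  for (v in nodes) {
    used <- greedy[as.character(intersect(adj[[v]], nset))]
    free <- setdiff(seq_len(k), used[!is.na(used)])
    if (length(free) == 0) {
      ok <- FALSE
      break
    }
    greedy[as.character(v)] <- free[1]
  }
  if (ok) return(greedy)
  if (length(nodes) > 14) return(NULL)
  # exact backtracking for small graphs
  assign_next <- function(i, col) {
    if (i > length(nodes)) return(col)
    v <- nodes[i]
    nbr <- as.character(intersect(adj[[v]], nset))
    for (cand in seq_len(k)) {
      if (!any(col[nbr] == cand, na.rm = TRUE)) {
        col[as.character(v)] <- cand
        res <- assign_next(i + 1L, col)
        if (!is.null(res)) return(res)
        col[as.character(v)] <- NA_integer_
      }
    }
    NULL
  }
  assign_next(1L, color)
}

# Coloring of a selection's conflict subgraph, or NULL if infeasible.
color_selection <- function(cc, sel) {
  nodes <- which(sel)
  color_nodes(nodes, cc$adj, cc$n_panels)
}
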