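#' Brute-force optimum panel (test oracle)
#'
#' Enumerates every feasible selection per bin cluster (respecting conflicts
#' or multi-panel colorability, per-bin caps and exclusions) and returns the
#' lexicographic optimum under the same objective order as the search:
#' bins tagged, obligates, tag deficit, cluster score, functional sum.
#' The enumeration and scoring are vectorized over subset/bin incidence
#' matrices -- a deliberately different computational path from the phase
#' search, so it can serve as an independent oracle. Clusters with more than
#' 20 candidates are refused.
#'
#' Objective ties are broken deterministically: fewest tags, then the
#' selection whose highest-ranked differing candidate is included.
#'
#' @inheritParams pick_panel
#' @return A list of class `tag_panel_oracle`: `selected` (character ids),
#'   `clusters` (tibble of per-cluster objectives), `panel_score`, and the
#'   summed `objective` components.
#' @export
brute_force_optimum <- function(bins, snps, config = panel_config(),
                                obligates = NULL, excluded = NULL,
                                pregenotyped = NULL) {
  stopifnot(inherits(config, "panel_config"))
  bins <- check_bins(bins)
  snps <- validate_snps(tibble::as_tibble(snps))
  if (!is.null(obligates) || !is.null(excluded) || !is.null(pregenotyped)) {
    snps <- flag_snps(snps, obligates, excluded, pregenotyped)
  }
  snps <- annotate_snps(snps, config)
  filt <- filter_candidates(bins, snps, config)
  surviving <- unique(unlist(filt$bins$candidates))
  edges <- build_conflict_graph(snps, config, nodes = surviving)
  pr <- compile_problem(filt$bins, snps, edges, config)

  per_cluster <- lapply(pr$clusters, brute_force_cluster)
  sel_ids <- unlist(lapply(seq_along(pr$clusters), function(k) {
    pr$clusters[[k]]$ids[per_cluster[[k]]$sel]
  }))
  objs <- do.call(rbind, lapply(per_cluster, function(x) x$obj))
  structure(list(
    selected = sel_ids %||% character(),
    clusters = tibble::tibble(
      cluster_id = seq_along(pr$clusters),
      tagged = objs[, "tagged"],
      obligates = objs[, "obligates"],
      deficit = -objs[, "neg_deficit"],
      score = objs[, "score"],
      functional = objs[, "functional"]
    ),
    panel_score = sum(objs[, "score"]),
    objective = colSums(objs)
  ), class = "tag_panel_oracle")
}

# exhaustive, vectorized enumeration over one compiled cluster
brute_force_cluster <- function(cc) {
  n <- cc$n
  if (n > 20L) {
    stop("brute_force_cluster refuses pools larger than 20 candidates (got ",
         n, ").")
  }
  nb <- length(cc$cand)
  if (n == 0L) {
    sel <- logical(0)
    return(list(sel = sel,
                obj = obj_from_counts(cc, sel, cand_counts(cc, sel))))
  }
  # incidence: bins x candidates
  B <- matrix(0, nrow = nb, ncol = n)
  for (b in seq_len(nb)) B[b, cc$cand[[b]]] <- 1
  pc <- pmin(cc$p, 1 - 1e-15)
  W <- t(B) * log1p(-pc)          # candidates x bins
  denom_w <- if (cc$infinium) cc$beads else rep(1, n)

  best <- NULL    # list(sel, obj, ntags)
  lowk <- min(n, 14L)
  Mlow <- vapply(seq_len(lowk), function(b) {
    as.numeric(bitwAnd(bitwShiftR(0:(2^lowk - 1L), b - 1L), 1L))
  }, numeric(2^lowk))
  if (lowk == 1L) Mlow <- matrix(Mlow, ncol = 1L)
  n_hi <- n - lowk

  for (hi in 0:(2^n_hi - 1L)) {
    M <- Mlow
    if (n_hi > 0) {
      hib <- as.numeric(bitwAnd(bitwShiftR(hi, 0:(n_hi - 1L)), 1L))
      M <- cbind(Mlow, matrix(rep(hib, each = nrow(Mlow)), nrow = nrow(Mlow)))
    }
    counts <- M %*% t(B)
    feas <- rowSums(counts > matrix(cc$max_tags, nrow(M), nb,
                                    byrow = TRUE)) == 0
    if (length(cc$e1)) {
      for (k in seq_along(cc$e1)) {
        feas <- feas & !(M[, cc$e1[k]] == 1 & M[, cc$e2[k]] == 1 &
                           cc$n_panels == 1L)
      }
      if (cc$n_panels > 1L) {
        # exact colorability check on rows that carry conflict pairs
        conflict_rows <- which(feas)
        for (r in conflict_rows) {
          selr <- M[r, ] == 1
          if (any(selr[cc$e1] & selr[cc$e2]) &&
              is.null(color_selection(cc, selr))) {
            feas[r] <- FALSE
          }
        }
      }
    }
    if (!any(feas)) next
    Mf <- M[feas, , drop = FALSE]
    countsf <- counts[feas, , drop = FALSE]
    P <- 1 - exp(Mf %*% W)
    if (any(cc$covered)) P[, cc$covered] <- 1
    num <- as.vector(P %*% cc$w)
    denom <- as.vector(Mf %*% denom_w)
    score <- ifelse(denom > 0, num / denom, 0)
    tagged <- rowSums(countsf > 0 |
                        matrix(cc$covered, nrow(Mf), nb, byrow = TRUE))
    oblig <- as.vector(Mf %*% as.numeric(cc$obligate))
    deficit <- rowSums(pmax(matrix(cc$expected, nrow(Mf), nb,
                                   byrow = TRUE) - countsf, 0))
    fsum <- as.vector(Mf %*% cc$frank)
    ntags <- rowSums(Mf)

    # round the score key to the comparator's resolution so float noise from
    # the vectorized path cannot leak past it into the functional key
    ord <- order(-tagged, -oblig, deficit, -round(score, 9), -fsum, ntags)
    for (r in ord[seq_len(min(8L, length(ord)))]) {
      obj <- c(tagged = tagged[r], obligates = oblig[r],
               neg_deficit = -deficit[r], score = score[r],
               functional = fsum[r])
      cand <- list(sel = Mf[r, ] == 1, obj = obj, ntags = ntags[r])
      if (is.null(best) || oracle_better(cand, best)) best <- cand
    }
  }
  best
}

# tie-break: objective, then fewer tags, then prefer including the
# highest-ranked candidate where the selections differ
oracle_better <- function(a, b) {
  if (obj_better(a$obj, b$obj)) return(TRUE)
  if (obj_better(b$obj, a$obj)) return(FALSE)
  if (a$ntags != b$ntags) return(a$ntags < b$ntags)
  d <- which(a$sel != b$sel)
  length(d) > 0 && a$sel[d[1]]
}
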