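#' Design an optimized tag SNP panel
#'
#' The main entry point: takes bin definitions and a SNP annotation table,
#' filters candidates, groups non-independent bins into clusters, and runs
#' the three-phase lexicographic search per cluster (greedy start, swap-in of
#' conflict-involved/two-bead tags, time-budgeted exhaustive swap with an
#' approximate fallback). Objectives, in order: bins tagged, obligates
#' included, tag deficit, bin-cluster score, functional-rank sum.
#'
#' @param bins A bin tibble from [read_bins()] (columns `bin_id`,
#'   `population`, `n_snps_in_bin`, list column `candidates`).
#' @param snps A SNP tibble from [read_snp_annotation()] or [snp_table()].
#' @param config A [panel_config()].
#' @param obligates,excluded,pregenotyped Optional character vectors of SNP
#'   ids to force in, keep out, or treat as already genotyped.
#' @return An object of class `tag_panel` with components `report` (the final
#'   panel, one row per selected SNP: obligates first, then by descending
#'   incremental contribution to the panel score), `untagged` (one row per
#'   candidate of every untagged bin with its exclusion reason), `run_log`
#'   (one row per bin cluster), and `summary`. Use [tidy()][tidy.tag_panel],
#'   [glance()][glance.tag_panel] and [autoplot()][autoplot.tag_panel] to
#'   explore it.
#' @examples
#' bins <- tibble::tibble(
#'   bin_id = c("b1", "b2"), population = "CEU", n_snps_in_bin = c(3L, 2L),
#'   candidates = list(c("rs1", "rs2"), "rs3")
#' )
#' snps <- snp_table(c("rs1", "rs2", "rs3"), "chr1", c(1e4, 2e4, 3e4),
#'                   "A", "G", c(0.9, 0.5, 0.8), "validated", "other")
#' panel <- pick_panel(bins, snps, panel_config(time_limit_s = 5))
#' glance(panel)
#' @export
pick_panel <- function(bins, snps, config = panel_config(),
                       obligates = NULL, excluded = NULL,
                       pregenotyped = NULL) {
  stopifnot(inherits(config, "panel_config"))
  bins <- check_bins(bins)
  snps <- validate_snps(tibble::as_tibble(snps))
  if (!is.null(obligates) || !is.null(excluded) || !is.null(pregenotyped)) {
    snps <- flag_snps(snps, obligates, excluded, pregenotyped)
  }
  all_cand <- unique(unlist(bins$candidates))
  unknown <- setdiff(all_cand, snps$snp_id)
  if (length(unknown)) {
    bad_input(paste0("Candidate tag SNP id not in annotation table: ",
                     paste(unknown, collapse = ", ")))
  }
  ob_ids <- snps$snp_id[snps$is_obligate]
  floating <- setdiff(ob_ids, all_cand)
  if (length(floating)) {
    bad_input(paste0("Obligate SNP ", floating[1],
                     " is not a candidate tag SNP of any bin."))
  }

  snps <- annotate_snps(snps, config)
  filt <- filter_candidates(bins, snps, config)
  fbins <- filt$bins
  surviving <- unique(unlist(fbins$candidates))
  edges <- build_conflict_graph(snps, config, nodes = surviving)
  pr <- compile_problem(fbins, snps, edges, config)

  results <- lapply(pr$clusters, optimize_cluster, config = config)
  assemble_panel(bins, pr, results, filt$exclusions, edges, config)
}

check_bins <- function(bins) {
  need <- c("bin_id", "population", "n_snps_in_bin", "candidates")
  if (!is.data.frame(bins) || !all(need %in% names(bins))) {
    bad_input(paste0("`bins` must have columns ",
                     paste(need, collapse = ", "), "."))
  }
  tibble::as_tibble(bins)
}

# ---- solution assembly ------------------------------------------------------

assemble_panel <- function(orig_bins, pr, results, filter_exclusions, edges,
                           config) {
  clusters <- pr$clusters
  fbins <- pr$bins
  snps <- pr$snps

  sel_rows <- list()
  run_log <- list()
  untagged_bins <- list()
  total_score <- 0
  tot <- c(tagged = 0, obligates = 0, deficit = 0, functional = 0)
  dropped_obligate_ids <- character()

  for (k in seq_along(clusters)) {
    cc <- clusters[[k]]
    res <- results[[k]]
    sel <- res$sel
    obj <- res$obj %||% cl_obj(cc, sel)
    counts <- cand_counts(cc, sel)
    total_score <- total_score + unname(obj["score"])
    tot["tagged"] <- tot["tagged"] + unname(obj["tagged"])
    tot["obligates"] <- tot["obligates"] + unname(obj["obligates"])
    tot["deficit"] <- tot["deficit"] - unname(obj["neg_deficit"])
    tot["functional"] <- tot["functional"] + unname(obj["functional"])
    dropped_obligate_ids <- c(dropped_obligate_ids,
                              cc$ids[res$dropped_obligates])

    # panel assignment: color the selected conflict subgraph
    panel_of <- rep(1L, sum(sel))
    names(panel_of) <- cc$ids[sel]
    if (config$n_panels > 1L && any(sel)) {
      col <- color_selection(cc, sel)
      if (!is.null(col)) {
        panel_of[] <- as.integer(col[as.character(which(sel))])
      }
    }

    # incremental contribution of each selected tag to the panel score
    if (any(sel)) {
      full_score <- unname(obj["score"])
      for (t in which(sel)) {
        drop <- sel
        drop[t] <- FALSE
        o2 <- obj_from_counts(cc, drop, cand_counts(cc, drop))
        delta <- full_score - unname(o2["score"])
        tagged_bins <- cc$bins_of[[t]]
        sel_rows[[length(sel_rows) + 1L]] <- tibble::tibble(
          snp_id = cc$ids[t],
          panel = unname(panel_of[cc$ids[t]]),
          bin_id = paste(cc$bin_id[tagged_bins], collapse = ","),
          populations = paste(cc$population[tagged_bins], collapse = ","),
          probability = cc$p[t],
          incremental_score = delta,
          obligate_flag = cc$obligate[t],
          cluster_id = k
        )
      }
    }

    # untagged bins: report an exclusion reason for every surviving candidate
    for (b in seq_len(length(cc$cand))) {
      if (cc$covered[b] || counts[b] > 0L) next
      cb <- cc$cand[[b]]
      if (length(cb)) {
        reasons <- vapply(cb, function(s) {
          untagged_reason(cc, sel, s)
        }, character(1))
        untagged_bins[[length(untagged_bins) + 1L]] <- tibble::tibble(
          bin_id = cc$bin_id[b], population = cc$population[b],
          snp_id = cc$ids[cb], reason = reasons
        )
      }
    }

    run_log[[k]] <- tibble::tibble(
      cluster_id = k,
      n_bins = length(cc$cand),
      n_candidates = cc$n,
      phase_reached = res$phase,
      exhausted = res$exhausted,
      approximate = res$approx_used,
      elapsed_s = round(res$elapsed, 4),
      n_selected = sum(sel),
      n_tagged = unname(obj["tagged"]),
      n_obligates = unname(obj["obligates"]),
      tag_deficit = -unname(obj["neg_deficit"]),
      cluster_score = unname(obj["score"]),
      functional_sum = unname(obj["functional"])
    )
  }

  report <- if (length(sel_rows)) dplyr::bind_rows(sel_rows) else {
    tibble::tibble(snp_id = character(), panel = integer(),
                   bin_id = character(), populations = character(),
                   probability = numeric(), incremental_score = numeric(),
                   obligate_flag = logical(), cluster_id = integer())
  }
  if (nrow(report)) {
    meta <- snps[match(report$snp_id, snps$snp_id), ]
    report$score <- meta$score
    report$confidence_class <- meta$confidence_class
    report$functional_class <- meta$functional_class
    report <- report[order(-report$obligate_flag, -report$incremental_score,
                           report$snp_id), ]
    report <- report[c("snp_id", "panel", "bin_id", "populations", "score",
                       "confidence_class", "functional_class", "probability",
                       "incremental_score", "obligate_flag", "cluster_id")]
  } else {
    report <- tibble::tibble(snp_id = character(), panel = integer(),
                             bin_id = character(), populations = character(),
                             score = numeric(), confidence_class = character(),
                             functional_class = character(),
                             probability = numeric(),
                             incremental_score = numeric(),
                             obligate_flag = logical(), cluster_id = integer())
  }

  untagged <- dplyr::bind_rows(
    c(list(tibble::tibble(bin_id = character(), population = character(),
                          snp_id = character(), reason = character())),
      untagged_bins)
  )
  # merge in filter-time exclusions for bins that ended up untagged
  tagged_key <- paste(fbins$bin_id, fbins$population)[
    bin_is_tagged(fbins, clusters, results)
  ]
  fx <- filter_exclusions
  if (nrow(fx)) {
    fx <- fx[!(paste(fx$bin_id, fx$population) %in% tagged_key), ]
    untagged <- dplyr::bind_rows(untagged, fx)
  }
  untagged <- dplyr::distinct(untagged)
  untagged <- untagged[order(untagged$bin_id, untagged$population,
                             untagged$snp_id), ]

  selected_ids <- report$snp_id
  beads_sel <- if (length(selected_ids)) {
    sum(snps$beads[match(selected_ids, snps$snp_id)])
  } else 0L

  same_panel_conflicts <- 0L
  if (nrow(edges) && length(selected_ids)) {
    pan <- stats::setNames(report$panel, report$snp_id)
    in_sel <- edges$snp_a %in% selected_ids & edges$snp_b %in% selected_ids
    if (any(in_sel)) {
      same_panel_conflicts <- sum(
        pan[edges$snp_a[in_sel]] == pan[edges$snp_b[in_sel]]
      )
    }
  }

  structure(list(
    report = report,
    untagged = untagged,
    run_log = dplyr::bind_rows(run_log),
    summary = list(
      n_bins = nrow(fbins),
      n_tagged = unname(tot["tagged"]),
      n_untagged = nrow(fbins) - unname(tot["tagged"]),
      n_tags = length(selected_ids),
      panel_score = total_score,
      n_obligates_selected = unname(tot["obligates"]),
      tag_deficit = unname(tot["deficit"]),
      functional_sum = unname(tot["functional"]),
      bead_type_total = beads_sel,
      same_panel_conflicts = same_panel_conflicts,
      dropped_obligates = unique(dropped_obligate_ids)
    ),
    selected = selected_ids,
    bins = orig_bins,
    bins_filtered = fbins,
    snps = snps,
    conflict_edges = edges,
    exclusions = filter_exclusions,
    config = config
  ), class = "tag_panel")
}

bin_is_tagged <- function(fbins, clusters, results) {
  out <- logical(nrow(fbins))
  i <- 0L
  for (k in seq_along(clusters)) {
    cc <- clusters[[k]]
    rows <- which(fbins$cluster_id == k)
    counts <- cand_counts(cc, results[[k]]$sel)
    out[rows] <- cc$covered | counts > 0L
  }
  out
}

untagged_reason <- function(cc, sel, s) {
  if (length(cc$adj[[s]]) && any(sel[cc$adj[[s]]])) {
    if (cc$n_panels == 1L) return("proximity_conflict")
    cand <- sel
    cand[s] <- TRUE
    if (is.null(color_selection(cc, cand))) return("proximity_conflict")
  }
  "superseded"
}

#' @export
print.tag_panel <- function(x, ...) {
  s <- x$summary
  cat("<tag_panel>\n")
  cat("  bins:", s$n_bins, "| tagged:", s$n_tagged,
      "| untagged:", s$n_untagged, "\n")
  cat("  tag SNPs:", s$n_tags, "| obligates:", s$n_obligates_selected,
      "| bead types:", s$bead_type_total, "\n")
  cat("  panel score:", format(s$panel_score, digits = 6),
      "| tag deficit:", s$tag_deficit,
      "| same-panel conflicts:", s$same_panel_conflicts, "\n")
  cat("  clusters:", nrow(x$run_log), "(",
      sum(x$run_log$exhausted), "searched exhaustively,",
      sum(x$run_log$approximate), "approximate )\n")
  invisible(x)
}

#' Write the final panel report
#'
#' Tab-separated, obligate tag SNPs first, remaining tags in order of their
#' incremental contribution to the panel score.
#'
#' @param panel A `tag_panel` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(panel, path) {
  stopifnot(inherits(panel, "tag_panel"))
  readr::write_tsv(panel$report, path, progress = FALSE)
  invisible(path)
}

#' Write the untagged-bins report
#'
#' One row per candidate tag SNP of every bin that ended up with no selected
#' tag, with the reason the candidate was not selected.
#'
#' @inheritParams write_panel_report
#' @return `path`, invisibly.
#' @export
write_untagged_bins <- function(panel, path) {
  stopifnot(inherits(panel, "tag_panel"))
  readr::write_tsv(panel$untagged, path, progress = FALSE)
  invisible(path)
}

#' Write the per-cluster run log
#'
#' One row per bin cluster: size, search phase reached, whether the search
#' completed exhaustively, elapsed time and the cluster score. Clusters whose
#' exhaustive search was truncated by the time limit (or that were routed to
#' the approximate search) have `exhausted = FALSE`.
#'
#' @inheritParams write_panel_report
#' @return `path`, invisibly.
#' @export
write_run_log <- function(panel, path) {
  stopifnot(inherits(panel, "tag_panel"))
  readr::write_tsv(panel$run_log, path, progress = FALSE)
  invisible(path)
}
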