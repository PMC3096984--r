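#' Map vendor scores and confidence classes to genotyping probabilities
#'
#' Combines each SNP's predicted genotyping score with its empirically
#' established confidence class through the configured discrete probability
#' map. Intervals are left-closed, right-open; a score below a class's lowest
#' interval takes the lowest interval's probability (the `-99` missing-score
#' sentinel therefore maps to the lowest cell). An unknown confidence class or
#' a score falling in a gap of the map is an error naming the offending cell.
#'
#' @param snps A SNP tibble (see [read_snp_annotation()]).
#' @param config A [panel_config()].
#' @return `snps` with a `probability` column of discrete values.
#' @examples
#' snps <- snp_table("rs1", "chr1", 100, "A", "G", 0.9, "validated", "other")
#' snp_probability(snps, panel_config())$probability
#' @export
snp_probability <- function(snps, config = panel_config()) {
  snps$probability <- prob_lookup(snps$score, snps$confidence_class,
                                  config$prob_map)
  snps
}

prob_lookup <- function(score, confidence_class, prob_map) {
  score <- ifelse(is.na(score), -99, score)
  out <- numeric(length(score))
  for (cls in unique(confidence_class)) {
    rows <- prob_map[prob_map$confidence_class == cls, ]
    if (nrow(rows) == 0) {
      bad_input(paste0("Probability map has no rows for confidence class '",
                       cls, "'."))
    }
    rows <- rows[order(rows$score_low), ]
    idx <- which(confidence_class == cls)
    s <- score[idx]
    cell <- findInterval(s, rows$score_low)   # 0 => below lowest: clamp
    cell[cell == 0] <- 1L
    in_gap <- s >= rows$score_high[cell] & s >= rows$score_low[1]
    if (any(in_gap)) {
      bad_input(paste0("Score ", s[in_gap][1], " with confidence class '",
                       cls, "' is not covered by the probability map."))
    }
    out[idx] <- rows$probability[cell]
  }
  out
}

#' Attach functional ranks
#'
#' Looks up each SNP's functional class in the configured rank table
#' (case-insensitive, `-`/`_` stripped); unlisted classes get rank 0.
#'
#' @inheritParams snp_probability
#' @return `snps` with a `functional_rank` column.
#' @export
snp_functional_rank <- function(snps, config = panel_config()) {
  ranks <- config$functional_ranks
  norm <- function(x) gsub("[-_ ]", "", tolower(x))
  names(ranks) <- norm(names(ranks))
  r <- unname(ranks[norm(snps$functional_class)])
  r[is.na(r)] <- 0
  snps$functional_rank <- r
  snps
}

#' Bead types consumed by a SNP on the Infinium assay
#'
#' SNPs whose alleles are the complementary pairs A/T or C/G require two bead
#' types; every other allele combination requires one. Allele order and
#' strand are irrelevant (A/T and C/G are their own reverse complements).
#'
#' @param allele1,allele2 Character vectors of single bases in `{A,C,G,T}`.
#' @return An integer vector of 1s and 2s.
#' @examples
#' bead_types(c("A", "A", "C"), c("T", "G", "G"))
#' @export
bead_types <- function(allele1, allele2) {
  a1 <- toupper(allele1)
  a2 <- toupper(allele2)
  stopifnot(all(a1 %in% c("A", "C", "G", "T")),
            all(a2 %in% c("A", "C", "G", "T")), all(a1 != a2))
  two <- (pmin(a1, a2) == "A" & pmax(a1, a2) == "T") |
    (pmin(a1, a2) == "C" & pmax(a1, a2) == "G")
  ifelse(two, 2L, 1L)
}

#' Build the proximity conflict graph
#'
#' Two SNPs conflict when they lie on the same chromosome separated by
#' `distance_cutoff_bp` bp or less (a 60 bp cutoff forbids pairs closer than
#' 61 bp). Nodes are the ids in `nodes` (default: all SNPs in `snps`); edges
#' are found by a per-chromosome sorted sweep.
#'
#' @param snps A SNP tibble with `snp_id`, `chrom`, `pos`.
#' @param config A [panel_config()]; only `distance_cutoff_bp` is used.
#' @param nodes Optional character vector restricting the node set.
#' @return A tibble of undirected edges with columns `snp_a`, `snp_b`
#'   (`snp_a < snp_b`), sorted for reproducibility.
#' @examples
#' snps <- snp_table(c("rs1", "rs2"), "chr1", c(100, 160), "A", "G",
#'                   c("C", "C"), 0.9, "validated", "other")
#' build_conflict_graph(snps, panel_config(distance_cutoff_bp = 60))
#' @export
build_conflict_graph <- function(snps, config = panel_config(), nodes = NULL) {
  cutoff <- config$distance_cutoff_bp
  tab <- snps[c("snp_id", "chrom", "pos")]
  if (!is.null(nodes)) tab <- tab[tab$snp_id %in% nodes, ]
  edges_a <- character()
  edges_b <- character()
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, ]
    sub <- sub[order(sub$pos, sub$snp_id), ]
    n <- nrow(sub)
    if (n < 2) next
    j <- 1L
    for (i in seq_len(n - 1L)) {
      k <- i + 1L
      while (k <= n && sub$pos[k] - sub$pos[i] <= cutoff) {
        edges_a <- c(edges_a, sub$snp_id[i])
        edges_b <- c(edges_b, sub$snp_id[k])
        k <- k + 1L
      }
    }
  }
  if (length(edges_a) == 0) {
    return(tibble::tibble(snp_a = character(), snp_b = character()))
  }
  out <- tibble::tibble(snp_a = pmin(edges_a, edges_b),
                        snp_b = pmax(edges_a, edges_b))
  out <- dplyr::distinct(out)
  out[order(out$snp_a, out$snp_b), ]
}

#' Filter candidate tag SNPs and flag covered bins
#'
#' Pre-processing ahead of optimization: removes user-excluded candidates and
#' candidates below the minimum genotyping score from every bin (recording an
#' exclusion reason per removal), removes previously genotyped SNPs from
#' candidate lists, and marks bins that contain a previously genotyped tag
#' SNP as covered (they need no new tags). When `conflict_all_snps` is set,
#' candidates within the cutoff of any non-candidate annotated SNP are also
#' removed (`proximity_conflict`). The operation is idempotent.
#'
#' @param bins A bin tibble from [read_bins()].
#' @param snps A flagged SNP tibble (see [flag_snps()]).
#' @param config A [panel_config()].
#' @return A list with elements `bins` (filtered; gains `pregenotyped_covered`
#'   and `n_candidates_prefilter` columns, with bins whose candidates were all
#'   removed retained as untagged), `exclusions` (tibble `bin_id`,
#'   `population`, `snp_id`, `reason`).
#' @export
filter_candidates <- function(bins, snps, config = panel_config()) {
  snp_idx <- stats::setNames(seq_len(nrow(snps)), snps$snp_id)
  all_cand <- unique(unlist(bins$candidates))
  unknown <- setdiff(all_cand, snps$snp_id)
  if (length(unknown)) {
    bad_input(paste0("Candidate tag SNP id not in annotation table: ",
                     paste(unknown, collapse = ", ")))
  }

  drop_reason <- stats::setNames(rep(NA_character_, nrow(snps)), snps$snp_id)
  drop_reason[snps$is_excluded] <- "user_excluded"
  below <- if (is.null(config$min_score)) {
    rep(FALSE, nrow(snps))
  } else {
    (is.na(snps$score) | snps$score < config$min_score) & !snps$is_excluded
  }
  drop_reason[below] <- "below_min_score"

  ob_dropped <- snps$is_obligate & !is.na(drop_reason)
  if (any(ob_dropped)) {
    bad_input(paste0("Obligate SNP ", snps$snp_id[ob_dropped][1],
                     " is removed by the ",
                     drop_reason[ob_dropped][1],
                     " filter; contradictory user input."))
  }

  if (config$conflict_all_snps) {
    non_cand <- setdiff(snps$snp_id, all_cand)
    if (length(non_cand)) {
      edges <- build_conflict_graph(snps, config)
      hit <- union(edges$snp_a[edges$snp_b %in% non_cand],
                   edges$snp_b[edges$snp_a %in% non_cand])
      hit <- intersect(hit, all_cand)
      hit <- hit[is.na(drop_reason[hit])]
      ob_hit <- hit[snps$is_obligate[snp_idx[hit]]]
      if (length(ob_hit)) {
        bad_input(paste0("Obligate SNP ", ob_hit[1], " conflicts with an ",
                         "annotated non-candidate SNP (conflict_all_snps)."))
      }
      drop_reason[hit] <- "proximity_conflict"
    }
  }

  preg <- snps$snp_id[snps$is_pregenotyped]
  has_pre <- "n_candidates_prefilter" %in% names(bins)
  has_cov <- "pregenotyped_covered" %in% names(bins)
  exclusions <- vector("list", nrow(bins))
  new_cand <- vector("list", nrow(bins))
  covered <- logical(nrow(bins))
  prefilter_n <- integer(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    cand <- bins$candidates[[b]]
    # idempotence: prefilter count survives a second pass
    prefilter_n[b] <- if (has_pre) {
      bins$n_candidates_prefilter[b]
    } else {
      length(cand)
    }
    covered[b] <- if (has_cov) {
      bins$pregenotyped_covered[b] || any(cand %in% preg)
    } else {
      any(cand %in% preg)
    }
    reasons <- drop_reason[cand]
    keep <- is.na(reasons) & !(cand %in% preg)
    dropped <- cand[!is.na(reasons)]
    if (length(dropped)) {
      exclusions[[b]] <- tibble::tibble(
        bin_id = bins$bin_id[b], population = bins$population[b],
        snp_id = dropped, reason = unname(reasons[dropped])
      )
    }
    new_cand[[b]] <- cand[keep]
  }
  out <- bins
  out$candidates <- new_cand
  out$pregenotyped_covered <- covered
  out$n_candidates_prefilter <- prefilter_n
  # covered bins need no tags of their own: keep only candidates that also
  # serve an uncovered bin (so cluster links and caps still apply), otherwise
  # an already-genotyped bin could spuriously reward adding a tag
  if (any(covered)) {
    live <- unique(unlist(out$candidates[!covered]))
    out$candidates[covered] <- lapply(out$candidates[covered],
                                      function(x) intersect(x, live))
  }
  list(
    bins = out,
    exclusions = dplyr::bind_rows(exclusions) %||% tibble::tibble(
      bin_id = character(), population = character(),
      snp_id = character(), reason = character()
    )
  )
}

`%||%` <- function(x, y) if (is.null(x) || (is.data.frame(x) && nrow(x) == 0 && ncol(x) == 0)) y else x
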