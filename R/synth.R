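#' Specification for a synthetic bin-tagging instance
#'
#' Describes the combinatorial structure of a synthetic panel-design
#' instance: LD bins with candidate tag SNPs, cross-population tag sharing,
#' and planted proximity conflicts. The defaults mirror a large
#' multi-population candidate set in which roughly 42% of tag SNPs are shared
#' between two populations, about a fifth of tag SNPs have a conflict partner
#' within the cutoff, and roughly 30% of bins carry more than one candidate
#' tag SNP. No population-genetic simulation is involved: the generator
#' emulates structure, not LD.
#'
#' @param n_bins Total number of bins to generate (across populations).
#' @param n_populations 1 or 2.
#' @param shared_tag_fraction Probability that a tag SNP of a two-population
#'   locus tags the bin in both populations.
#' @param candidates_per_bin Integer range `c(lo, hi)` for the number of
#'   candidate tag SNPs per locus; counts are drawn from a truncated
#'   geometric-like distribution (decay 0.3) so single-candidate bins
#'   dominate.
#' @param conflict_density Probability that a pair of tag SNPs from adjacent
#'   loci is planted within the proximity cutoff.
#' @param prob_levels Discrete genotyping probability levels the generated
#'   probability map will produce (highest level corresponds to the best
#'   score interval).
#' @param at_cg_fraction Fraction of SNPs given A/T or C/G alleles (two bead
#'   types on the Infinium assay).
#' @param missing_score_fraction Fraction of SNPs with a missing vendor score
#'   (the `-99` sentinel).
#' @param distance_cutoff_bp Cutoff used when planting conflicts; keep equal
#'   to the `panel_config()` cutoff used downstream.
#' @param seed RNG seed; every generated artifact is a deterministic function
#'   of the spec including the seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_bins = 50,
                       n_populations = 2,
                       shared_tag_fraction = 0.42,
                       candidates_per_bin = c(1, 5),
                       conflict_density = 0.21,
                       prob_levels = c(0.5, 0.7, 0.85, 0.95),
                       at_cg_fraction = 0.12,
                       missing_score_fraction = 0.02,
                       distance_cutoff_bp = 60,
                       seed = 1) {
  fracs <- c(shared_tag_fraction, conflict_density, at_cg_fraction,
             missing_score_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    bad_input("All fractions must lie in [0, 1].")
  }
  if (!n_populations %in% c(1, 2)) {
    bad_input("`n_populations` must be 1 or 2.")
  }
  if (n_bins < 1) bad_input("`n_bins` must be >= 1.")
  if (conflict_density > 0 && n_bins < 2) {
    bad_input("Planting conflicts requires at least 2 bins.")
  }
  if (length(candidates_per_bin) != 2 || candidates_per_bin[1] < 1 ||
      candidates_per_bin[2] < candidates_per_bin[1]) {
    bad_input("`candidates_per_bin` must be a range c(lo, hi) with lo >= 1.")
  }
  if (any(prob_levels <= 0 | prob_levels > 1)) {
    bad_input("`prob_levels` must lie in (0, 1].")
  }
  structure(list(
    n_bins = as.integer(n_bins),
    n_populations = as.integer(n_populations),
    shared_tag_fraction = shared_tag_fraction,
    candidates_per_bin = as.integer(candidates_per_bin),
    conflict_density = conflict_density,
    prob_levels = sort(prob_levels),
    at_cg_fraction = at_cg_fraction,
    missing_score_fraction = missing_score_fraction,
    distance_cutoff_bp = distance_cutoff_bp,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' Generate a synthetic panel-design instance
#'
#' Lays out loci along a chromosome (far apart relative to the cutoff), draws
#' per-locus candidate tag SNPs, shares tags across populations, and plants
#' proximity conflicts between tags of adjacent loci. Also builds a
#' probability map realizing the requested discrete levels. Deterministic
#' given the spec's seed: writing twice yields byte-identical files.
#'
#' @param spec A [synth_spec()].
#' @param dir Optional directory; when given, writes `bins.tsv` (tabular
#'   dialect), `snps.tsv` and `config.yaml` there.
#' @return A list of class `synth_instance`: `bins`, `snps`, `config` (a
#'   [panel_config()] whose probability map realizes `prob_levels`),
#'   `realized` (realized shared-tag and conflict-involved fractions) and
#'   `spec`.
#' @export
generate_instance <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  withr_seed(spec$seed, {
    pops <- c("CEU", "YRI")[seq_len(spec$n_populations)]
    lo <- spec$candidates_per_bin[1]
    hi <- spec$candidates_per_bin[2]
    sizes <- lo:hi
    size_w <- 0.3^(seq_along(sizes) - 1)

    bin_rows <- list()
    snp_ids <- character()
    snp_pos <- numeric()
    locus_of_snp <- integer()
    shared_flags <- logical()
    next_snp <- 1L
    locus <- 0L
    locus_gap <- 10000
    tag_gap <- 500

    while (length(bin_rows) < spec$n_bins) {
      locus <- locus + 1L
      m <- if (length(sizes) == 1) sizes else sample(sizes, 1, prob = size_w)
      ids <- sprintf("rs%05d", next_snp:(next_snp + m - 1L))
      next_snp <- next_snp + m
      pos <- locus * locus_gap + tag_gap * seq_len(m)
      snp_ids <- c(snp_ids, ids)
      snp_pos <- c(snp_pos, pos)
      locus_of_snp <- c(locus_of_snp, rep(locus, m))
      if (length(pops) == 1) {
        assign_pop <- rep(1L, m)
        shared <- rep(FALSE, m)
      } else {
        shared <- stats::runif(m) < spec$shared_tag_fraction
        assign_pop <- ifelse(stats::runif(m) < 0.5, 1L, 2L)
      }
      shared_flags <- c(shared_flags, shared)
      for (p in seq_along(pops)) {
        members <- ids[shared | assign_pop == p]
        if (length(members) == 0) next
        if (length(bin_rows) >= spec$n_bins) break
        bin_rows[[length(bin_rows) + 1L]] <- tibble::tibble(
          bin_id = sprintf("bin%04d", locus),
          population = pops[p],
          # bin membership: tags plus simulated non-tag members
          n_snps_in_bin = length(members) +
            stats::rpois(1, 2),
          candidates = list(members)
        )
      }
    }
    bins <- dplyr::bind_rows(bin_rows)

    # plant proximity conflicts between adjacent loci
    n_conflict_snps <- 0L
    if (spec$conflict_density > 0 && locus >= 2) {
      for (l in seq_len(locus - 1L)) {
        if (stats::runif(1) >= spec$conflict_density) next
        a <- which(locus_of_snp == l)
        b <- which(locus_of_snp == l + 1L)
        if (!length(a) || !length(b)) next
        ai <- a[length(a)]
        bi <- b[1]
        snp_pos[bi] <- snp_pos[ai] +
          sample.int(max(1, spec$distance_cutoff_bp), 1)
        n_conflict_snps <- n_conflict_snps + 2L
      }
    }

    n <- length(snp_ids)
    at_cg <- stats::runif(n) < spec$at_cg_fraction
    pair_other <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pair_atcg <- list(c("A", "T"), c("C", "G"))
    alleles <- t(vapply(seq_len(n), function(i) {
      if (at_cg[i]) pair_atcg[[sample.int(2, 1)]] else
        pair_other[[sample.int(4, 1)]]
    }, character(2)))
    score <- round(stats::runif(n), 3)
    score[stats::runif(n) < spec$missing_score_fraction] <- NA_real_
    conf <- sample(c("validated", "unvalidated"), n, replace = TRUE,
                   prob = c(0.7, 0.3))
    func <- sample(c("nonsense", "missense", "nonsynonymous", "coding",
                     "other"), n, replace = TRUE,
                   prob = c(0.01, 0.05, 0.04, 0.1, 0.8))
    snps <- snp_table(snp_ids, "chr1", snp_pos, alleles[, 1], alleles[, 2],
                      score, conf, func)

    levels <- spec$prob_levels
    nl <- length(levels)
    breaks <- seq(0, 1, length.out = nl + 1)
    pm <- tibble::tibble(
      score_low = rep(breaks[-(nl + 1)], 2),
      score_high = rep(c(breaks[2:nl], Inf), 2),
      confidence_class = rep(c("validated", "unvalidated"), each = nl),
      probability = c(levels, pmax(min(levels), c(levels[1], levels[-nl])))
    )
    config <- panel_config(
      distance_cutoff_bp = spec$distance_cutoff_bp,
      min_score = 0.1,
      prob_map = pm
    )

    kept <- unique(unlist(bins$candidates))
    realized_shared <- if (spec$n_populations == 2) {
      idx <- match(kept, snp_ids)
      mean(shared_flags[idx])
    } else 0
    edges <- build_conflict_graph(snps, config, nodes = kept)
    realized_conflict <- if (length(kept)) {
      length(unique(c(edges$snp_a, edges$snp_b))) / length(kept)
    } else 0

    inst <- structure(list(
      bins = bins,
      snps = snps[snps$snp_id %in% kept, ],
      config = config,
      realized = list(shared_tag_fraction = realized_shared,
                      conflict_involved_fraction = realized_conflict),
      spec = spec
    ), class = "synth_instance")

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_bins(inst$bins, file.path(dir, "bins.tsv"))
      write_snp_annotation(inst$snps, file.path(dir, "snps.tsv"))
      write_panel_config(inst$config, file.path(dir, "config.yaml"))
    }
    inst
  })
}

# evaluate expr under a local, restorable RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.synth_instance <- function(x, ...) {
  cat("<synth_instance>\n")
  cat("  bins:", nrow(x$bins), "| populations:",
      length(unique(x$bins$population)),
      "| candidate tag SNPs:", nrow(x$snps), "\n")
  cat("  realized shared-tag fraction:",
      round(x$realized$shared_tag_fraction, 3),
      "| conflict-involved fraction:",
      round(x$realized$conflict_involved_fraction, 3), "\n")
  invisible(x)
}
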