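#' Panel design configuration
#'
#' Collects every threshold, mapping and mode switch that governs panel
#' optimization. The defaults correspond to a single-panel GoldenGate design
#' with one tag SNP per bin and a 60 bp proximity cutoff.
#'
#' @param distance_cutoff_bp Proximity conflict cutoff in base pairs. Two SNPs
#'   on the same chromosome separated by `distance_cutoff_bp` bp or less (i.e.
#'   closer than `distance_cutoff_bp + 1` bp) conflict and cannot share a
#'   panel. Default 60, Illumina's GoldenGate recommendation.
#' @param min_score Minimum vendor genotyping score for a SNP to remain a
#'   candidate. SNPs with a missing score (the `-99` sentinel) fail this
#'   filter. Set to `NULL` to disable the filter entirely, in which case
#'   missing scores are mapped through the lowest probability interval.
#' @param max_tags_per_bin Maximum number of tag SNPs to select per bin:
#'   either a single integer (default 1) or a function of the bin's total SNP
#'   membership returning an integer (useful to tag large bins redundantly).
#' @param max_bin_probability Genotyping probability above which a bin is
#'   considered successfully assayed; once a bin reaches it no further tags
#'   are added. The default of 1 disables the shortcut (no bin can reach it).
#' @param prob_map Data frame mapping (score interval x confidence class) to a
#'   discrete genotyping probability, with columns `score_low`, `score_high`,
#'   `confidence_class`, `probability`. Intervals are left-closed,
#'   right-open; scores below the lowest interval of a class take that
#'   interval's probability. See [default_prob_map()].
#' @param functional_ranks Named numeric vector mapping functional class to an
#'   integer rank; higher rank is preferred. Classes not listed get rank 0.
#'   See [default_functional_ranks()].
#' @param n_panels Number of assay panels. With more than one panel,
#'   conflicting tag SNP pairs may both be selected and are distributed
#'   across panels so that no panel contains a conflict.
#' @param infinium Logical; optimize for the Infinium assay. A/T and C/G SNPs
#'   consume two bead types (all others one) and the cluster score denominator
#'   becomes the bead-type total rather than the tag count.
#' @param time_limit_s Per-cluster wall-clock budget in seconds for the
#'   exhaustive swap search. `0` disables the swap search entirely and
#'   returns the phase-2 solution.
#' @param conflict_all_snps Logical; when `TRUE`, candidate tag SNPs within
#'   the cutoff of *any* SNP in the annotation table (not only other
#'   candidates) are removed before optimization.
#' @param bin_weight Either `"candidates"` (default: a bin's weight in the
#'   cluster score is its number of candidate tag SNPs) or `"bin_members"`
#'   (weight by the bin's total SNP membership).
#' @param candidate_count Whether the candidate-count weight is taken
#'   `"after_filter"` (default) or `"before_filter"` (before the min-score /
#'   exclusion filter).
#' @param force_approximate Logical; route every cluster through the
#'   approximate (single-in / multi-out) search instead of the exhaustive
#'   phase-3 swap. Mainly for benchmarking the fallback.
#'
#' @return An object of class `panel_config` (a validated named list).
#' @examples
#' cfg <- panel_config(min_score = 0.4, max_tags_per_bin = 1)
#' cfg$distance_cutoff_bp
#' @export
panel_config <- function(distance_cutoff_bp = 60,
                         min_score = 0.4,
                         max_tags_per_bin = 1,
                         max_bin_probability = 1,
                         prob_map = default_prob_map(),
                         functional_ranks = default_functional_ranks(),
                         n_panels = 1,
                         infinium = FALSE,
                         time_limit_s = 50,
                         conflict_all_snps = FALSE,
                         bin_weight = c("candidates", "bin_members"),
                         candidate_count = c("after_filter", "before_filter"),
                         force_approximate = FALSE) {
  bin_weight <- match.arg(bin_weight)
  candidate_count <- match.arg(candidate_count)
  prob_map <- validate_prob_map(prob_map)
  if (!is.numeric(distance_cutoff_bp) || length(distance_cutoff_bp) != 1 ||
      is.na(distance_cutoff_bp) || distance_cutoff_bp < 0) {
    bad_input("`distance_cutoff_bp` must be a single non-negative number.")
  }
  if (!is.null(min_score) &&
      (!is.numeric(min_score) || length(min_score) != 1 || is.na(min_score))) {
    bad_input("`min_score` must be a single number or NULL.")
  }
  if (!is.function(max_tags_per_bin)) {
    if (!is.numeric(max_tags_per_bin) || length(max_tags_per_bin) != 1 ||
        is.na(max_tags_per_bin) || max_tags_per_bin < 1) {
      bad_input("`max_tags_per_bin` must be an integer >= 1 or a function.")
    }
    max_tags_per_bin <- as.integer(max_tags_per_bin)
  }
  if (!is.numeric(max_bin_probability) || length(max_bin_probability) != 1 ||
      is.na(max_bin_probability) ||
      max_bin_probability <= 0 || max_bin_probability > 1) {
    bad_input("`max_bin_probability` must be in (0, 1].")
  }
  if (!is.numeric(n_panels) || length(n_panels) != 1 || is.na(n_panels) ||
      n_panels < 1) {
    bad_input("`n_panels` must be an integer >= 1.")
  }
  if (!is.numeric(time_limit_s) || length(time_limit_s) != 1 ||
      is.na(time_limit_s) || time_limit_s < 0) {
    bad_input("`time_limit_s` must be a single non-negative number.")
  }
  if (is.null(names(functional_ranks)) && length(functional_ranks) > 0) {
    bad_input("`functional_ranks` must be a named numeric vector.")
  }
  structure(
    list(
      distance_cutoff_bp = as.numeric(distance_cutoff_bp),
      min_score = min_score,
      max_tags_per_bin = max_tags_per_bin,
      max_bin_probability = as.numeric(max_bin_probability),
      prob_map = prob_map,
      functional_ranks = functional_ranks,
      n_panels = as.integer(n_panels),
      infinium = isTRUE(infinium),
      time_limit_s = as.numeric(time_limit_s),
      conflict_all_snps = isTRUE(conflict_all_snps),
      bin_weight = bin_weight,
      candidate_count = candidate_count,
      force_approximate = isTRUE(force_approximate)
    ),
    class = "panel_config"
  )
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config>\n")
  cat("  distance cutoff:", x$distance_cutoff_bp, "bp",
      if (x$conflict_all_snps) "(checked against all annotated SNPs)" else "",
      "\n")
  cat("  min score:", if (is.null(x$min_score)) "disabled" else x$min_score,
      "| max tags/bin:",
      if (is.function(x$max_tags_per_bin)) "<function>" else x$max_tags_per_bin,
      "| max bin probability:", x$max_bin_probability, "\n")
  cat("  panels:", x$n_panels,
      "| assay:", if (x$infinium) "Infinium (bead-type denominator)" else "GoldenGate",
      "| time limit:", x$time_limit_s, "s/cluster\n")
  cat("  probability map:", nrow(x$prob_map), "cells over classes {",
      paste(unique(x$prob_map$confidence_class), collapse = ", "), "}\n")
  invisible(x)
}

#' Default genotyping probability map
#'
#' A small placeholder table mapping vendor score intervals crossed with the
#' confidence classes `"validated"` and `"unvalidated"` onto the discrete
#' probability levels 0.5/0.7/0.85/0.95. Real projects should replace it with
#' a map calibrated on their own retrospective genotyping results; the
#' discreteness (a small set of probability levels) is what enables
#' functional-rank tie-breaking.
#'
#' @return A tibble with columns `score_low`, `score_high`,
#'   `confidence_class`, `probability`. Intervals are left-closed,
#'   right-open; the top interval is unbounded above.
#' @examples
#' default_prob_map()
#' @export
default_prob_map <- function() {
  tibble::tibble(
    score_low = rep(c(0, 0.25, 0.5, 0.75), 2),
    score_high = rep(c(0.25, 0.5, 0.75, Inf), 2),
    confidence_class = rep(c("validated", "unvalidated"), each = 4),
    probability = c(0.5, 0.7, 0.85, 0.95,
                    0.5, 0.5, 0.7, 0.85)
  )
}

#' Default functional-class ranks
#'
#' Higher rank means a class is preferred when genotyping probabilities tie.
#' Classes are matched case-insensitively after stripping `-`/`_`; classes
#' not listed receive rank 0.
#'
#' @return A named numeric vector.
#' @examples
#' default_functional_ranks()
#' @export
default_functional_ranks <- function() {
  c(nonsense = 5, missense = 4, nonsynonymous = 3, coding = 2, other = 1)
}

validate_prob_map <- function(prob_map) {
  need <- c("score_low", "score_high", "confidence_class", "probability")
  if (!is.data.frame(prob_map) || !all(need %in% names(prob_map))) {
    bad_input(paste0("`prob_map` must be a data frame with columns ",
                     paste(need, collapse = ", "), "."))
  }
  prob_map <- tibble::as_tibble(prob_map)[need]
  if (any(is.na(prob_map$probability)) ||
      any(prob_map$probability <= 0) || any(prob_map$probability > 1)) {
    bad_input("Every mapped probability must lie in (0, 1].")
  }
  if (any(prob_map$score_low >= prob_map$score_high)) {
    bad_input("`prob_map` intervals must satisfy score_low < score_high.")
  }
  # intervals within a class must not overlap
  by_class <- split(prob_map, prob_map$confidence_class)
  for (tab in by_class) {
    tab <- tab[order(tab$score_low), ]
    if (nrow(tab) > 1 &&
        any(tab$score_low[-1] < tab$score_high[-nrow(tab)] - 1e-12)) {
      bad_input("`prob_map` intervals overlap within a confidence class.")
    }
  }
  prob_map
}

#' Read a panel configuration from a YAML file
#'
#' The file holds the same keys as [panel_config()] arguments. `prob_map` is
#' given as a list of rows, each with `score_low`, `score_high`,
#' `confidence_class` and `probability`; `functional_ranks` as a mapping of
#' class to rank. Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `panel_config` object.
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) bad_input(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  args <- list()
  scalar_keys <- c("distance_cutoff_bp", "min_score", "max_tags_per_bin",
                   "max_bin_probability", "n_panels", "infinium",
                   "time_limit_s", "conflict_all_snps", "bin_weight",
                   "candidate_count", "force_approximate")
  for (k in intersect(scalar_keys, names(raw))) args[[k]] <- raw[[k]]
  if (!is.null(raw$prob_map)) {
    args$prob_map <- dplyr::bind_rows(lapply(raw$prob_map, function(row) {
      tibble::tibble(
        score_low = as.numeric(row$score_low),
        score_high = as.numeric(row$score_high),
        confidence_class = as.character(row$confidence_class),
        probability = as.numeric(row$probability)
      )
    }))
  }
  if (!is.null(raw$functional_ranks)) {
    args$functional_ranks <- unlist(raw$functional_ranks)
  }
  do.call(panel_config, args)
}

#' Write a panel configuration to a YAML file
#'
#' @param config A `panel_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(config, path) {
  stopifnot(inherits(config, "panel_config"))
  if (is.function(config$max_tags_per_bin)) {
    bad_input("A function-valued `max_tags_per_bin` cannot be serialized to YAML.")
  }
  out <- unclass(config)
  out$prob_map <- lapply(seq_len(nrow(config$prob_map)), function(i) {
    as.list(config$prob_map[i, ])
  })
  out$functional_ranks <- as.list(config$functional_ranks)
  yaml::write_yaml(out, path)
  invisible(path)
}

# classed condition so the CLI can map user-input problems to exit code 2
bad_input <- function(msg) {
  rlang::abort(msg, class = "tagpanel_bad_input")
}
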