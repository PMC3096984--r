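#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tag panel into its report tibble
#'
#' One row per selected tag SNP: obligates first, remaining tags by
#' descending incremental contribution to the panel score.
#'
#' @param x A `tag_panel`.
#' @param ... Unused.
#' @return A tibble with columns `snp_id`, `panel`, `bin_id`, `populations`,
#'   `score`, `confidence_class`, `functional_class`, `probability`,
#'   `incremental_score`, `obligate_flag`, `cluster_id`.
#' @export
tidy.tag_panel <- function(x, ...) {
  x$report
}

#' One-row summary of a tag panel
#'
#' @param x A `tag_panel`.
#' @param ... Unused.
#' @return A one-row tibble: bin counts, tag count, panel score, obligates,
#'   tag deficit, functional sum, bead-type total, same-panel conflict count,
#'   and cluster search statistics.
#' @export
glance.tag_panel <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_bins = s$n_bins,
    n_tagged = s$n_tagged,
    n_untagged = s$n_untagged,
    n_tags = s$n_tags,
    panel_score = s$panel_score,
    n_obligates_selected = s$n_obligates_selected,
    tag_deficit = s$tag_deficit,
    functional_sum = s$functional_sum,
    bead_type_total = s$bead_type_total,
    same_panel_conflicts = s$same_panel_conflicts,
    n_clusters = nrow(x$run_log),
    n_clusters_exhausted = sum(x$run_log$exhausted),
    n_clusters_approximate = sum(x$run_log$approximate)
  )
}

#' Plot a tag panel
#'
#' `type = "probability"` compares the distribution of genotyping
#' probabilities among candidate tag SNPs before optimization with the
#' selected panel (enrichment of high-probability tags); `type =
#' "contribution"` shows each selected tag's incremental contribution to the
#' panel score.
#'
#' @param object A `tag_panel`.
#' @param type `"probability"` or `"contribution"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tag_panel <- function(object, type = c("probability", "contribution"),
                               ...) {
  type <- match.arg(type)
  if (type == "probability") {
    cand_ids <- unique(unlist(object$bins_filtered$candidates))
    cand <- object$snps[object$snps$snp_id %in% cand_ids, ]
    df <- dplyr::bind_rows(
      tibble::tibble(set = "candidates", probability = cand$probability),
      tibble::tibble(set = "selected",
                     probability = object$report$probability)
    )
    df <- dplyr::count(dplyr::group_by(df, .data$set),
                       probability = factor(.data$probability))
    df <- dplyr::mutate(df, fraction = .data$n / sum(.data$n))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$probability,
                                     y = .data$fraction,
                                     fill = .data$set)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "genotyping probability",
                    y = "fraction of tag SNPs", fill = NULL,
                    title = "Probability enrichment upon optimization") +
      ggplot2::theme_minimal()
  } else {
    df <- object$report
    df$snp_id <- factor(df$snp_id, levels = rev(df$snp_id))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$incremental_score,
                                     y = .data$snp_id,
                                     fill = .data$obligate_flag)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "incremental contribution to panel score",
                    y = NULL, fill = "obligate",
                    title = "Per-tag contribution") +
      ggplot2::theme_minimal()
  }
}
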