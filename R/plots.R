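#' Plot compartment expression profiles
#'
#' Line plot of per-gene NE across the ordered compartments, optionally
#' colored by coexpression group, on a log scale (the standard display for the
#' wide dynamic range of crystallin expression).
#'
#' @param profiles Wide profile tibble ([compartment_profiles()]).
#' @param groups Optional `coexpression_groups` or membership tibble; ungrouped
#'   genes are dropped when supplied.
#' @param log_scale Use log10 y axis (default TRUE).
#' @return A ggplot object.
#' @export
plot_compartment_profiles <- function(profiles, groups = NULL,
                                      log_scale = TRUE) {
  long <- profiles |>
    tidyr::pivot_longer(dplyr::all_of(lens_compartments),
                        names_to = "compartment", values_to = "ne") |>
    dplyr::mutate(compartment = as_compartment(.data$compartment))
  if (!is.null(groups)) {
    memb <- if (inherits(groups, "coexpression_groups")) groups$membership
            else groups
    long <- dplyr::inner_join(long, memb, by = "gene_id")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$compartment, y = .data$ne,
                                          group = .data$gene_id)) +
    ggplot2::geom_line(ggplot2::aes(
      color = if (is.null(groups)) NULL else .data$group)) +
    ggplot2::labs(x = "Lens compartment", y = "Normalized expression (NE)",
                  color = "Group") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.coexpression_groups <- function(object, profiles, ...) {
  plot_compartment_profiles(profiles, object, ...) +
    ggplot2::facet_wrap(~group, scales = "free_y")
}

#' @export
autoplot.venn_partition <- function(object, ...) {
  dat <- object$counts |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = rev(object$counts$category)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Differentially expressed genes",
                  y = "Adjacent comparisons") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.replicate_qc <- function(object, ...) {
  abort_if(object$degenerate, "degenerate QC object cannot be plotted")
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               color = .data$compartment,
                               shape = factor(.data$replicate))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2]),
      color = "Compartment", shape = "Replicate") +
    ggplot2::theme_minimal()
}

#' Plot ranked transcription-factor candidates
#'
#' @param candidates Output of [rank_candidates()].
#' @param top Show at most this many factors per group.
#' @return A ggplot object.
#' @export
plot_tf_ranking <- function(candidates, top = 10) {
  dat <- candidates |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_min(.data$rank_score, n = top) |>
    dplyr::ungroup() |>
    dplyr::mutate(factor_id = stats::reorder(.data$factor_id, .data$score))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$factor_id,
                                    fill = .data$unique_to_group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = expression(-log[10](P) %*% bar(R)^2),
                  y = NULL, fill = "Matrix unique to group") +
    ggplot2::theme_minimal()
}
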