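#' Correlate candidate factor expression with group-member profiles
#'
#' For each candidate transcription factor, the coefficient of determination
#' of its 4-point compartment profile against every member of a coexpression
#' group, and the mean across members. The per-member contribution is
#' sign-aware: an anticorrelated (r <= 0) member contributes 0, so the mean
#' reflects positive coexpression evidence only.
#'
#' @param profiles Wide profile tibble ([compartment_profiles()]) covering
#'   both factors and group members.
#' @param group Character vector of group member gene ids, or a
#'   `coexpression_groups` object plus `group_name`.
#' @param tf_ids Character vector of candidate factor gene ids.
#' @param group_name Group to use when `group` is a `coexpression_groups`.
#' @return List with `per_member` (tibble `tf_id`, `gene_id`, `r`, `r2`) and
#'   `per_tf` (tibble `tf_id`, `mean_r2`, `min_r2`, `all_positive`,
#'   `constant`, `quantified`). Factors absent from `profiles` are returned
#'   with `quantified = FALSE` and NA correlations.
#' @export
tf_expression_correlation <- function(profiles, group, tf_ids,
                                      group_name = NULL) {
  if (inherits(group, "coexpression_groups")) {
    abort_if(is.null(group_name), "group_name required")
    group <- group$membership$gene_id[group$membership$group == group_name]
  }
  m <- profile_matrix(profiles)
  miss_members <- setdiff(group, rownames(m))
  abort_if(length(miss_members) > 0,
           paste("group member(s) not quantified:",
                 paste(miss_members, collapse = ", ")))

  quantified <- tf_ids[tf_ids %in% rownames(m)]
  per_member <- purrr::map_dfr(quantified, function(tf) {
    purrr::map_dfr(group, function(g) {
      pr <- profile_r2(m[tf, ], m[g, ], n_expected = ncol(m))
      tibble::tibble(tf_id = tf, gene_id = g, r = pr$r, r2 = pr$r2,
                     constant = pr$constant)
    })
  })

  per_tf <- if (nrow(per_member) > 0) {
    per_member |>
      dplyr::group_by(.data$tf_id) |>
      dplyr::summarise(
        mean_r2 = mean(ifelse(.data$r > 0, .data$r2, 0)),
        min_r2 = min(.data$r2),
        all_positive = all(.data$r > 0),
        constant = any(.data$constant),
        .groups = "drop") |>
      dplyr::mutate(quantified = TRUE)
  } else {
    tibble::tibble(tf_id = character(), mean_r2 = numeric(),
                   min_r2 = numeric(), all_positive = logical(),
                   constant = logical(), quantified = logical())
  }
  not_q <- setdiff(tf_ids, quantified)
  if (length(not_q) > 0) {
    per_tf <- dplyr::bind_rows(per_tf, tibble::tibble(
      tf_id = not_q, mean_r2 = NA_real_, min_r2 = NA_real_,
      all_positive = NA, constant = NA, quantified = FALSE))
  }
  list(per_member = per_member, per_tf = per_tf)
}

#' Hypergeometric motif over-representation P value
#'
#' One-sided probability of observing at least `k` group promoters carrying
#' the matrix, given the number of carriers in the background universe. For a
#' matrix present in all members, k equals the group size.
#'
#' @param matrix_id Matrix identifier.
#' @param group Character vector of group member gene ids.
#' @param presence A `motif_scan` or logical presence matrix covering the
#'   universe.
#' @param universe Background gene ids (default all genes in the presence
#'   matrix); must contain the group.
#' @param k Carrier threshold (default: observed carriers in the group).
#' @return The hypergeometric tail probability P(X >= k).
#' @export
motif_enrichment_p <- function(matrix_id, group, presence,
                               universe = NULL, k = NULL) {
  pm <- presence_matrix(presence)
  if (is.null(universe)) universe <- rownames(pm)
  abort_if(!all(group %in% universe), "universe must contain the group")
  abort_if(length(universe) < length(group),
           "universe smaller than the group")
  abort_if(!matrix_id %in% colnames(pm), "matrix not in presence matrix")
  carriers <- sum(pm[universe, matrix_id])
  if (is.null(k)) k <- sum(pm[group, matrix_id])
  n <- length(group)
  N <- length(universe)
  stats::phyper(k - 1, carriers, N - carriers, n, lower.tail = FALSE)
}

#' Combined motif-evidence and correlation score
#'
#' score = -log10(P) * mean R2; monotone increasing in both evidence
#' components. A P of exactly 0 is clamped to the smallest positive double
#' with a warning.
#'
#' @param enrichment_p Enrichment P value(s) in (0, 1].
#' @param mean_r2 Mean profile R-squared in `[0, 1]`.
#' @return Numeric score(s).
#' @export
combined_score <- function(enrichment_p, mean_r2) {
  abort_if(any(enrichment_p < 0) || any(enrichment_p > 1),
           "enrichment_p must be in [0, 1]")
  abort_if(any(mean_r2 < 0 | mean_r2 > 1, na.rm = TRUE),
           "mean_r2 must be in [0, 1]")
  if (any(enrichment_p == 0)) {
    rlang::warn("P = 0 clamped to the smallest positive double")
    enrichment_p[enrichment_p == 0] <- .Machine$double.xmin
  }
  -log10(enrichment_p) * mean_r2
}

#' Rank candidate transcription factors per coexpression group
#'
#' For each group, considers every factor predicted to bind a matrix common to
#' all group members, annotates it with whether any such matrix is unique to
#' the group, its mean profile R-squared against the members, the matrix
#' enrichment P (the smallest over its common matrices), the combined score,
#' and the P < `p_cut` & mean R2 > `r2_cut` filter flag. Two ranking views are
#' reported as rank columns: `rank_score` orders by combined score
#' (descending; ties by smaller P, then factor id) over all candidates, and
#' `rank_filter` orders the filter-passing candidates by mean R-squared.
#'
#' @param groups `coexpression_groups` or membership tibble.
#' @param presence `motif_scan` or logical presence matrix.
#' @param partition Optional [partition_matrices()] result (recomputed if
#'   NULL).
#' @param profiles Wide profile table covering factors and members.
#' @param factor_map Tibble `factor_id`, `matrix_id` (factor gene ids must
#'   match `profiles` gene ids to be quantified).
#' @param universe Background universe for enrichment (default all genes in
#'   the presence matrix).
#' @param p_cut,r2_cut Filter thresholds (defaults 0.05 and 0.9).
#' @return Tibble with one row per (group, factor): `group`, `factor_id`,
#'   `matrix_ids`, `unique_to_group`, `mean_r2`, `enrichment_p`, `score`,
#'   `passes_filter`, `rank_score`, `rank_filter`. Unquantified factors are
#'   recorded in `attr(, "not_quantified")`.
#' @export
rank_candidates <- function(groups, presence, partition = NULL, profiles,
                            factor_map, universe = NULL,
                            p_cut = 0.05, r2_cut = 0.9) {
  members <- group_member_list(groups)
  pm <- presence_matrix(presence)
  if (is.null(partition)) partition <- partition_matrices(pm, groups)
  if (is.null(universe)) universe <- rownames(pm)

  not_quantified <- tibble::tibble(group = character(), factor_id = character())
  out <- purrr::map_dfr(names(members), function(g) {
    cm <- common_matrices(partition, g)
    um <- unique_matrices(partition, g)
    fm <- factor_map |> dplyr::filter(.data$matrix_id %in% cm)
    if (nrow(fm) == 0) return(tibble::tibble())

    tfc <- tf_expression_correlation(profiles, members[[g]],
                                     unique(fm$factor_id))
    nq <- tfc$per_tf$tf_id[!tfc$per_tf$quantified]
    if (length(nq) > 0) {
      not_quantified <<- dplyr::bind_rows(
        not_quantified, tibble::tibble(group = g, factor_id = nq))
    }

    enr <- vapply(cm, function(m)
      motif_enrichment_p(m, members[[g]], pm, universe), numeric(1))

    fm |>
      dplyr::group_by(factor_id = .data$factor_id) |>
      dplyr::summarise(
        matrix_ids = paste(sort(.data$matrix_id), collapse = ","),
        unique_to_group = any(.data$matrix_id %in% um),
        enrichment_p = min(enr[.data$matrix_id]),
        .groups = "drop") |>
      dplyr::inner_join(
        tfc$per_tf |> dplyr::filter(.data$quantified) |>
          dplyr::select("tf_id", "mean_r2", "all_positive"),
        by = c(factor_id = "tf_id")) |>
      dplyr::mutate(
        group = g,
        score = combined_score(.data$enrichment_p, .data$mean_r2),
        passes_filter = .data$enrichment_p < p_cut &
          .data$mean_r2 > r2_cut & .data$all_positive
      ) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$enrichment_p,
                     .data$factor_id) |>
      dplyr::mutate(rank_score = dplyr::row_number()) |>
      dplyr::arrange(dplyr::desc(.data$passes_filter),
                     dplyr::desc(.data$mean_r2)) |>
      dplyr::mutate(rank_filter = ifelse(.data$passes_filter,
                                         cumsum(.data$passes_filter),
                                         NA_integer_)) |>
      dplyr::relocate("group") |>
      dplyr::arrange(.data$rank_score)
  })
  attr(out, "not_quantified") <- not_quantified
  out
}
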