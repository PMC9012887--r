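#' Critical coefficient of determination for an n-point profile
#'
#' The R-squared value above which a Pearson correlation over n observations
#' attains two-tailed significance at level alpha, from the Student-t critical
#' value: R2 = t^2 / (t^2 + df) with df = n - 2 and
#' t = qt(1 - alpha/2, df). For n = 4 (df = 2) this has the closed form
#' (1 - alpha)^2, because the null distribution of r over 4 points is uniform
#' on [-1, 1]; at alpha = 0.05 the threshold is exactly 0.9025.
#'
#' @param n Number of observations (>= 3).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return The critical R-squared.
#' @export
critical_r2 <- function(n, alpha = 0.05) {
  abort_if(n < 3, "n must be >= 3 (df = n - 2 must be positive)")
  abort_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  df <- n - 2
  t <- stats::qt(1 - alpha / 2, df)
  t^2 / (t^2 + df)
}

#' Coefficient of determination between two compartment profiles
#'
#' Pearson correlation of the two profiles over the ordered compartments and
#' its square. A constant profile has no defined correlation; it is reported
#' as r = 0, R2 = 0 with `constant = TRUE`. Significance requires both
#' R2 > critical_r2(n, alpha) and r > 0 (coordinate expression, not mere
#' collinearity).
#'
#' @param a,b Numeric profiles of equal length (>= 3; the lens design uses 4).
#' @param alpha Significance level for the critical R-squared.
#' @param n_expected Expected profile length (default 4); a different length
#'   is an error.
#' @return One-row tibble `r`, `r2`, `sign`, `constant`, `significant`.
#' @export
profile_r2 <- function(a, b, alpha = 0.05, n_expected = 4) {
  abort_if(length(a) != n_expected || length(b) != n_expected,
           sprintf("profiles must have %d values", n_expected))
  constant <- stats::sd(a) == 0 || stats::sd(b) == 0
  r <- if (constant) 0 else stats::cor(a, b)
  r2 <- r^2
  tibble::tibble(
    r = r, r2 = r2, sign = sign(r), constant = constant,
    significant = !constant & r > 0 & r2 > critical_r2(length(a), alpha)
  )
}

#' All pairwise profile correlations
#'
#' @param profiles Wide profile tibble from [compartment_profiles()]
#'   (`gene_id` plus one column per compartment), or a gene x compartment
#'   numeric matrix.
#' @param alpha Significance level.
#' @return Tibble `gene_a`, `gene_b`, `r`, `r2`, `constant`, `significant`
#'   with one row per unordered gene pair.
#' @export
pairwise_r2 <- function(profiles, alpha = 0.05) {
  m <- profile_matrix(profiles)
  n_obs <- ncol(m)
  crit <- critical_r2(n_obs, alpha)
  sds <- apply(m, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[sds == 0, ] <- 0
  cm[, sds == 0] <- 0
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(
    gene_a = rownames(m)[idx[, 1]],
    gene_b = rownames(m)[idx[, 2]],
    r = cm[idx],
    r2 = cm[idx]^2,
    constant = unname(sds[idx[, 1]] == 0 | sds[idx[, 2]] == 0)
  ) |>
    dplyr::mutate(significant = !.data$constant & .data$r > 0 &
                    .data$r2 > crit)
}

profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  m <- as.matrix(profiles[setdiff(names(profiles), "gene_id")])
  rownames(m) <- profiles$gene_id
  m
}

#' Form coordinately expressed groups by threshold correlation
#'
#' Builds the graph whose edges join gene pairs with r > 0 and
#' R2 >= `threshold`, enumerates its maximal cliques, and reports them as
#' groups in deterministic order (largest first, ties by lexicographically
#' smallest member). A gene belonging to several maximal cliques is assigned
#' to the first (largest) one, with the ambiguity recorded. When
#' `require_separation` is set, a clique is reported only if every cross-pair
#' R2 against every already-reported group is below the significance
#' threshold `critical_r2(n_obs, alpha)`.
#'
#' @param x Pairwise correlation tibble from [pairwise_r2()], or a wide
#'   profile table (correlations are computed).
#' @param threshold Grouping R-squared floor (default 0.93, the observed
#'   within-group floor of the crystallin groups).
#' @param alpha Significance level for the separation criterion.
#' @param require_separation Enforce between-group separation (default TRUE).
#' @param n_obs Profile length used for the critical R-squared (default 4).
#' @return Object of class `coexpression_groups` with `membership` (tibble
#'   `group`, `gene_id`), `summary` (per group: size, minimum within-group R2,
#'   maximum R2 against any other reported group), `ambiguities`, `dropped`
#'   (cliques failing separation), plus the parameters. Supports [tidy()] and
#'   [glance()].
#' @export
form_groups <- function(x, threshold = 0.93, alpha = 0.05,
                        require_separation = TRUE, n_obs = 4) {
  abort_if(threshold <= 0 || threshold > 1, "threshold must be in (0, 1]")
  cors <- if (is.data.frame(x) && all(c("gene_a", "gene_b", "r2") %in% names(x)))
    x else pairwise_r2(x, alpha)
  genes <- sort(unique(c(cors$gene_a, cors$gene_b)))
  crit <- critical_r2(n_obs, alpha)

  edges <- cors |> dplyr::filter(.data$r > 0, .data$r2 >= threshold)
  g <- igraph::graph_from_data_frame(
    edges[c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes))
  cliques <- igraph::max_cliques(g)
  cliques <- lapply(cliques, function(cl) sort(names(cl)))
  # deterministic order: size desc, then lexicographic first member
  ord <- order(-vapply(cliques, length, 1L),
               vapply(cliques, `[`, "", 1))
  cliques <- cliques[ord]

  # fast pairwise R2 lookup
  r2_of <- function(g1, g2) {
    hit <- (cors$gene_a == g1 & cors$gene_b == g2) |
      (cors$gene_a == g2 & cors$gene_b == g1)
    if (!any(hit)) NA_real_ else cors$r2[hit][1]
  }
  cross_max_r2 <- function(members_a, members_b) {
    max(apply(expand.grid(members_a, members_b, stringsAsFactors = FALSE), 1,
              function(p) r2_of(p[1], p[2])), na.rm = TRUE)
  }

  assigned <- character()
  groups <- list()
  ambiguities <- tibble::tibble(gene_id = character(),
                                assigned_group = character(),
                                competing_clique = character())
  dropped <- list()
  for (cl in cliques) {
    overlap <- intersect(cl, assigned)
    members <- setdiff(cl, assigned)
    if (length(members) == 0) next
    if (length(overlap) > 0) {
      ambiguities <- dplyr::bind_rows(ambiguities, tibble::tibble(
        gene_id = overlap,
        assigned_group = names(groups)[vapply(overlap, function(gn)
          which(vapply(groups, function(gr) gn %in% gr, TRUE))[1], 1L)],
        competing_clique = paste(cl, collapse = ",")))
      rlang::inform(paste("ambiguous clique membership for:",
                          paste(overlap, collapse = ", ")))
    }
    if (require_separation && length(groups) > 0) {
      seps <- vapply(groups, function(gr) cross_max_r2(members, gr), 1)
      if (any(seps >= crit)) {
        dropped[[length(dropped) + 1]] <- tibble::tibble(
          clique = paste(members, collapse = ","),
          max_cross_r2 = max(seps))
        next
      }
    }
    groups[[sprintf("group%d", length(groups) + 1)]] <- members
    assigned <- c(assigned, members)
  }

  membership <- purrr::imap_dfr(groups, function(members, nm)
    tibble::tibble(group = nm, gene_id = members))

  summary <- purrr::imap_dfr(groups, function(members, nm) {
    within <- if (length(members) < 2) NA_real_ else
      min(apply(utils::combn(members, 2), 2, function(p) r2_of(p[1], p[2])))
    others <- setdiff(unlist(groups), members)
    between <- if (length(others) == 0) NA_real_ else
      cross_max_r2(members, others)
    tibble::tibble(group = nm, n = length(members),
                   min_within_r2 = within, max_between_r2 = between)
  })
  if (nrow(summary) > 0 && any(!is.na(summary$min_within_r2))) {
    stopifnot(all(summary$min_within_r2 >= threshold, na.rm = TRUE))
  }

  structure(list(membership = membership, summary = summary,
                 ambiguities = ambiguities,
                 dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                           else tibble::tibble(),
                 threshold = threshold, alpha = alpha,
                 separation_r2 = crit),
            class = "coexpression_groups")
}

#' @export
print.coexpression_groups <- function(x, ...) {
  cat(sprintf("Coexpression groups (R2 >= %.3f, separation R2 < %.4f)\n",
              x$threshold, x$separation_r2))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.coexpression_groups <- function(x, ...) x$membership

#' @export
glance.coexpression_groups <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$summary),
                 n_genes_grouped = nrow(x$membership),
                 min_within_r2 = suppressWarnings(min(x$summary$min_within_r2,
                                                      na.rm = TRUE)),
                 max_between_r2 = suppressWarnings(max(x$summary$max_between_r2,
                                                       na.rm = TRUE)),
                 n_ambiguous = nrow(x$ambiguities))
}

#' Replicate agreement QC by sample-level PCA
#'
#' Principal component analysis of log-transformed gene-level NE over samples.
#' Flags replicate pairs whose distance in the retained component space
#' exceeds `flag_factor` times the median between-compartment sample distance.
#'
#' @param ne NE tibble (gene or transcript level).
#' @param log_pseudocount Added before log10 (default 0.01).
#' @param flag_factor Distance-rule multiplier (default 0.5).
#' @return Object of class `replicate_qc` with `scores` (sample PCA scores),
#'   `variance_explained`, `replicate_distances` (with `flagged`), and
#'   `degenerate` (TRUE when fewer than 2 informative components exist).
#' @export
replicate_qc <- function(ne, log_pseudocount = 0.01, flag_factor = 0.5) {
  gn <- gene_ne(ne)
  abort_if(dplyr::n_distinct(gn$sample) < 2, "at least 2 samples required")
  wide <- gn |>
    dplyr::select("gene_id", "sample", "ne") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "ne")
  m <- t(log10(as.matrix(wide[-1]) + log_pseudocount))

  keep <- apply(m, 2, stats::sd) > 0
  meta <- gn |> dplyr::distinct(.data$sample, .data$compartment,
                                .data$replicate)
  if (sum(keep) < 2 || nrow(m) < 3) {
    return(structure(list(scores = NULL, variance_explained = NULL,
                          replicate_distances = NULL, degenerate = TRUE),
                     class = "replicate_qc"))
  }
  pca <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  k <- min(ncol(pca$x), 4)
  scores <- tibble::as_tibble(pca$x[, seq_len(k), drop = FALSE]) |>
    dplyr::mutate(sample = rownames(m), .before = 1) |>
    dplyr::left_join(meta, by = "sample")

  sm <- pca$x[, seq_len(k), drop = FALSE]
  d <- as.matrix(stats::dist(sm))
  same <- outer(scores$compartment, scores$compartment, "==")
  between_med <- stats::median(d[!same & upper.tri(d)])
  rep_dist <- scores |>
    dplyr::group_by(.data$compartment) |>
    dplyr::summarise(distance = {
      ss <- .data$sample
      if (length(ss) == 2) d[ss[1], ss[2]] else NA_real_
    }, .groups = "drop") |>
    dplyr::mutate(flagged = !is.na(.data$distance) & between_med > 0 &
                    .data$distance > flag_factor * between_med)

  structure(list(scores = scores, variance_explained = ve,
                 replicate_distances = rep_dist, degenerate = FALSE),
            class = "replicate_qc")
}

#' @export
print.replicate_qc <- function(x, ...) {
  if (x$degenerate) {
    cat("Replicate QC: degenerate input (fewer than 2 informative components)\n")
  } else {
    cat(sprintf("Replicate QC: PC1 %.1f%%, PC2 %.1f%% of variance\n",
                100 * x$variance_explained[1], 100 * x$variance_explained[2]))
    print(x$replicate_distances)
  }
  invisible(x)
}

#' @export
tidy.replicate_qc <- function(x, ...) {
  if (x$degenerate) return(tibble::tibble())
  x$scores
}

#' @export
glance.replicate_qc <- function(x, ...) {
  if (x$degenerate) return(tibble::tibble(degenerate = TRUE))
  tibble::tibble(degenerate = FALSE,
                 pc1_var = x$variance_explained[1],
                 pc2_var = x$variance_explained[2],
                 n_flagged = sum(x$replicate_distances$flagged))
}
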