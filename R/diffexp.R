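#' Audic-Claverie conditional probability mass
#'
#' The probability of observing `y` reads for a transcript in a library of
#' size `N2` given `x` reads in a library of size `N1`, under Poisson sampling
#' with a flat prior on the underlying rate:
#' p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)).
#' Computed in log space. (This is the negative binomial density with
#' size x + 1 and success probability N1/(N1+N2).)
#'
#' @param y,x Non-negative counts (vectorized).
#' @param n1,n2 Library sizes (> 0).
#' @param log Return log probability.
#' @return Numeric vector of probabilities.
#' @export
ac_pmf <- function(y, x, n1 = 1, n2 = 1, log = FALSE) {
  abort_if(any(x < 0) || any(y < 0), "counts must be non-negative")
  abort_if(any(n1 <= 0) || any(n2 <= 0), "library sizes must be positive")
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) -
    lgamma(y + 1) - (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

# Min-likelihood two-sided tail of the conditional distribution p(.|x) with
# depth ratio r = N2/N1, evaluated at observation y. Probabilities within a
# relative factor 1e-7 of the observed one count as ties (included).
ac_two_sided_onedir <- function(x, y, r) {
  size <- x + 1
  prob <- 1 / (1 + r)
  lp <- function(k) ac_pmf(k, x, 1, r, log = TRUE)
  thresh <- lp(y) + 1e-7
  m <- floor(x * r)  # mode of the conditional distribution
  if (lp(m) <= thresh) return(1)

  if (y < m) {
    lower <- stats::pnbinom(y, size, prob)
    # smallest b > m with lp(b) <= thresh (lp is non-increasing past the mode)
    lo <- m
    hi <- m + 1
    while (lp(hi) > thresh) {
      lo <- hi
      hi <- 2 * (hi - m) + m + 1
    }
    while (hi - lo > 1) {
      mid <- lo + (hi - lo) %/% 2
      if (lp(mid) > thresh) lo <- mid else hi <- mid
    }
    upper <- stats::pnbinom(hi - 1, size, prob, lower.tail = FALSE)
  } else {
    upper <- stats::pnbinom(y - 1, size, prob, lower.tail = FALSE)
    # largest a < m with lp(a) <= thresh (lp is non-decreasing up to the mode)
    if (m == 0 || lp(0) > thresh) {
      lower <- 0
    } else {
      lo <- 0
      hi <- m
      while (hi - lo > 1) {
        mid <- lo + (hi - lo) %/% 2
        if (lp(mid) <= thresh) lo <- mid else hi <- mid
      }
      lower <- stats::pnbinom(lo, size, prob)
    }
  }
  min(1, lower + upper)
}

#' Audic-Claverie two-sided P value
#'
#' Exact two-sided test for a difference in a transcript's counts between two
#' libraries under Poisson sampling. For each conditioning direction the
#' two-sided tail is the minimum-likelihood sum: all outcomes whose
#' conditional probability does not exceed that of the observation. The
#' reported P is the average of the two conditioning directions
#' (y given x, and x given y), which makes the statistic exactly symmetric
#' under (x, N1) <-> (y, N2).
#'
#' @param x,y Observed counts (vectorized).
#' @param n1,n2 Library sizes.
#' @return Numeric vector of P values in (0, 1].
#' @export
audic_claverie_p <- function(x, y, n1 = 1, n2 = 1) {
  abort_if(any(x < 0) || any(y < 0), "counts must be non-negative")
  abort_if(any(n1 <= 0) || any(n2 <= 0), "library sizes must be positive")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) {
    r <- n2[i] / n1[i]
    (ac_two_sided_onedir(x[i], y[i], r) +
       ac_two_sided_onedir(y[i], x[i], 1 / r)) / 2
  }, numeric(1))
}

#' Pairwise differential expression between compartments
#'
#' Applies the Audic-Claverie test transcript-wise for each requested
#' compartment pair, aggregates transcript P values to gene level (minimum
#' transcript P with a Sidak correction for the number of transcripts),
#' adjusts across genes within each comparison, and computes a log2 fold
#' change from compartment-mean NE.
#'
#' @param counts Counts tibble or `synthetic_lens_counts` object.
#' @param samples Sample sheet (taken from the object when available).
#' @param pairs List of length-2 compartment vectors (default all 6 pairs);
#'   see [adjacent_pairs()] and [all_pairs()].
#' @param alpha Significance level on the adjusted P (default 0.05).
#' @param adjust Multiple-testing adjustment across genes within each
#'   comparison: `"BH"` (default) or `"bonferroni"`.
#' @param replicate_mode `"sum"` (default): replicate counts are summed per
#'   compartment before testing. `"both"`: the two replicate-wise tests are
#'   run separately and the larger P is kept (significance then requires both
#'   replicates to agree).
#' @param pseudocount NE pseudocount for the log2 fold change (default 0.5).
#' @param library_sizes Optional named per-sample totals (default column
#'   sums).
#' @return Tibble with one row per gene and pair: `gene_id`, `pair`,
#'   `comp_a`, `comp_b`, `x`, `y`, `n1`, `n2`, `p`, `p_adj`, `log2fc`,
#'   `significant`.
#' @export
test_all_pairs <- function(counts, samples = NULL, pairs = all_pairs(),
                           alpha = 0.05, adjust = c("BH", "bonferroni"),
                           replicate_mode = c("sum", "both"),
                           pseudocount = 0.5, library_sizes = NULL) {
  adjust <- match.arg(adjust)
  replicate_mode <- match.arg(replicate_mode)
  if (inherits(counts, "synthetic_lens_counts")) {
    samples <- counts$samples
    counts <- counts$counts
  }
  abort_if(is.null(samples), "a sample sheet is required")
  comps <- unique(unlist(pairs))
  abort_if(!all(comps %in% lens_compartments),
           paste("unknown compartment in pairs:",
                 paste(setdiff(comps, lens_compartments), collapse = ", ")))

  sample_cols <- intersect(names(counts), samples$sample)
  mat <- as.matrix(counts[sample_cols])
  if (is.null(library_sizes)) {
    library_sizes <- colSums(mat)
  } else {
    library_sizes <- library_sizes[sample_cols]
  }

  ne_means <- compartment_means(compute_ne(counts, samples,
                                           library_sizes = library_sizes))

  cols_of <- function(comp, rep = NULL) {
    sel <- samples$sample[samples$compartment == comp &
                            (is.null(rep) | samples$replicate %in% rep)]
    intersect(sel, sample_cols)
  }

  purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    ca <- cols_of(a); cb <- cols_of(b)
    abort_if(length(ca) == 0 || length(cb) == 0,
             sprintf("no samples for comparison %s", pair_label(pr)))

    x <- rowSums(mat[, ca, drop = FALSE])
    y <- rowSums(mat[, cb, drop = FALSE])
    N1 <- sum(library_sizes[ca]); N2 <- sum(library_sizes[cb])

    if (replicate_mode == "sum") {
      p_t <- audic_claverie_p(x, y, N1, N2)
    } else {
      reps <- sort(unique(samples$replicate))
      p_reps <- vapply(reps, function(r) {
        car <- cols_of(a, r); cbr <- cols_of(b, r)
        audic_claverie_p(rowSums(mat[, car, drop = FALSE]),
                         rowSums(mat[, cbr, drop = FALSE]),
                         sum(library_sizes[car]), sum(library_sizes[cbr]))
      }, numeric(nrow(mat)))
      p_t <- apply(p_reps, 1, max)
    }

    gene_tbl <- tibble::tibble(gene_id = counts$gene_id,
                               x = x, y = y, p_t = p_t) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        x = sum(.data$x), y = sum(.data$y),
        p = 1 - (1 - min(.data$p_t))^dplyr::n(),  # Sidak over transcripts
        .groups = "drop"
      ) |>
      dplyr::mutate(p = pmin(1, .data$p),
                    p_adj = stats::p.adjust(.data$p, method = adjust))

    fc <- ne_means |>
      dplyr::filter(.data$compartment %in% c(a, b)) |>
      tidyr::pivot_wider(names_from = "compartment", values_from = "ne") |>
      dplyr::mutate(log2fc = log2((.data[[b]] + pseudocount) /
                                    (.data[[a]] + pseudocount))) |>
      dplyr::select("gene_id", "log2fc")

    gene_tbl |>
      dplyr::left_join(fc, by = "gene_id") |>
      dplyr::mutate(pair = pair_label(pr), comp_a = a, comp_b = b,
                    n1 = N1, n2 = N2,
                    significant = .data$p_adj < alpha) |>
      dplyr::relocate("pair", "comp_a", "comp_b", .after = "gene_id")
  })
}

venn_categories <- function(labels) {
  subsets <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = " & ", simplify = FALSE)))
  unlist(subsets)
}

#' Partition genes over the adjacent-comparison Venn diagram
#'
#' Labels each gene by the subset of the three adjacent comparisons (EC-EQ,
#' EQ-FP, FP-FC) in which it is significant: 7 disjoint non-empty categories
#' plus `"none"`. Category counts over the 7 categories sum to the number of
#' genes significant in at least one adjacent comparison.
#'
#' @param de Differential-expression tibble from [test_all_pairs()]; must
#'   contain all requested adjacent comparisons.
#' @param adjacent List of adjacent compartment pairs (default
#'   [adjacent_pairs()]).
#' @return Object of class `venn_partition` with `labels` (tibble `gene_id`,
#'   `category`) and `counts` (tibble `category`, `n`, zeros included, in
#'   canonical subset order). Supports [tidy()], [glance()] and [autoplot()].
#' @export
venn_partition <- function(de, adjacent = adjacent_pairs()) {
  wanted <- vapply(adjacent, pair_label, "")
  missing <- setdiff(wanted, unique(de$pair))
  abort_if(length(missing) > 0,
           paste("missing comparison(s):", paste(missing, collapse = ", ")))

  cats <- venn_categories(wanted)
  labels <- de |>
    dplyr::filter(.data$pair %in% wanted) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(category = {
      sig <- wanted[wanted %in% .data$pair[.data$significant]]
      if (length(sig) == 0) "none" else paste(sig, collapse = " & ")
    }, .groups = "drop")

  counts <- tibble::tibble(category = cats) |>
    dplyr::left_join(dplyr::count(labels, .data$category), by = "category") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))

  structure(list(labels = labels, counts = counts, comparisons = wanted),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Adjacent-comparison Venn partition\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.venn_partition <- function(x, ...) x$labels

#' @export
glance.venn_partition <- function(x, ...) {
  tibble::tibble(n_significant = sum(x$counts$n),
                 n_genes = nrow(x$labels),
                 n_categories_nonzero = sum(x$counts$n > 0))
}
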