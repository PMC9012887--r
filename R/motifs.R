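#' Extract strand-aware upstream promoter windows
#'
#' For a plus-strand gene the promoter is the window `[tss - window, tss)` in
#' 0-based half-open coordinates; for a minus-strand gene it is
#' `[tss + 1, tss + window]` on the reference, reverse complemented. Windows
#' are truncated at contig edges with a warning; a TSS lying off its contig
#' produces a per-gene error record instead of a sequence.
#'
#' @param tss Tibble `gene_id`, `chrom`, `tss` (0-based position of the
#'   transcription start base), `strand` (`"+"`/`"-"`).
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector)
#'   of contigs.
#' @param window Window length in bases (default 1000).
#' @return Named [Biostrings::DNAStringSet] of promoters; genes with errors
#'   are omitted and recorded in `attr(, "errors")` (tibble `gene_id`,
#'   `reason`).
#' @export
extract_promoters <- function(tss, genome, window = 1000) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  abort_if(is.null(names(genome)), "genome contigs must be named")
  seqs <- character(0)
  errors <- list()
  truncated <- character(0)
  for (i in seq_len(nrow(tss))) {
    gene <- tss$gene_id[i]
    chrom <- tss$chrom[i]
    if (!chrom %in% names(genome)) {
      errors[[length(errors) + 1]] <- tibble::tibble(
        gene_id = gene, reason = paste("unknown contig", chrom))
      next
    }
    clen <- Biostrings::width(genome[chrom])
    pos <- tss$tss[i]  # 0-based
    if (pos < 0 || pos >= clen) {
      errors[[length(errors) + 1]] <- tibble::tibble(
        gene_id = gene, reason = "TSS off contig")
      next
    }
    if (tss$strand[i] == "+") {
      start0 <- max(0, pos - window)  # [start0, pos)
      if (start0 > pos - window) truncated <- c(truncated, gene)
      if (pos == 0) {
        seqs[gene] <- ""
        next
      }
      s <- Biostrings::subseq(genome[[chrom]], start = start0 + 1, end = pos)
      seqs[gene] <- as.character(s)
    } else {
      end0 <- min(clen - 1, pos + window)  # (pos, end0] 0-based inclusive
      if (end0 < pos + window) truncated <- c(truncated, gene)
      if (pos + 1 > clen - 1) {
        seqs[gene] <- ""
        next
      }
      s <- Biostrings::subseq(genome[[chrom]], start = pos + 2, end = end0 + 1)
      seqs[gene] <- as.character(Biostrings::reverseComplement(s))
    }
  }
  if (length(truncated) > 0) {
    rlang::warn(paste("promoter window truncated at contig edge for:",
                      paste(truncated, collapse = ", ")))
  }
  out <- Biostrings::DNAStringSet(seqs)
  attr(out, "errors") <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(gene_id = character(), reason = character())
  out
}

# Exact distribution of the per-window log-odds score under the background
# model, by dynamic-programming convolution over positions on a discretized
# score grid. Returns the smallest score whose upper tail probability is
# <= p_value.
pwm_score_threshold <- function(logodds, background, p_value,
                                granularity = 1e-3) {
  w <- ncol(logodds)
  grid <- round(logodds / granularity)
  offsets <- apply(grid, 2, min)
  spans <- apply(grid, 2, max) - offsets
  total_span <- sum(spans)
  dist <- c(1, numeric(total_span))  # probability over shifted integer scores
  pos0 <- 0
  for (j in seq_len(w)) {
    newdist <- numeric(pos0 + spans[j] + 1)
    for (b in 1:4) {
      sh <- grid[b, j] - offsets[j]
      idx <- seq_len(pos0 + 1) + sh
      newdist[idx] <- newdist[idx] + background[b] * dist[seq_len(pos0 + 1)]
    }
    dist <- newdist
    pos0 <- pos0 + spans[j]
  }
  tail_p <- rev(cumsum(rev(dist)))
  k <- which(tail_p <= p_value)[1]
  if (is.na(k)) return(Inf)  # p_value smaller than the max-score mass
  ((k - 1) + sum(offsets)) * granularity
}

scan_one <- function(codes, logodds, n_score) {
  w <- ncol(logodds)
  L <- length(codes)
  if (L < w) return(numeric(0))
  npos <- L - w + 1
  sc <- numeric(npos)
  for (j in seq_len(w)) {
    col <- c(n_score[j], logodds[, j])  # index 1 = N, 2:5 = A,C,G,T
    sc <- sc + col[codes[j:(j + npos - 1)] + 1]
  }
  sc
}

#' Scan promoters with a PWM collection
#'
#' Log-likelihood-ratio scoring of every window position against a 0-order
#' background model, on both strands. A gene carries a matrix ("presence")
#' when at least one window scores at or above the matrix's threshold. The
#' default threshold is the score whose upper-tail probability per position
#' under the background model is `p_value` (exact, via dynamic programming on
#' the score distribution); the alternative is a fraction of the maximum
#' attainable score. `N` positions contribute the expected background
#' log-odds.
#'
#' @param promoters Named [Biostrings::DNAStringSet] or named character
#'   vector over A/C/G/T/N.
#' @param pwms A [pwm_set()] (or named list of matrices).
#' @param threshold `"pvalue"` (default) or `"fraction"`.
#' @param p_value Per-position tail probability for the `"pvalue"` rule
#'   (default 1e-4).
#' @param fraction Relative-score cutoff for the `"fraction"` rule (default
#'   0.8: hits score at least 80% of the way from the minimum to the maximum
#'   attainable score).
#' @param background Named A/C/G/T frequencies; default estimated from the
#'   scanned sequences (0-order).
#' @return Object of class `motif_scan` with `presence` (gene x matrix logical
#'   matrix), `hits` (tibble `gene_id`, `matrix_id`, `start`, `end`, `strand`,
#'   `score`; 0-based half-open, minus-strand hits reported on reference-like
#'   promoter coordinates), and `params`. Supports [tidy()].
#' @export
scan_promoters <- function(promoters, pwms,
                           threshold = c("pvalue", "fraction"),
                           p_value = 1e-4, fraction = 0.8,
                           background = NULL) {
  threshold <- match.arg(threshold)
  mats <- if (inherits(pwms, "pwm_set")) pwms$matrices else pwms
  abort_if(length(mats) == 0, "empty PWM set")
  if (inherits(promoters, "DNAStringSet")) {
    seqs <- as.character(promoters)
  } else {
    seqs <- promoters
  }
  abort_if(is.null(names(seqs)), "promoters must be named by gene")
  up <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  ok <- c(A = 1, C = 2, G = 3, T = 4)
  codes <- lapply(up, function(ch) {
    v <- unname(ok[ch])
    v[is.na(v)] <- 0L  # N / ambiguity codes
    as.integer(v)
  })

  if (is.null(background)) {
    tab <- table(factor(unlist(up), levels = DNA_BASES))
    abort_if(sum(tab) == 0, "no A/C/G/T content to estimate background from")
    background <- as.numeric(tab) / sum(tab)
  } else {
    background <- as.numeric(background[DNA_BASES]) / sum(background[DNA_BASES])
  }

  genes <- names(seqs)
  presence <- matrix(FALSE, nrow = length(genes), ncol = length(mats),
                     dimnames = list(genes, names(mats)))
  hits <- list()

  for (mid in names(mats)) {
    p <- pwm_normalize(mats[[mid]])
    lo <- log2(p / background)
    w <- ncol(lo)
    thr <- switch(threshold,
      pvalue = pwm_score_threshold(lo, background, p_value),
      fraction = {
        smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
        smin + fraction * (smax - smin)
      })
    n_score <- colSums(lo * background)  # expected background contribution
    lo_rc <- pwm_revcomp(lo)
    n_score_rc <- colSums(lo_rc * background)
    for (g in genes) {
      sc_f <- scan_one(codes[[g]], lo, n_score)
      sc_r <- scan_one(codes[[g]], lo_rc, n_score_rc)
      hf <- which(sc_f >= thr)
      hr <- which(sc_r >= thr)
      if (length(hf) + length(hr) > 0) {
        presence[g, mid] <- TRUE
        hits[[length(hits) + 1]] <- tibble::tibble(
          gene_id = g, matrix_id = mid,
          start = c(hf, hr) - 1L, end = c(hf, hr) - 1L + w,
          strand = rep(c("+", "-"), c(length(hf), length(hr))),
          score = c(sc_f[hf], sc_r[hr]))
      }
    }
  }

  structure(list(
    presence = presence,
    hits = if (length(hits)) dplyr::bind_rows(hits) else
      tibble::tibble(gene_id = character(), matrix_id = character(),
                     start = integer(), end = integer(),
                     strand = character(), score = numeric()),
    params = list(threshold = threshold, p_value = p_value,
                  fraction = fraction, background = background)),
    class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat(sprintf("Motif scan: %d genes x %d matrices, %d hits (%s rule)\n",
              nrow(x$presence), ncol(x$presence), nrow(x$hits),
              x$params$threshold))
  invisible(x)
}

#' @export
tidy.motif_scan <- function(x, ...) x$hits

#' Gene x matrix presence matrix
#'
#' @param x A `motif_scan` object (or a logical matrix, returned as is).
#' @return Logical matrix, genes x matrices.
#' @export
presence_matrix <- function(x) {
  if (inherits(x, "motif_scan")) x$presence else x
}

group_member_list <- function(groups) {
  if (inherits(groups, "coexpression_groups")) groups <- groups$membership
  abort_if(!all(c("group", "gene_id") %in% names(groups)),
           "groups must have columns `group` and `gene_id`")
  split(groups$gene_id, groups$group)
}

#' Partition binding-site matrices into group-common and group-unique sets
#'
#' A matrix is "common to" a group when it is present in the promoter of every
#' member. The partition classifies each group-common matrix by the exact set
#' of groups it is common to: common to all groups, shared by a subset, or
#' unique to one group ("unique" means not common to any other group;
#' presence in some, but not all, promoters of another group does not
#' disqualify). The additive identity |common(g)| = sum of the subset cells
#' containing g holds by construction and is asserted.
#'
#' @param presence A `motif_scan` object or gene x matrix logical matrix.
#' @param groups A `coexpression_groups` object or tibble `group`, `gene_id`.
#' @return Object of class `matrix_partition` with `membership` (tibble
#'   `matrix_id`, `category`, `n_groups`; category is the "+"-joined set of
#'   groups the matrix is common to), `cells` (tibble `category`, `n`),
#'   `per_group` (tibble `group`, `n_common`, `n_unique`, `n_all_groups`), and
#'   `common` (named list of matrix ids per group). Supports [tidy()] and
#'   [glance()].
#' @export
partition_matrices <- function(presence, groups) {
  pm <- presence_matrix(presence)
  members <- group_member_list(groups)
  sizes <- vapply(members, length, 1L)
  abort_if(length(members) == 0 || any(sizes == 0),
           "group with zero members")
  miss <- setdiff(unlist(members), rownames(pm))
  abort_if(length(miss) > 0,
           paste("group member(s) missing from presence matrix:",
                 paste(miss, collapse = ", ")))

  common <- lapply(members, function(gs) {
    colnames(pm)[colSums(pm[gs, , drop = FALSE]) == length(gs)]
  })
  gnames <- names(members)

  all_common <- sort(unique(unlist(common)))
  membership <- tibble::tibble(matrix_id = character(),
                               category = character(),
                               n_groups = integer())
  if (length(all_common) > 0) {
    membership <- purrr::map_dfr(all_common, function(m) {
      in_g <- gnames[vapply(common, function(cm) m %in% cm, TRUE)]
      tibble::tibble(matrix_id = m,
                     category = paste(in_g, collapse = "+"),
                     n_groups = length(in_g))
    })
  }

  cells <- membership |> dplyr::count(.data$category)
  per_group <- purrr::map_dfr(gnames, function(g) {
    tibble::tibble(
      group = g,
      n_common = length(common[[g]]),
      n_unique = sum(membership$category == g),
      n_all_groups = sum(membership$n_groups == length(gnames)))
  })

  # additive identity: each group's common count is the sum of its cells
  for (g in gnames) {
    in_cat <- vapply(strsplit(membership$category, "\\+"),
                     function(s) g %in% s, TRUE)
    stopifnot(sum(in_cat) == length(common[[g]]))
  }

  structure(list(membership = membership, cells = cells,
                 per_group = per_group, common = common),
            class = "matrix_partition")
}

#' Matrices common to all members of a group
#' @param partition A `matrix_partition`.
#' @param group Group name.
#' @return Character vector of matrix ids.
#' @export
common_matrices <- function(partition, group) partition$common[[group]]

#' Matrices unique to a group
#' @inheritParams common_matrices
#' @return Character vector of matrix ids common to all members of `group` but
#'   not common to all members of any other group.
#' @export
unique_matrices <- function(partition, group) {
  partition$membership$matrix_id[partition$membership$category == group]
}

#' @export
print.matrix_partition <- function(x, ...) {
  cat("Matrix partition across groups\n")
  print(x$per_group)
  invisible(x)
}

#' @export
tidy.matrix_partition <- function(x, ...) x$membership

#' @export
glance.matrix_partition <- function(x, ...) {
  tibble::tibble(n_matrices = nrow(x$membership),
                 n_groups = nrow(x$per_group),
                 n_all_groups = x$per_group$n_all_groups[1])
}
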