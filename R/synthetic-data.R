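#' Default compartment profile shapes for planted coexpression groups
#'
#' Three stylized expression patterns over (EC, EQ, FP, FC), with the fold
#' ranges typical of highly expressed crystallins: group 1 rises about
#' tenfold from the central to the equatorial epithelium and then plateaus
#' (slight decline into the fibers); group 2 increases dramatically
#' (tens-fold) from the epithelia into the fiber cells; group 3 rises from
#' the epithelia, peaking in the cortical fibers. Pairwise profile R-squared
#' of the shapes is 0.23, 0.63 and 0.56, all well below the n = 4 critical
#' R-squared, so the groups are separable in expectation.
#'
#' @return Named list of three non-negative length-4 numeric vectors.
#' @export
default_profile_shapes <- function() {
  list(
    group1 = c(1.0, 9.0, 9.0, 8.0),
    group2 = c(1.0, 2.0, 25.0, 40.0),
    group3 = c(0.5, 4.0, 10.0, 7.0)
  )
}

#' Configuration for the synthetic lens dataset generator
#'
#' Defines the study conditions the generator emulates: a 4-compartment x
#' 2-replicate count matrix with planted coordinately expressed groups of
#' distinct profile shape, one dominant transcript whose share of the mRNA pool
#' rises from 2.5% to 16% across compartments, a panel of housekeeping genes
#' with constant true abundance, negative-binomial count noise, and promoter
#' sequences carrying planted group-specific binding-site motifs.
#'
#' @param n_genes Total number of genes (planted roles plus background).
#' @param group_sizes Integer vector, one planted coexpression group per entry.
#'   Default `c(4, 5, 2)`, the sizes of the three crystallin groups.
#' @param profile_shapes List of length-4 non-negative shape vectors, one per
#'   group; shapes must be pairwise separable (profile R-squared below the
#'   n = 4 critical value).
#' @param dominant_fractions Expected share of the read pool taken by the
#'   dominant transcript in each compartment, each in `[0, 1)`. Default
#'   `c(0.025, 0.05, 0.12, 0.16)`; the end points are the reported rise of the
#'   delta1-crystallin fraction, the middle values interpolate.
#' @param include_dominant Plant the dominant transcript at all.
#' @param housekeeping_count Number of constant-abundance housekeeping genes
#'   (default 14, matching the size of the standard control panel).
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion *
#'   mu^2). Default 0.01, i.e. a 10% biological coefficient of variation
#'   between pooled replicates.
#' @param noise_model One of `"nb"` (negative binomial, default), `"poisson"`
#'   (dispersion-free limit; the null model of the Audic-Claverie test),
#'   `"multinomial"` (column sums exactly equal to `library_sizes`), or
#'   `"expected"` (noise-free: counts are rounded expectations).
#' @param library_sizes 8 positive values, one per sample (4 compartments x 2
#'   replicates). Default 1e7 reads each, the order of magnitude of a bulk
#'   lens library.
#' @param transcripts_per_gene Number of transcript isoforms per gene
#'   (default 1); gene abundance is split over isoforms at fixed random
#'   proportions.
#' @param promoter_length Promoter window length in bases (default 1000).
#' @param background_motif_prob Probability that a background promoter carries
#'   one randomly chosen motif instance (default 0.05).
#' @param base_composition Named A/C/G/T probabilities for background promoter
#'   sequence.
#' @param ratio_pair Include a fixed 4:1 abundance pair of genes (an
#'   alphaA/alphaB-crystallin-like fixture for ratio-invariance tests).
#' @param include_regulators Plant, per group, one regulator gene whose
#'   expression follows the group shape and bind it to the group's motif, plus
#'   one uncorrelated factor bound to the same motif and one decoy factor bound
#'   to a decoy motif.
#' @param group_scale,background_scale Median true abundance of group genes and
#'   of background/housekeeping genes (arbitrary molar units).
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration.
#'
#' @return Object of class `synthetic_config` (a validated named list).
#' @export
synthetic_config <- function(n_genes = 60,
                             group_sizes = c(4, 5, 2),
                             profile_shapes = default_profile_shapes(),
                             dominant_fractions = c(EC = 0.025, EQ = 0.05,
                                                    FP = 0.12, FC = 0.16),
                             include_dominant = TRUE,
                             housekeeping_count = 14,
                             dispersion = 0.01,
                             noise_model = c("nb", "poisson", "multinomial",
                                             "expected"),
                             library_sizes = rep(1e7, 8),
                             transcripts_per_gene = 1,
                             promoter_length = 1000,
                             background_motif_prob = 0.05,
                             base_composition = c(A = 0.3, C = 0.2,
                                                  G = 0.2, T = 0.3),
                             ratio_pair = FALSE,
                             include_regulators = TRUE,
                             group_scale = 50,
                             background_scale = 5,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  group_sizes <- as.integer(group_sizes)
  n_groups <- length(group_sizes)
  if (n_groups == 0) profile_shapes <- list()

  abort_if(length(profile_shapes) != n_groups,
           "profile_shapes must supply one shape per group")
  abort_if(!all(vapply(profile_shapes, length, 1L) == 4),
           "each profile shape must have 4 values (EC, EQ, FP, FC)")
  abort_if(any(unlist(profile_shapes) < 0), "profile shapes must be non-negative")
  abort_if(any(dominant_fractions < 0) || any(dominant_fractions >= 1),
           "dominant_fractions must lie in [0, 1)")
  abort_if(length(library_sizes) != 8 || any(library_sizes <= 0),
           "library_sizes must be 8 positive values")
  abort_if(dispersion < 0, "dispersion must be non-negative")
  abort_if(transcripts_per_gene < 1, "transcripts_per_gene must be >= 1")

  # group shapes must be separable in expectation
  if (n_groups > 1) {
    shp <- do.call(cbind, profile_shapes)
    r2 <- stats::cor(shp)^2
    worst <- max(r2[upper.tri(r2)])
    abort_if(worst >= critical_r2(4, 0.05),
             sprintf("profile shapes are not separable: max pairwise R^2 = %.3f",
                     worst))
  }

  n_special <- sum(group_sizes) + housekeeping_count +
    as.integer(include_dominant) + 2L * as.integer(ratio_pair) +
    if (include_regulators) 3L * n_groups else 0L
  abort_if(n_special > n_genes,
           sprintf("group_sizes plus planted roles (%d genes) exceed n_genes (%d)",
                   n_special, n_genes))

  cfg <- list(
    n_genes = as.integer(n_genes),
    group_sizes = as.integer(group_sizes),
    n_groups = n_groups,
    profile_shapes = profile_shapes,
    dominant_fractions = stats::setNames(as.numeric(dominant_fractions),
                                         lens_compartments),
    include_dominant = include_dominant,
    housekeeping_count = as.integer(housekeeping_count),
    dispersion = dispersion,
    noise_model = noise_model,
    library_sizes = as.numeric(library_sizes),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    promoter_length = as.integer(promoter_length),
    background_motif_prob = background_motif_prob,
    base_composition = base_composition / sum(base_composition),
    ratio_pair = ratio_pair,
    include_regulators = include_regulators,
    group_scale = group_scale,
    background_scale = background_scale,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synthetic_config")
}

group_names <- function(config) names(config$profile_shapes)

# Gene roster with roles and true per-compartment molar abundance.
build_roster <- function(config) {
  shapes <- config$profile_shapes
  gnames <- group_names(config)
  rows <- list()

  for (g in seq_along(config$group_sizes)) {
    for (i in seq_len(config$group_sizes[g])) {
      scale <- stats::rlnorm(1, log(config$group_scale), 0.8)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = sprintf("G%d_%02d", g, i), role = "group",
        group = gnames[g], abundance = list(shapes[[g]] * scale))
    }
  }

  if (config$include_regulators) {
    for (g in seq_along(config$group_sizes)) {
      scale <- stats::rlnorm(1, log(config$group_scale / 5), 0.3)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = sprintf("REG%d", g), role = "regulator",
        group = gnames[g], abundance = list(shapes[[g]] * scale))
      # a factor bound to the same motif but with a flat, uncorrelated profile
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = sprintf("TFU%d", g), role = "tf_uncorrelated",
        group = NA_character_,
        abundance = list(rep(stats::rlnorm(1, log(config$group_scale / 5), 0.3), 4)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = sprintf("TFD%d", g), role = "tf_decoy",
        group = NA_character_,
        abundance = list(rep(stats::rlnorm(1, log(config$group_scale / 5), 0.3), 4)))
    }
  }

  for (i in seq_len(config$housekeeping_count)) {
    level <- stats::rlnorm(1, log(config$background_scale * 2), 1.2)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = sprintf("HK%02d", i), role = "housekeeping",
      group = NA_character_, abundance = list(rep(level, 4)))
  }

  if (config$ratio_pair) {
    base <- config$profile_shapes[[1]] * config$group_scale
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = "RPA", role = "ratio_pair", group = NA_character_,
      abundance = list(base * 4))
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = "RPB", role = "ratio_pair", group = NA_character_,
      abundance = list(base))
  }

  if (config$include_dominant) {
    # placeholder; solved after the rest of the pool is known
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = "DOM1", role = "dominant", group = NA_character_,
      abundance = list(rep(NA_real_, 4)))
  }

  n_bg <- config$n_genes - length(rows)
  for (i in seq_len(n_bg)) {
    level <- stats::rlnorm(1, log(config$background_scale), 0.8)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = sprintf("BG%03d", i), role = "background",
      group = NA_character_, abundance = list(rep(level, 4)))
  }

  dplyr::bind_rows(rows)
}

#' Sample metadata table for the 4 x 2 design
#'
#' @param library_sizes Optional 8 library sizes to attach.
#' @return Tibble with `sample`, `compartment`, `replicate` (and
#'   `library_size` when supplied), samples ordered EC_1, EC_2, ..., FC_2.
#' @export
sample_sheet <- function(library_sizes = NULL) {
  s <- tibble::tibble(
    compartment = rep(lens_compartments, each = 2),
    replicate = rep(1:2, times = 4)
  ) |>
    dplyr::mutate(sample = paste0(.data$compartment, "_", .data$replicate),
                  .before = 1)
  if (!is.null(library_sizes)) s$library_size <- as.numeric(library_sizes)
  s
}

#' Generate a synthetic compartment count matrix with known ground truth
#'
#' Draws a transcript x 8-sample integer count matrix emulating pooled-lens
#' bulk RNA-seq over the four compartments with two replicates each. Expected
#' counts are proportional to true molar abundance times transcript length;
#' the dominant transcript's expected read share per compartment equals
#' `config$dominant_fractions`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_lens_counts` with elements
#'   `counts` (tibble: `transcript_id`, `gene_id`, `length`, 8 sample columns),
#'   `samples` (the sample sheet with library sizes), and `truth` (list with
#'   `genes` role/group table, `true_abundance` gene x compartment tibble,
#'   `housekeeping_ids`, `dominant_id`).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    roster <- build_roster(config)

    # transcripts and lengths
    tpg <- config$transcripts_per_gene
    tx <- roster |>
      dplyr::select("gene_id") |>
      tidyr::uncount(tpg) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::mutate(isoform = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        transcript_id = if (tpg == 1) .data$gene_id
                        else paste0(.data$gene_id, ".", .data$isoform),
        length = pmax(200L, as.integer(round(stats::rlnorm(dplyr::n(),
                                                           log(2000), 0.4))))
      )
    # split gene abundance across isoforms at fixed proportions
    tx <- tx |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::mutate(iso_frac = {
        w <- stats::rgamma(dplyr::n(), shape = 5); w / sum(w)
      }) |>
      dplyr::ungroup()

    abundance <- do.call(rbind, roster$abundance)
    rownames(abundance) <- roster$gene_id
    colnames(abundance) <- lens_compartments

    # expected read weight per transcript and compartment
    len_kb <- tx$length / 1000
    wt <- abundance[tx$gene_id, , drop = FALSE] * tx$iso_frac * len_kb

    if (config$include_dominant) {
      dom_row <- which(tx$gene_id == "DOM1")
      rest <- colSums(wt[-dom_row, , drop = FALSE])
      f <- config$dominant_fractions
      total_w <- f / (1 - f) * rest  # summed dominant weight per compartment
      per_kb <- tx$iso_frac[dom_row] * len_kb[dom_row]
      wt[dom_row, ] <- outer(per_kb / sum(per_kb), total_w)
      abundance["DOM1", ] <- total_w / sum(per_kb)
    }

    samples <- sample_sheet(config$library_sizes)
    prob <- sweep(wt, 2, colSums(wt), "/")

    counts <- matrix(0L, nrow = nrow(tx), ncol = nrow(samples),
                     dimnames = list(tx$transcript_id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- prob[, samples$compartment[j]] * samples$library_size[j]
      counts[, j] <- switch(
        config$noise_model,
        nb = if (config$dispersion == 0) stats::rpois(length(mu), mu)
             else stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$dispersion),
        poisson = stats::rpois(length(mu), mu),
        multinomial = as.integer(stats::rmultinom(
          1, size = samples$library_size[j], prob = mu)),
        expected = as.integer(round(mu))
      )
    }

    counts_tbl <- dplyr::bind_cols(
      tx |> dplyr::select("transcript_id", "gene_id", "length"),
      tibble::as_tibble(counts)
    )

    truth <- list(
      genes = roster |> dplyr::select("gene_id", "role", "group"),
      true_abundance = tibble::as_tibble(abundance, rownames = "gene_id"),
      housekeeping_ids = roster$gene_id[roster$role == "housekeeping"],
      dominant_id = if (config$include_dominant) "DOM1" else NULL
    )

    structure(list(counts = counts_tbl, samples = samples, truth = truth,
                   config = config),
              class = "synthetic_lens_counts")
  })
}

#' @export
print.synthetic_lens_counts <- function(x, ...) {
  cat(sprintf("Synthetic lens counts: %d transcripts / %d genes x %d samples (%s noise)\n",
              nrow(x$counts), dplyr::n_distinct(x$counts$gene_id),
              nrow(x$samples), x$config$noise_model))
  invisible(x)
}
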