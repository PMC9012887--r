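#' The standard 14-gene housekeeping control panel
#'
#' Reference genes in common use as RNA-seq / qRT-PCR controls, used to
#' correct compartment-level compositional skew.
#'
#' @format Character vector of 14 gene symbols.
#' @export
housekeeping_panel <- c("GAPDH", "ACTB", "HMBS", "H6PD", "RPL4", "RPLP0",
                        "RPLP1", "TFRC", "ALB", "B2M", "SDHA", "TBP",
                        "TUBB", "YWHAZ")

#' Compute normalized expression (NE) per transcript
#'
#' NE is an RPKM-style quantity: reads in a transcript's exons divided by
#' transcript length in kilobases and sequencing depth in millions of mapped
#' reads, so NE(t, s) = count / (length_kb * depth_millions). Depth is
#' per-sample by default (`depth = "per_sample"`); `depth = "pooled"` uses the
#' mean depth of the whole dataset for every sample.
#'
#' @param counts Counts tibble (`transcript_id`, `gene_id`, `length`, sample
#'   columns), or a `synthetic_lens_counts` object.
#' @param samples Sample sheet tibble (`sample`, `compartment`, `replicate`);
#'   taken from the object when `counts` is a `synthetic_lens_counts`.
#' @param library_sizes Optional named per-sample mapped-read totals; defaults
#'   to the column sums of the count matrix.
#' @param depth `"per_sample"` (default) or `"pooled"`.
#' @return Long tibble with `transcript_id`, `gene_id`, `sample`,
#'   `compartment`, `replicate`, `count`, `ne` and a logical `corrected`
#'   column (all `FALSE`). Transcripts with missing length are excluded with a
#'   warning.
#' @export
compute_ne <- function(counts, samples = NULL, library_sizes = NULL,
                       depth = c("per_sample", "pooled")) {
  depth <- match.arg(depth)
  if (inherits(counts, "synthetic_lens_counts")) {
    samples <- counts$samples
    counts <- counts$counts
  }
  abort_if(is.null(samples), "a sample sheet is required")
  abort_if(nrow(counts) == 0, "empty count matrix")
  sample_cols <- intersect(names(counts), samples$sample)
  abort_if(length(sample_cols) == 0, "no sample columns found in counts")

  bad_len <- is.na(counts$length) | counts$length <= 0
  if (any(bad_len)) {
    rlang::warn(sprintf(
      "%d transcript(s) with missing or non-positive length excluded: %s",
      sum(bad_len),
      paste(utils::head(counts$transcript_id[bad_len], 5), collapse = ", ")))
    counts <- counts[!bad_len, , drop = FALSE]
  }

  if (is.null(library_sizes)) {
    library_sizes <- colSums(as.matrix(counts[sample_cols]))
  } else {
    library_sizes <- library_sizes[sample_cols]
  }
  abort_if(any(library_sizes <= 0) || any(is.na(library_sizes)),
           "zero or missing library size")
  if (depth == "pooled") {
    library_sizes[] <- mean(library_sizes)
  }

  counts |>
    dplyr::select("transcript_id", "gene_id", "length",
                  dplyr::all_of(sample_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "sample",
                        values_to = "count") |>
    dplyr::left_join(samples[c("sample", "compartment", "replicate")],
                     by = "sample") |>
    dplyr::mutate(
      ne = .data$count / ((.data$length / 1000) *
                            unname(library_sizes[.data$sample]) / 1e6),
      corrected = FALSE
    ) |>
    dplyr::select(-"length")
}

#' Aggregate transcript NE to gene level
#'
#' A gene's NE is the sum of its transcripts' NE values (the gene's total mRNA
#' output).
#'
#' @param ne Transcript-level NE tibble from [compute_ne()], or an
#'   already-gene-level tibble (returned unchanged).
#' @return Long tibble `gene_id`, `sample`, `compartment`, `replicate`, `ne`,
#'   `corrected`.
#' @export
gene_ne <- function(ne) {
  if (!"transcript_id" %in% names(ne)) return(ne)
  ne |>
    dplyr::group_by(.data$gene_id, .data$sample, .data$compartment,
                    .data$replicate, .data$corrected) |>
    dplyr::summarise(ne = sum(.data$ne), .groups = "drop") |>
    dplyr::relocate("ne", .after = "replicate")
}

#' Per-compartment mean NE
#'
#' Arithmetic mean of the replicate NE values per gene and compartment.
#'
#' @param ne Gene- or transcript-level NE tibble (transcripts are aggregated
#'   first).
#' @return Tibble `gene_id`, `compartment`, `ne` (compartment ordered
#'   EC, EQ, FP, FC).
#' @export
compartment_means <- function(ne) {
  gene_ne(ne) |>
    dplyr::group_by(.data$gene_id, .data$compartment) |>
    dplyr::summarise(ne = mean(.data$ne), .groups = "drop") |>
    dplyr::mutate(compartment = as_compartment(.data$compartment)) |>
    dplyr::arrange(.data$gene_id, .data$compartment)
}

#' Wide gene-by-compartment profile table
#'
#' @param ne NE tibble (any level; compartment means are computed).
#' @return Tibble `gene_id`, `EC`, `EQ`, `FP`, `FC`.
#' @export
compartment_profiles <- function(ne) {
  compartment_means(ne) |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "ne")
}

#' Housekeeping-panel correction factors
#'
#' For each compartment c the factor is the mean over panel genes g of
#' NE(g, c) / NE(g, reference): the average control-gene level relative to the
#' reference compartment. The reference compartment's factor is 1 by
#' construction. Panel genes absent from the table or with zero (or, with
#' `pseudocount = 0`, missing) reference expression are dropped with a
#' warning.
#'
#' @param ne NE tibble (gene or transcript level).
#' @param panel Character vector of housekeeping gene ids.
#' @param reference Reference compartment (default `"EC"`).
#' @param pseudocount Added to compartment-mean NE before forming ratios
#'   (default 0; genes failing the reference > 0 requirement are dropped).
#' @return Tibble `compartment`, `factor`, with attribute `panel_used`.
#' @export
correction_factors <- function(ne, panel, reference = "EC", pseudocount = 0) {
  abort_if(!reference %in% lens_compartments, "unknown reference compartment")
  means <- compartment_means(ne) |>
    dplyr::filter(.data$gene_id %in% panel) |>
    dplyr::mutate(ne = .data$ne + pseudocount)

  present <- unique(means$gene_id)
  missing <- setdiff(panel, present)
  if (length(missing) > 0) {
    rlang::warn(paste("panel gene(s) not quantified, dropped:",
                      paste(missing, collapse = ", ")))
  }
  ref_ne <- means |>
    dplyr::filter(.data$compartment == reference) |>
    dplyr::select("gene_id", ref = "ne")
  usable <- ref_ne$gene_id[ref_ne$ref > 0]
  dropped <- setdiff(present, usable)
  if (length(dropped) > 0) {
    rlang::warn(paste("panel gene(s) with zero reference expression, dropped:",
                      paste(dropped, collapse = ", ")))
  }
  abort_if(length(usable) == 0, "no usable housekeeping panel genes")

  out <- means |>
    dplyr::filter(.data$gene_id %in% usable) |>
    dplyr::left_join(ref_ne, by = "gene_id") |>
    dplyr::group_by(.data$compartment) |>
    dplyr::summarise(factor = mean(.data$ne / .data$ref), .groups = "drop")
  attr(out, "panel_used") <- usable
  attr(out, "reference") <- reference
  out
}

#' Correct NE for compositional skew against a housekeeping panel
#'
#' Divides every NE value by its compartment's correction factor (see
#' [correction_factors()]). After correction, a value of 1 equals the average
#' control-gene expression level in that compartment. Within-compartment
#' ratios of any two genes are unchanged.
#'
#' @inheritParams correction_factors
#' @return The input tibble with `ne` rescaled and `corrected = TRUE`;
#'   attribute `correction_factors` holds the factor table.
#' @export
housekeeping_correct <- function(ne, panel, reference = "EC",
                                 pseudocount = 0) {
  fac <- correction_factors(ne, panel, reference, pseudocount)
  lut <- stats::setNames(fac$factor, as.character(fac$compartment))
  out <- ne |>
    dplyr::mutate(ne = .data$ne / unname(lut[as.character(.data$compartment)]),
                  corrected = TRUE)
  attr(out, "correction_factors") <- fac
  out
}
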