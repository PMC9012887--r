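make_counts <- function(counts_list, lengths, genes = NULL) {
  n <- length(lengths)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  tibble::tibble(
    transcript_id = paste0("t", seq_len(n)),
    gene_id = genes,
    length = lengths,
    !!!counts_list
  )
}

two_sample_sheet <- function(samples) {
  sample_sheet()[sample_sheet()$sample %in% samples, ]
}

test_that("NE follows the reads-per-kilobase-per-million definition", {
  counts <- make_counts(list(EC_1 = c(10L, 999990L)), c(1000L, 2000L))
  ne <- compute_ne(counts, sample_sheet()[1, ])
  # 10 reads, 1 kb transcript, library of 1e6 reads -> NE = 10
  expect_equal(ne$ne[ne$transcript_id == "t1"], 10)
})

test_that("NE is invariant under uniform count scaling of a sample", {
  cfg <- synthetic_config(n_genes = 40, seed = 3)
  synth <- generate_counts(cfg)
  ne1 <- compute_ne(synth)
  doubled <- synth$counts
  doubled$EC_1 <- 2L * doubled$EC_1
  ne2 <- compute_ne(doubled, synth$samples)
  expect_equal(ne2$ne, ne1$ne, tolerance = 1e-12)
})

test_that("gene NE is the sum of its transcripts' NE", {
  counts <- make_counts(list(EC_1 = c(3L, 8L)), c(1000L, 2000L),
                        genes = c("gA", "gA"))
  ne <- compute_ne(counts, sample_sheet()[1, ],
                   library_sizes = c(EC_1 = 1e6))
  expect_equal(ne$ne, c(3, 4))
  expect_equal(gene_ne(ne)$ne, 7)
})

test_that("missing lengths drop the transcript with a warning, zero library errors", {
  counts <- make_counts(list(EC_1 = c(5L, 5L)), c(NA, 1000L))
  expect_warning(ne <- compute_ne(counts, sample_sheet()[1, ]),
                 "missing or non-positive length")
  expect_equal(nrow(ne), 1)
  zero <- make_counts(list(EC_1 = c(0L, 0L)), c(500L, 1000L))
  expect_error(compute_ne(zero, sample_sheet()[1, ]), "library size")
})

test_that("hand-computed correction factors: panel gene (2,4,4,4) -> (1,2,2,2)", {
  ne <- tibble::tibble(
    gene_id = "hk1",
    sample = sample_sheet()$sample,
    compartment = sample_sheet()$compartment,
    replicate = sample_sheet()$replicate,
    ne = rep(c(2, 4, 4, 4), each = 2),
    corrected = FALSE
  )
  fac <- correction_factors(ne, panel = "hk1", reference = "EC")
  expect_equal(fac$factor, c(1, 2, 2, 2))
})

test_that("a constant panel makes correction the identity", {
  # every gene constant and noise-free: composition never shifts, so panel
  # profiles are exactly flat and the correction must be the identity
  cfg <- synthetic_config(n_genes = 40, group_sizes = integer(0),
                          include_dominant = FALSE,
                          include_regulators = FALSE,
                          seed = 10, noise_model = "expected")
  synth <- generate_counts(cfg)
  gne <- gene_ne(compute_ne(synth))
  corr <- housekeeping_correct(gne, synth$truth$housekeeping_ids)
  fac <- attr(corr, "correction_factors")
  expect_equal(fac$factor, rep(1, 4), tolerance = 1e-9)
  expect_equal(corr$ne, gne$ne, tolerance = 1e-9)
})

test_that("panel genes with zero reference expression are dropped, empty panel errors", {
  ne <- tibble::tibble(
    gene_id = rep(c("hk1", "hk2"), each = 8),
    sample = rep(sample_sheet()$sample, 2),
    compartment = rep(sample_sheet()$compartment, 2),
    replicate = rep(sample_sheet()$replicate, 2),
    ne = c(rep(c(0, 1, 1, 1), each = 2), rep(c(2, 4, 4, 4), each = 2)),
    corrected = FALSE
  )
  expect_warning(fac <- correction_factors(ne, c("hk1", "hk2")),
                 "zero reference")
  expect_equal(fac$factor, c(1, 2, 2, 2))
  expect_error(
    suppressWarnings(correction_factors(ne, "hk1")),
    "no usable housekeeping")
})

test_that("correction preserves within-compartment ratios (4:1 fixture)", {
  cfg <- synthetic_config(ratio_pair = TRUE, seed = 12)
  synth <- generate_counts(cfg)
  gne <- gene_ne(compute_ne(synth))
  corr <- housekeeping_correct(gne, synth$truth$housekeeping_ids)
  raw_prof <- compartment_profiles(gne)
  cor_prof <- compartment_profiles(corr)
  ratio_raw <- as.numeric(raw_prof[raw_prof$gene_id == "RPA",
                                   lens_compartments] /
                            raw_prof[raw_prof$gene_id == "RPB",
                                     lens_compartments])
  ratio_cor <- as.numeric(cor_prof[cor_prof$gene_id == "RPA",
                                   lens_compartments] /
                            cor_prof[cor_prof$gene_id == "RPB",
                                     lens_compartments])
  expect_equal(ratio_cor, ratio_raw, tolerance = 1e-12)
  # and the pair's NE ratio is near the planted 4:1
  expect_equal(ratio_cor, rep(4, 4), tolerance = 0.3)
})

test_that("correction flattens housekeeping profiles under dominant-gene skew", {
  cfg <- synthetic_config(seed = 13)
  synth <- generate_counts(cfg)
  gne <- gene_ne(compute_ne(synth))
  corr <- housekeeping_correct(gne, synth$truth$housekeeping_ids)
  hk <- synth$truth$housekeeping_ids
  raw <- compartment_profiles(gne)
  cor_ <- compartment_profiles(corr)
  raw_ratio <- raw$FC[match(hk, raw$gene_id)] / raw$EC[match(hk, raw$gene_id)]
  cor_ratio <- cor_$FC[match(hk, cor_$gene_id)] / cor_$EC[match(hk, cor_$gene_id)]
  # raw housekeeping NE shows a spurious decline as the dominant gene rises
  # from 2.5% to 16% of the pool; corrected NE recovers a flat profile
  expect_lt(mean(raw_ratio), 0.95)
  expect_equal(mean(cor_ratio), 1, tolerance = 0.1)
})

test_that("noise-free corrected profiles are proportional to true abundance", {
  cfg <- synthetic_config(noise_model = "expected", seed = 14)
  synth <- generate_counts(cfg)
  corr <- housekeeping_correct(gene_ne(compute_ne(synth)),
                               synth$truth$housekeeping_ids)
  prof <- compartment_profiles(corr)
  ab <- synth$truth$true_abundance
  for (g in prof$gene_id) {
    ratio <- as.numeric(prof[prof$gene_id == g, lens_compartments]) /
      as.numeric(ab[ab$gene_id == g, lens_compartments])
    expect_equal(ratio / ratio[1], rep(1, 4), tolerance = 0.02)
  }
})
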