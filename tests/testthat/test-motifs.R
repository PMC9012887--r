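test_that("plus-strand promoter extraction does the window arithmetic", {
  set.seed(5)
  contig <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                  collapse = "")
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 5000,
                        strand = "+")
  prom <- extract_promoters(tss, c(chr1 = contig), window = 1000)
  # 0-based window [4000, 5000) = 1-based substring 4001..5000
  expect_equal(as.character(prom[["g"]]), substr(contig, 4001, 5000))
})

test_that("minus-strand extraction reverse-complements the downstream window", {
  set.seed(6)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 1000,
                        strand = "-")
  prom <- extract_promoters(tss, c(chr1 = contig), window = 500)
  want <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 1002, 1501))))
  expect_equal(as.character(prom[["g"]]), want)
})

test_that("synthetic promoters round-trip through a genome embedding", {
  cfg <- synthetic_config(n_genes = 40, seed = 41)
  synth <- generate_counts(cfg)
  prom <- generate_promoters(cfg, synth)
  emb <- embed_promoters_in_genome(prom$promoters, seed = 2)
  back <- extract_promoters(emb$tss, emb$genome,
                            window = cfg$promoter_length)
  expect_equal(as.character(back)[names(prom$promoters)],
               as.character(prom$promoters))
})

test_that("edge windows are truncated with a warning, off-contig TSS recorded", {
  contig <- c(chr1 = strrep("ACGT", 100))  # 400 bases
  tss <- tibble::tibble(gene_id = c("near_start", "off"),
                        chrom = "chr1", tss = c(50, 1000),
                        strand = "+")
  expect_warning(prom <- extract_promoters(tss, contig, window = 100),
                 "truncated")
  expect_equal(length(prom[["near_start"]]), 50)
  errs <- attr(prom, "errors")
  expect_equal(errs$gene_id, "off")
})

test_that("scanning recovers planted motifs with a bounded false-positive rate", {
  cfg <- synthetic_config(seed = 42, background_motif_prob = 0)
  synth <- generate_counts(cfg)
  prom <- generate_promoters(cfg, synth)
  sc <- scan_promoters(prom$promoters, prom$pwms)
  pm <- presence_matrix(sc)
  genes <- synth$truth$genes
  planted <- prom$planted_sites
  for (i in seq_len(nrow(planted))) {
    expect_true(pm[planted$gene_id[i], planted$matrix_id[i]])
  }
  # false-positive presence on unplanted (gene, matrix) pairs stays below
  # the per-window expectation 2 * L * p (with margin for discreteness)
  unplanted <- !vapply(seq_len(nrow(pm)), function(i)
    rownames(pm)[i] %in% planted$gene_id, TRUE)
  fpr <- mean(pm[unplanted, ])
  expect_lt(fpr, 2 * 2 * cfg$promoter_length * 1e-4)
})

test_that("all-N sequences produce no hits", {
  pwms <- pwm_set(list(M = pwm_from_consensus("TGACGTCA")))
  sc <- scan_promoters(c(g1 = strrep("N", 500), g2 = strrep("ACGT", 125)),
                       pwms)
  expect_false(sc$presence["g1", "M"])
})

test_that("a palindromic PWM hits both strands at the same positions", {
  pwms <- pwm_set(list(P = pwm_from_consensus("TGACGTCA")))  # self-revcomp
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  seq <- paste0(seq, "TGACGTCA", substr(seq, 1, 100))
  sc <- scan_promoters(c(g = seq), pwms)
  hits <- tidy(sc)
  fwd <- hits[hits$strand == "+", c("start", "score")]
  rev <- hits[hits$strand == "-", c("start", "score")]
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$score, rev$score, tolerance = 1e-9)
})

test_that("the p-value score threshold matches exhaustive enumeration", {
  pwm <- pwm_from_consensus("ACGTA", strength = 0.7)
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  p <- lenscoex:::pwm_normalize(pwm)
  lo <- log2(p / bg)
  # enumerate all 4^5 windows and their background probabilities
  grid <- expand.grid(rep(list(1:4), 5))
  scores <- apply(grid, 1, function(idx) sum(lo[cbind(idx, 1:5)]))
  probs <- apply(grid, 1, function(idx) prod(bg[idx]))
  # exact window scores differ from the discretized DP scores by at most
  # w * granularity / 2 = 2.5e-3; margins account for that
  # the best window of this short motif has background probability ~1.1e-3,
  # so only tail levels above that are achievable
  for (pv in c(0.05, 1e-2, 5e-3)) {
    thr <- lenscoex:::pwm_score_threshold(lo, bg, pv)
    expect_lte(sum(probs[scores >= thr + 2.6e-3]), pv + 1e-15)
    expect_gt(sum(probs[scores >= thr - 4e-3]), pv)
  }
  # an unachievable tail level means no score qualifies
  expect_identical(lenscoex:::pwm_score_threshold(lo, bg, 1e-6), Inf)
})

test_that("fraction threshold rule flags only near-maximal matches", {
  pwms <- pwm_set(list(M = pwm_from_consensus("TTTTTTTTTT")))
  seqs <- c(perfect = strrep("T", 30), junk = strrep("G", 30))
  sc <- scan_promoters(seqs, pwms, threshold = "fraction", fraction = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_true(sc$presence["perfect", "M"])
  expect_false(sc$presence["junk", "M"])
})

test_that("matrix partition matches brute-force subset enumeration", {
  set.seed(8)
  genes <- paste0("g", 1:12)
  members <- list(group1 = genes[1:4], group2 = genes[5:9],
                  group3 = genes[10:11])
  pm <- matrix(runif(12 * 40) < 0.6, nrow = 12,
               dimnames = list(genes, paste0("m", 1:40)))
  part <- partition_matrices(pm, tibble::tibble(
    group = rep(names(members), lengths(members)),
    gene_id = unlist(members)))
  want <- brute_partition_counts(pm, members)
  got <- part$cells
  expect_equal(sort(got$n), sort(as.integer(want)))
  for (cat in names(want)) {
    expect_equal(got$n[got$category == cat], as.integer(want[[cat]]))
  }
  # additive identity per group
  for (g in names(members)) {
    in_cat <- vapply(strsplit(part$membership$category, "\\+"),
                     function(s) g %in% s, TRUE)
    expect_equal(sum(in_cat), part$per_group$n_common[
      part$per_group$group == g])
  }
})

test_that("single group with fully shared matrices: unique equals common", {
  pm <- matrix(TRUE, nrow = 3, ncol = 5,
               dimnames = list(paste0("g", 1:3), paste0("m", 1:5)))
  part <- partition_matrices(pm, tibble::tibble(group = "group1",
                                                gene_id = paste0("g", 1:3)))
  expect_equal(sort(unique_matrices(part, "group1")),
               sort(common_matrices(part, "group1")))
})

test_that("a group with zero members is an error", {
  pm <- matrix(TRUE, 2, 2, dimnames = list(c("a", "b"), c("m1", "m2")))
  expect_error(
    partition_matrices(pm, tibble::tibble(group = character(),
                                          gene_id = character())),
    "group|members")
  expect_error(
    partition_matrices(pm, tibble::tibble(group = "g1", gene_id = "zz")),
    "missing from presence")
})
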