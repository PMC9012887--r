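test_that("critical R2 at n = 4 matches the closed form and quadrature", {
  # for df = 2 the null distribution of r is uniform on [-1, 1], so the
  # two-tailed critical r is 1 - alpha and the R2 bound (1 - alpha)^2
  expect_equal(critical_r2(4, 0.05), 0.95^2, tolerance = 1e-12)
  expect_equal(critical_r2(4, 0.5), 0.25, tolerance = 1e-12)
  # independent quadrature oracle: invert the t(2) tail by numerical
  # integration for a non-standard alpha
  alpha <- 0.2
  tc <- stats::uniroot(function(q)
    2 * stats::integrate(function(u) stats::dt(u, 2), q, Inf)$value - alpha,
    c(0.01, 100), tol = 1e-12)$root
  expect_equal(critical_r2(4, alpha), tc^2 / (tc^2 + 2), tolerance = 1e-9)
  # limiting behavior and errors
  expect_lt(critical_r2(4, 0.999), 1e-5)
  expect_error(critical_r2(2, 0.05), "n must be")
})

test_that("profile R2 is affine-invariant, symmetric and sign-aware", {
  a <- c(1, 5, 9, 7)
  expect_equal(profile_r2(a, 3 * a + 2)$r2, 1, tolerance = 1e-12)
  expect_true(profile_r2(a, 3 * a + 2)$significant)
  refl <- profile_r2(a, -a)
  expect_equal(refl$r2, 1, tolerance = 1e-12)
  expect_lt(refl$r, 0)
  expect_false(refl$significant)
  expect_equal(profile_r2(a, a)$r2, 1)
  b <- c(2, 1, 7, 6)
  expect_equal(profile_r2(a, b)$r, profile_r2(b, a)$r)
  expect_error(profile_r2(a, c(1, 2, 3)), "4 values")
})

test_that("profile R2 of (1,2,3,4) vs (1,2,3,5) matches the direct formula", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  n <- 4
  r_direct <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(profile_r2(x, y)$r2, r_direct^2, tolerance = 1e-12)
})

test_that("constant profiles are flagged with R2 = 0", {
  res <- profile_r2(c(2, 2, 2, 2), c(1, 5, 9, 7))
  expect_true(res$constant)
  expect_equal(res$r2, 0)
  expect_false(res$significant)
})

test_that("pairwise_r2 agrees with profile_r2 on every pair", {
  m <- rbind(a = c(1, 5, 9, 7), b = c(2, 2.5, 8, 14), c = c(3, 3, 3, 3))
  colnames(m) <- lens_compartments
  pw <- pairwise_r2(m)
  for (i in seq_len(nrow(pw))) {
    single <- profile_r2(m[pw$gene_a[i], ], m[pw$gene_b[i], ])
    expect_equal(pw$r2[i], single$r2, tolerance = 1e-12)
    expect_equal(pw$significant[i], single$significant)
  }
})

test_that("threshold 1 with no collinear profiles yields only singletons", {
  set.seed(1)
  m <- matrix(runif(20), nrow = 5,
              dimnames = list(paste0("g", 1:5), lens_compartments))
  gr <- form_groups(m, threshold = 1, require_separation = FALSE)
  expect_true(all(gr$summary$n == 1))
})

test_that("planted groups are recovered exactly at low noise", {
  skip_if_not_installed("mclust")
  cfg <- synthetic_config(seed = 31, dispersion = 0.002)
  synth <- generate_counts(cfg)
  corr <- housekeeping_correct(gene_ne(compute_ne(synth)),
                               synth$truth$housekeeping_ids)
  truth <- default_group_truth(synth)
  prof <- compartment_profiles(corr)
  gr <- form_groups(prof[prof$gene_id %in% truth$gene_id, ])
  ari <- mclust::adjustedRandIndex(group_labels(gr, truth$gene_id),
                                   truth$group)
  expect_equal(ari, 1)
  expect_true(all(gr$summary$min_within_r2 >= gr$threshold, na.rm = TRUE))
  expect_true(all(gr$summary$max_between_r2 < critical_r2(4, 0.05)))
})

test_that("a gene shared between two cliques is assigned to the larger one", {
  # g1..g3 mutually collinear; g4, g5 collinear with each other and with g3
  # only, so g3 sits in two maximal cliques {g1,g2,g3} and {g3,g4,g5};
  # profiles engineered so the cliques tie in size via distinct genes
  m <- rbind(
    g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(1, 2, 3, 4.05),
    g4 = c(1, 1.9, 3.2, 4.2), g5 = c(1, 1.92, 3.18, 4.18)
  )
  colnames(m) <- lens_compartments
  pw <- pairwise_r2(m)
  # force the second clique below threshold on the g1-g4 style pairs only
  gr <- suppressMessages(
    form_groups(pw, threshold = 0.999, require_separation = FALSE))
  memb <- tidy(gr)
  expect_true("g3" %in% memb$gene_id)
  # g3 appears exactly once
  expect_equal(sum(memb$gene_id == "g3"), 1)
  g3_group <- memb$group[memb$gene_id == "g3"]
  first_group_size <- gr$summary$n[gr$summary$group == g3_group]
  expect_true(first_group_size >= max(gr$summary$n[gr$summary$group != g3_group]))
})

test_that("separation drops cliques correlated with reported groups", {
  m <- rbind(
    g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(1.1, 2, 3, 4),
    g4 = c(1, 2.05, 3.1, 4.1)
  )
  colnames(m) <- lens_compartments
  gr <- suppressMessages(form_groups(m, threshold = 0.9999,
                                     require_separation = TRUE))
  # only one group survives: everything else correlates above the critical R2
  expect_equal(nrow(gr$summary), 1)
  expect_gt(nrow(gr$dropped), 0)
})

test_that("replicate QC flags duplicates at distance zero and degenerate input", {
  cfg <- synthetic_config(n_genes = 40, seed = 32, noise_model = "expected")
  synth <- generate_counts(cfg)
  gne <- gene_ne(compute_ne(synth))
  qc <- replicate_qc(gne)
  # noise-free replicates are identical -> replicate distance exactly 0
  expect_true(all(qc$replicate_distances$distance < 1e-10))
  expect_false(any(qc$replicate_distances$flagged))

  flat <- gne
  flat$ne <- 1
  qc2 <- replicate_qc(flat)
  expect_true(qc2$degenerate)
  expect_equal(glance(qc2)$degenerate, TRUE)
})

test_that("PC1 separates epithelial from fiber samples on default synthesis", {
  cfg <- synthetic_config(seed = 33)
  synth <- generate_counts(cfg)
  qc <- replicate_qc(gene_ne(compute_ne(synth)))
  sc <- qc$scores
  epi <- sc$PC1[sc$compartment %in% c("EC", "EQ")]
  fib <- sc$PC1[sc$compartment %in% c("FP", "FC")]
  expect_true(max(epi) < min(fib) || max(fib) < min(epi))
})
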