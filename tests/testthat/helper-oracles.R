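# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pmf via lchoose, tails via exhaustive truncated
# summation, set partitions via subset enumeration.

# Audic-Claverie conditional pmf, direct binomial-coefficient form
brute_ac_pmf <- function(y, x, r) {
  exp(y * log(r) + lchoose(x + y, y) - (x + y + 1) * log(1 + r))
}

# Min-likelihood two-sided tail by exhaustive enumeration over one
# conditioning direction
brute_ac_onedir <- function(x, y, r) {
  ymax <- ceiling(30 * (x + 5) * max(r, 1)) + 300
  pv <- brute_ac_pmf(0:ymax, x, r)
  pobs <- pv[y + 1]
  min(1, sum(pv[pv <= pobs * (1 + 1e-7)]))
}

# Symmetrized two-sided P (average of both conditioning directions)
brute_ac_p <- function(x, y, n1, n2) {
  r <- n2 / n1
  (brute_ac_onedir(x, y, r) + brute_ac_onedir(y, x, 1 / r)) / 2
}

# Matrix partition by exhaustive subset enumeration: for every matrix,
# enumerate the set of groups in which it is present in all members.
brute_partition_counts <- function(pm, members) {
  gnames <- names(members)
  cats <- vapply(colnames(pm), function(m) {
    in_g <- gnames[vapply(members, function(gs) all(pm[gs, m]), TRUE)]
    if (length(in_g) == 0) NA_character_ else paste(in_g, collapse = "+")
  }, "")
  table(cats[!is.na(cats)])
}

# Map a recovered grouping to integer labels over a fixed gene set;
# unassigned genes get their own singleton labels.
group_labels <- function(groups, genes) {
  memb <- if (inherits(groups, "coexpression_groups")) groups$membership
          else groups
  lab <- memb$group[match(genes, memb$gene_id)]
  lab[is.na(lab)] <- paste0("un_", seq_len(sum(is.na(lab))))
  lab
}

default_group_truth <- function(synth) {
  g <- synth$truth$genes
  g[g$role == "group", c("gene_id", "group")]
}
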