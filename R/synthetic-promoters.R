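#' Default PWM collection for the synthetic generator
#'
#' Three planted group motifs (M_G1, M_G2, M_G3) and three decoy motifs
#' (M_BG1..M_BG3) built from distinct width-10 consensus strings, plus a
#' factor map: each group motif is bound by that group's planted regulator
#' (REGg) and by an uncorrelated factor (TFUg); each decoy motif by a decoy
#' factor (TFDg).
#'
#' @param config A [synthetic_config()].
#' @return A [pwm_set()].
#' @export
default_pwm_set <- function(config) {
  consensi <- c(M_G1 = "TGACGTCATC", M_G2 = "CCAATGGGAT", M_G3 = "GAAGGTCACG",
                M_BG1 = "TTGCAAGTCC", M_BG2 = "ACGCGTATAA", M_BG3 = "CATGCCTAGG")
  n <- config$n_groups
  keep <- c(paste0("M_G", seq_len(min(n, 3))), paste0("M_BG", 1:3))
  mats <- lapply(consensi[keep], pwm_from_consensus)
  fm <- dplyr::bind_rows(
    tibble::tibble(factor_id = paste0("REG", seq_len(min(n, 3))),
                   matrix_id = paste0("M_G", seq_len(min(n, 3)))),
    tibble::tibble(factor_id = paste0("TFU", seq_len(min(n, 3))),
                   matrix_id = paste0("M_G", seq_len(min(n, 3)))),
    tibble::tibble(factor_id = paste0("TFD", 1:3),
                   matrix_id = paste0("M_BG", 1:3))
  )
  pwm_set(mats, fm)
}

plant_instance <- function(seq_chars, motif_chars, start0) {
  seq_chars[(start0 + 1):(start0 + length(motif_chars))] <- motif_chars
  seq_chars
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

#' Generate promoter sequences with planted group-specific motifs
#'
#' Emits one promoter of `config$promoter_length` bases per gene. Every member
#' of a planted coexpression group carries at least one instance of its
#' group's motif consensus (on a random strand at a random offset); every
#' other gene carries one instance of a randomly chosen motif with probability
#' `config$background_motif_prob`.
#'
#' @param config A [synthetic_config()].
#' @param truth The `truth` element of [generate_counts()] output (or the
#'   whole `synthetic_lens_counts` object).
#' @param pwms Optional [pwm_set()]; defaults to [default_pwm_set()].
#' @return List of class `synthetic_promoters` with `promoters`
#'   (named [Biostrings::DNAStringSet]), `pwms` ([pwm_set()]),
#'   `planted_sites` (tibble `gene_id`, `matrix_id`, `start`, `end`, `strand`;
#'   0-based half-open) and `planted_motifs` (group -> matrix id map).
#' @export
generate_promoters <- function(config, truth, pwms = default_pwm_set(config)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (inherits(truth, "synthetic_lens_counts")) truth <- truth$truth
  genes <- truth$genes
  gnames <- group_names(config)
  planted_motifs <- stats::setNames(paste0("M_G", seq_along(gnames)), gnames)
  abort_if(!all(planted_motifs %in% names(pwms$matrices)),
           "a planted motif is missing from the PWM set")

  L <- config$promoter_length
  widths <- vapply(pwms$matrices, ncol, 1L)
  abort_if(any(widths > L), "motif longer than promoter window")

  withr::with_seed(config$seed + 1L, {
    seqs <- character(nrow(genes))
    sites <- list()
    for (i in seq_len(nrow(genes))) {
      chars <- sample(DNA_BASES, L, replace = TRUE,
                      prob = config$base_composition)
      plant_id <- NA_character_
      if (genes$role[i] == "group") {
        plant_id <- planted_motifs[[genes$group[i]]]
      } else if (stats::runif(1) < config$background_motif_prob) {
        plant_id <- sample(names(pwms$matrices), 1)
      }
      if (!is.na(plant_id)) {
        motif <- strsplit(attr(pwms$matrices[[plant_id]], "consensus") %||%
                            pwm_consensus(pwms$matrices[[plant_id]]), "")[[1]]
        w <- length(motif)
        start0 <- sample(0:(L - w), 1)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") motif else revcomp_chars(motif)
        chars <- plant_instance(chars, ins, start0)
        sites[[length(sites) + 1]] <- tibble::tibble(
          gene_id = genes$gene_id[i], matrix_id = plant_id,
          start = start0, end = start0 + w, strand = strand)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    promoters <- Biostrings::DNAStringSet(stats::setNames(seqs, genes$gene_id))
    planted_sites <- if (length(sites)) dplyr::bind_rows(sites) else
      tibble::tibble(gene_id = character(), matrix_id = character(),
                     start = integer(), end = integer(), strand = character())
    structure(list(promoters = promoters, pwms = pwms,
                   planted_sites = planted_sites,
                   planted_motifs = planted_motifs),
              class = "synthetic_promoters")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Embed promoters into a synthetic genome contig
#'
#' Lays the promoters head-to-tail (separated by random spacer sequence) on a
#' single contig and returns the transcription start site table that makes
#' [extract_promoters()] recover exactly the input sequences. Genes are
#' alternately placed on the plus and minus strand to exercise strand-aware
#' extraction.
#'
#' @param promoters Named [Biostrings::DNAStringSet] (or named character).
#' @param spacer Number of spacer bases between genes.
#' @param seed Seed for the spacer sequence.
#' @return List with `genome` (a one-contig [Biostrings::DNAStringSet] named
#'   `chrS`) and `tss` (tibble `gene_id`, `chrom`, `tss`, `strand`; `tss` is
#'   the 0-based position of the transcription start base).
#' @export
embed_promoters_in_genome <- function(promoters, spacer = 200, seed = 1L) {
  if (!inherits(promoters, "DNAStringSet")) {
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  abort_if(is.null(names(promoters)), "promoters must be named by gene")
  withr::with_seed(seed, {
    pieces <- character()
    pos <- 0L  # 0-based current end of contig
    tss <- list()
    for (i in seq_along(promoters)) {
      sp <- paste(sample(DNA_BASES, spacer, replace = TRUE), collapse = "")
      pieces <- c(pieces, sp)
      pos <- pos + spacer
      p <- as.character(promoters[[i]])
      w <- nchar(p)
      strand <- if (i %% 2 == 1) "+" else "-"
      if (strand == "+") {
        # promoter occupies [pos, pos + w); TSS is the next base
        pieces <- c(pieces, p)
        tss[[i]] <- tibble::tibble(gene_id = names(promoters)[i],
                                   chrom = "chrS", tss = pos + w,
                                   strand = "+")
      } else {
        # reverse strand: reference carries the reverse complement and the
        # TSS base sits immediately 5' of it on the minus strand
        pieces <- c(pieces, paste(revcomp_chars(strsplit(p, "")[[1]]),
                                  collapse = ""))
        tss[[i]] <- tibble::tibble(gene_id = names(promoters)[i],
                                   chrom = "chrS", tss = pos - 1L,
                                   strand = "-")
      }
      pos <- pos + w
    }
    # trailing spacer so minus-strand TSS bases always exist on the contig
    pieces <- c(pieces, paste(sample(DNA_BASES, spacer, replace = TRUE),
                              collapse = ""))
    genome <- Biostrings::DNAStringSet(c(chrS = paste(pieces, collapse = "")))
    list(genome = genome, tss = dplyr::bind_rows(tss))
  })
}
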