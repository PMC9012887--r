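#' Write and read count tables as TSV
#'
#' The on-disk layout is one row per transcript: `transcript_id`, `gene_id`,
#' `length`, then one column per sample.
#'
#' @param counts Counts tibble as produced by [generate_counts()].
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly; `read_counts_tsv()`
#'   returns the counts tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Write and read the count matrix in MatrixMarket (MTX) form
#'
#' Writes `*.mtx` plus two sidecar files (`*.rows.tsv` with transcript id,
#' gene id and length; `*.cols.txt` with sample names).
#'
#' @inheritParams write_counts_tsv
#' @param prefix Path prefix (files `<prefix>.mtx`, `<prefix>.rows.tsv`,
#'   `<prefix>.cols.txt`).
#' @return `write_counts_mtx()` returns `prefix` invisibly;
#'   `read_counts_mtx()` the reassembled counts tibble.
#' @export
write_counts_mtx <- function(counts, prefix) {
  meta_cols <- c("transcript_id", "gene_id", "length")
  m <- Matrix::Matrix(as.matrix(counts[setdiff(names(counts), meta_cols)]),
                      sparse = TRUE)
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  utils::write.table(counts[meta_cols], paste0(prefix, ".rows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(setdiff(names(counts), meta_cols), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rows <- utils::read.table(paste0(prefix, ".rows.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  cols <- readLines(paste0(prefix, ".cols.txt"))
  storage.mode(m) <- "integer"
  colnames(m) <- cols
  dplyr::bind_cols(tibble::as_tibble(rows), tibble::as_tibble(m))
}

#' Write promoter (or any) sequences to FASTA
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write and read interval tables as BED
#'
#' BED is 0-based, half-open: `chrom`, `start`, `end`, `name`, `score`,
#' `strand`. Site tables keyed by `gene_id` use the gene as the chrom field
#' (intervals in promoter-local coordinates).
#'
#' @param sites Tibble with columns `gene_id` (or `chrom`), `start`, `end`,
#'   and optionally `matrix_id`/`name`, `score`, `strand`.
#' @param path File path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` a tibble with
#'   columns `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
write_bed <- function(sites, path) {
  chrom <- if ("chrom" %in% names(sites)) sites$chrom else sites$gene_id
  name <- if ("name" %in% names(sites)) sites$name
          else if ("matrix_id" %in% names(sites)) sites$matrix_id else "."
  score <- if ("score" %in% names(sites)) sites$score else 0
  strand <- if ("strand" %in% names(sites)) sites$strand else "."
  bed <- data.frame(chrom = chrom, start = sites$start, end = sites$end,
                    name = name, score = score, strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")[seq_along(bed)]
  tibble::as_tibble(bed)
}

#' Write a minimal transcript annotation as GTF
#'
#' One `transcript` feature per transcript on a synthetic layout (supplied TSS
#' table or a dummy tiling), carrying `gene_id` and `transcript_id`
#' attributes. Coordinates written 1-based closed per GTF convention.
#'
#' @param counts Counts tibble (for transcript ids, gene ids and lengths).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(counts, path) {
  start1 <- cumsum(c(1, utils::head(counts$length + 100, -1)))
  lines <- sprintf(
    'chrS\tlenscoex\ttranscript\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
    start1, start1 + counts$length - 1, counts$gene_id, counts$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write the full synthetic dataset to a directory
#'
#' Emits counts (TSV and MTX), a GTF-lite annotation, the sample sheet, truth
#' tables, promoters FASTA, PWMs in JASPAR and MEME formats, and a BED of
#' planted motif sites.
#'
#' @param synth Output of [generate_counts()].
#' @param prom Output of [generate_promoters()] (optional).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(synth, prom = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_tsv(synth$counts, file.path(dir, "counts.tsv"))
  write_counts_mtx(synth$counts, file.path(dir, "counts"))
  write_annotation_gtf(synth$counts, file.path(dir, "annotation.gtf"))
  utils::write.table(synth$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(synth$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(synth$truth$true_abundance,
                     file.path(dir, "truth_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(prom)) {
    write_fasta(prom$promoters, file.path(dir, "promoters.fasta"))
    write_jaspar(prom$pwms, file.path(dir, "pwms.jaspar"))
    write_meme(prom$pwms, file.path(dir, "pwms.meme"))
    write_bed(prom$planted_sites, file.path(dir, "planted_sites.bed"))
    utils::write.table(prom$pwms$factor_map, file.path(dir, "factor_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
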