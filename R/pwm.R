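DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from a consensus string
#'
#' Each position assigns `strength` probability to the consensus base and
#' splits the remainder evenly over the other three bases.
#'
#' @param consensus Character string over A/C/G/T.
#' @param strength Probability of the consensus base per position.
#' @return 4 x width probability matrix with rownames A, C, G, T and the
#'   consensus stored in `attr(, "consensus")`.
#' @export
pwm_from_consensus <- function(consensus, strength = 0.85) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  abort_if(!all(bases %in% DNA_BASES), "consensus must be over A/C/G/T")
  m <- matrix((1 - strength) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- strength
  attr(m, "consensus") <- paste(bases, collapse = "")
  m
}

#' Assemble a PWM collection
#'
#' @param matrices Named list of 4 x width matrices (counts or probabilities;
#'   rows A, C, G, T).
#' @param factor_map Optional tibble `factor_id`, `matrix_id` recording which
#'   transcription factors are predicted to bind each matrix (a matrix may be
#'   bound by many factors and a factor may bind many matrices).
#' @return Object of class `pwm_set`.
#' @export
pwm_set <- function(matrices, factor_map = NULL) {
  abort_if(is.null(names(matrices)) || any(names(matrices) == ""),
           "matrices must be a named list")
  matrices <- lapply(matrices, function(m) {
    abort_if(nrow(m) != 4, "PWM must have 4 rows (A, C, G, T)")
    rownames(m) <- DNA_BASES
    m
  })
  if (is.null(factor_map)) {
    factor_map <- tibble::tibble(factor_id = character(),
                                 matrix_id = character())
  }
  structure(list(matrices = matrices, factor_map = factor_map),
            class = "pwm_set")
}

#' @export
print.pwm_set <- function(x, ...) {
  cat(sprintf("PWM set: %d matrices (widths %s), %d factor annotations\n",
              length(x$matrices),
              paste(range(vapply(x$matrices, ncol, 1L)), collapse = "-"),
              nrow(x$factor_map)))
  invisible(x)
}

#' @export
length.pwm_set <- function(x) length(x$matrices)

# Normalize columns of a PWM to probabilities with a small floor so log-odds
# are finite.
pwm_normalize <- function(m, floor = 1e-4) {
  p <- sweep(m, 2, colSums(m), "/")
  p <- pmax(p, floor)
  sweep(p, 2, colSums(p), "/")
}

pwm_consensus <- function(m) {
  paste(DNA_BASES[apply(m, 2, which.max)], collapse = "")
}

pwm_revcomp <- function(m) {
  m2 <- m[4:1, ncol(m):1, drop = FALSE]
  rownames(m2) <- DNA_BASES
  m2
}

#' Write / read PWMs in JASPAR text format
#'
#' The JASPAR format stores one matrix per record: a `>ID name` header line
#' followed by four rows `A [ n n ... ]` through `T [ ... ]`.
#'
#' @param pwms A [pwm_set()] or named list of matrices.
#' @param path Output / input file path.
#' @return `write_jaspar()` returns `path` invisibly; `read_jaspar()` returns a
#'   [pwm_set()].
#' @export
write_jaspar <- function(pwms, path) {
  mats <- if (inherits(pwms, "pwm_set")) pwms$matrices else pwms
  lines <- unlist(lapply(names(mats), function(id) {
    m <- mats[[id]]
    c(paste0(">", id, " ", id),
      vapply(DNA_BASES, function(b) {
        paste0(b, " [ ", paste(format(m[b, ], trim = TRUE), collapse = " "), " ]")
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_jaspar
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  abort_if(length(starts) == 0, "no JASPAR records found")
  mats <- list()
  for (s in starts) {
    id <- strsplit(sub("^>", "", lines[s]), "\\s+")[[1]][1]
    rows <- lines[s + 1:4]
    m <- t(vapply(rows, function(r) {
      nums <- sub("^[ACGT]\\s*\\[?\\s*", "", r)
      nums <- sub("\\]\\s*$", "", nums)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(sub("\\]\\s*$", "",
      sub("^[ACGT]\\s*\\[?\\s*", "", rows[1]))), "\\s+")[[1]]))))
    rownames(m) <- DNA_BASES
    mats[[id]] <- m
  }
  pwm_set(mats)
}

#' Write / read PWMs in MEME minimal motif format
#'
#' @inheritParams write_jaspar
#' @param background Named A/C/G/T background frequencies written to the
#'   header.
#' @return `write_meme()` returns `path` invisibly; `read_meme()` a
#'   [pwm_set()].
#' @export
write_meme <- function(pwms, path, background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25)) {
  mats <- if (inherits(pwms, "pwm_set")) pwms$matrices else pwms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
               ""), con)
  for (id in names(mats)) {
    p <- pwm_normalize(mats[[id]])
    writeLines(c(paste("MOTIF", id),
                 sprintf("letter-probability matrix: alength= 4 w= %d", ncol(p)),
                 apply(p, 2, function(col) paste(sprintf("%.6f", col),
                                                 collapse = " ")),
                 ""), con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  abort_if(length(starts) == 0, "no MEME motifs found")
  mats <- list()
  for (s in starts) {
    id <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- s + grep("letter-probability matrix", lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    block <- lines[(h + 1):(h + w)]
    m <- t(vapply(block, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    mats[[id]] <- t(m)
    rownames(mats[[id]]) <- DNA_BASES
  }
  pwm_set(mats)
}
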