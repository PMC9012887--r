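#' Ordered lens compartments
#'
#' The four microdissected lens zones in differentiation order: central
#' epithelium (EC), equatorial epithelium (EQ), cortical fibers (FP), central
#' fibers (FC).
#'
#' @format Character vector of length 4.
#' @export
lens_compartments <- c("EC", "EQ", "FP", "FC")

#' Adjacent compartment pairs
#'
#' The three developmentally sequential comparisons EC-EQ, EQ-FP, FP-FC.
#'
#' @return List of length-2 character vectors.
#' @export
adjacent_pairs <- function() {
  list(c("EC", "EQ"), c("EQ", "FP"), c("FP", "FC"))
}

#' All pairwise compartment comparisons
#'
#' @return List of the 6 unordered compartment pairs.
#' @export
all_pairs <- function() {
  utils::combn(lens_compartments, 2, simplify = FALSE)
}

pair_label <- function(pair) paste(pair, collapse = "-")

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible(TRUE)
}

# ordered compartment factor, errors on unknown levels
as_compartment <- function(x) {
  bad <- setdiff(unique(x), lens_compartments)
  abort_if(length(bad) > 0,
           paste0("unknown compartment(s): ", paste(bad, collapse = ", ")))
  factor(x, levels = lens_compartments)
}

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
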