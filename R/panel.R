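#' Population panel
#'
#' A population panel fixes the set of populations, their order, their
#' sample sizes and their analysis weights. Every matrix produced by the
#' package carries a panel and is emitted with rows and columns in panel
#' order, which prevents silent misalignment between data types.
#'
#' Weights default to uniform. When per-population effective sizes are
#' supplied the weights are `w_i = ne_i / sum(ne)`, which down-weights
#' populations whose small long-term size makes drift a stronger confounder.
#'
#' @param labels character vector of unique population identifiers
#' @param n per-population individual sample sizes (counts, >= 1);
#'   recycled if scalar
#' @param ne optional per-population effective population sizes; when given,
#'   weights are proportional to `ne`
#' @param w optional explicit weights; normalized to sum to 1. At most one
#'   of `ne` and `w` may be given.
#' @return an object of class `population_panel` with fields `labels`, `n`,
#'   `ne` and `w` (weights summing to 1)
#' @examples
#' population_panel(c("A", "B", "C"), n = 50)
#' population_panel(c("A", "B"), n = c(30, 40), ne = c(1200, 800))
#' @export
population_panel <- function(labels, n, ne = NULL, w = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stopf("population labels must be unique")
  G <- length(labels)
  if (G < 1L) stopf("panel needs at least one population")
  n <- rep_len(as.numeric(n), G)
  if (any(!is.finite(n)) || any(n < 1)) stopf("all sample sizes n must be >= 1")
  if (!is.null(ne) && !is.null(w))
    stopf("supply at most one of 'ne' and 'w'")
  if (!is.null(ne)) {
    ne <- rep_len(as.numeric(ne), G)
    if (any(!is.finite(ne)) || any(ne <= 0)) stopf("effective sizes must be positive")
    w <- ne / sum(ne)
  } else if (!is.null(w)) {
    w <- as.numeric(w)
    if (length(w) != G) stopf("weights must have one entry per population")
    if (any(!is.finite(w)) || any(w <= 0)) stopf("weights must be positive")
    w <- w / sum(w)
  } else {
    w <- rep(1 / G, G)
  }
  structure(
    list(labels = labels, n = n, ne = ne, w = w),
    class = "population_panel"
  )
}

#' @export
print.population_panel <- function(x, ...) {
  cat("Population panel:", length(x$labels), "populations\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.population_panel <- function(x, ...) {
  data.frame(
    population = x$labels,
    n = x$n,
    ne = if (is.null(x$ne)) NA_real_ else x$ne,
    w = x$w,
    stringsAsFactors = FALSE
  )
}

#' @export
length.population_panel <- function(x) length(x$labels)

#' Restrict a panel to a subset of its populations
#'
#' Retains panel order and renormalizes weights over the subset.
#'
#' @param panel a [population_panel()]
#' @param labels populations to keep (any order; panel order is preserved)
#' @return a `population_panel` over the subset
#' @export
subset_panel <- function(panel, labels) {
  keep <- panel$labels %in% labels
  if (!all(labels %in% panel$labels))
    stopf("unknown population(s): %s",
          paste(setdiff(labels, panel$labels), collapse = ", "))
  if (is.null(panel$ne)) {
    population_panel(panel$labels[keep], panel$n[keep], w = panel$w[keep])
  } else {
    population_panel(panel$labels[keep], panel$n[keep], ne = panel$ne[keep])
  }
}

same_panel <- function(a, b) {
  identical(a$labels, b$labels)
}

assert_panel <- function(panel) {
  if (!inherits(panel, "population_panel"))
    stopf("expected a population_panel object")
  invisible(panel)
}
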