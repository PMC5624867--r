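#' Kinship (R) matrix
#'
#' An R-matrix is the standardized variance-covariance matrix of population
#' deviations from the weighted regional centroid. Off-diagonal entries are
#' average kinship coefficients r_ij: positive values mean two populations
#' are more similar than the regional average, negative values more
#' distinct. Diagonal entries r_ii measure each population's divergence
#' from the centroid, and their weighted sum is the minimum Fst of the
#' region:
#'
#'   Fst = sum_i w_i r_ii
#'
#' By construction the weighted row sums vanish (`sum_j w_j r_ij = 0` for
#' every i): the centroid is the origin of the space the matrix describes.
#' Sampling-bias correction can push diagonal entries slightly below zero;
#' such values are retained here and only clamped when converting to
#' distances.
#'
#' @param r G x G symmetric numeric matrix of kinship coefficients, with
#'   dimnames matching the panel labels (set from the panel if absent)
#' @param panel a [population_panel()]
#' @param h2 heritability used (phenotypic sources) or `NA` (allele
#'   frequencies)
#' @param bias_corrected logical flag: was a small-sample diagonal
#'   correction applied?
#' @param source one of `"allele"`, `"metric"`, `"threshold"`, `"target"`
#' @return an object of class `kinship_matrix` with fields `r`, `panel`,
#'   `fst`, `h2`, `bias_corrected`, `source`
#' @export
kinship_matrix <- function(r, panel, h2 = NA_real_, bias_corrected = FALSE,
                           source = c("allele", "metric", "threshold", "target")) {
  assert_panel(panel)
  source <- match.arg(source)
  r <- as.matrix(r)
  G <- length(panel$labels)
  if (!all(dim(r) == G)) stopf("r must be %d x %d to match the panel", G, G)
  if (max(abs(r - t(r))) > 1e-10) stopf("kinship matrix must be symmetric")
  r <- (r + t(r)) / 2
  dimnames(r) <- list(panel$labels, panel$labels)
  rs <- as.numeric(r %*% panel$w)
  if (max(abs(rs)) > 1e-8)
    stopf("weighted row sums must vanish (centroid property); max |sum| = %.3g",
          max(abs(rs)))
  structure(
    list(
      r = r,
      panel = panel,
      fst = sum(panel$w * diag(r)),
      h2 = h2,
      bias_corrected = isTRUE(bias_corrected),
      source = source
    ),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("R-matrix (%s), %d populations, Fst = %.5f%s\n",
              x$source, length(x$panel$labels), x$fst,
              if (x$bias_corrected) ", bias-corrected" else ""))
  if (!is.na(x$h2)) cat(sprintf("heritability h2 = %g\n", x$h2))
  print(round(x$r, digits))
  invisible(x)
}

# Project a symmetric matrix onto the centroid constraint of the panel:
# R = P M P' with P = I - 1 w'. Weighted row sums of the result are zero
# to machine precision, and PSD inputs stay PSD.
centroid_project <- function(m, w) {
  G <- nrow(m)
  P <- diag(G) - matrix(1, G, 1) %*% matrix(w, 1, G)
  out <- P %*% m %*% t(P)
  (out + t(out)) / 2
}

#' Convert an R-matrix to pairwise squared distances
#'
#' Squared biological distances between populations follow directly from
#' kinship coefficients:
#'
#'   d2_ij = r_ii + r_jj - 2 r_ij
#'
#' When a bias-corrected diagonal dips below zero this expression can go
#' (slightly) negative for very close pairs; such entries are clamped to
#' zero and the count is reported via a message.
#'
#' @param k a [kinship_matrix()]
#' @return an object of class `distance_matrix` with fields `d2` (squared
#'   distances, zero diagonal) and `panel`
#' @examples
#' pan <- population_panel(c("A", "B"), n = 50)
#' f <- data.frame(population = rep(c("A", "B"), each = 2),
#'                 locus = "L1", allele = c("a1", "a2", "a1", "a2"),
#'                 frequency = c(0.6, 0.4, 0.4, 0.6), n_obs = 50)
#' k <- allele_rmatrix(frequency_table(f, pan), pan)
#' rmatrix_to_distance(k)$d2["A", "B"]  # 0.16
#' @export
rmatrix_to_distance <- function(k) {
  stopifnot(inherits(k, "kinship_matrix"))
  r <- k$r
  d2 <- outer(diag(r), diag(r), `+`) - 2 * r
  neg <- sum(d2 < 0)
  if (neg > 0) {
    message(sprintf("rmatrix_to_distance: clamped %d negative squared distance(s) to 0", neg))
    d2[d2 < 0] <- 0
  }
  diag(d2) <- 0
  d2 <- (d2 + t(d2)) / 2
  structure(list(d2 = d2, panel = k$panel), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, digits = 4, ...) {
  cat("Squared-distance matrix,", length(x$panel$labels), "populations\n")
  print(round(x$d2, digits))
  invisible(x)
}

#' Restrict a kinship matrix to a subset of populations
#'
#' Subsetting changes the regional centroid, so the submatrix is
#' re-projected onto the centroid constraint of the reduced panel (with
#' renormalized weights) and Fst is recomputed. This mirrors re-running the
#' estimator on the subset under the same deviations.
#'
#' @param k a [kinship_matrix()]
#' @param labels populations to keep
#' @return a `kinship_matrix` over the subset
#' @export
subset_kinship <- function(k, labels) {
  stopifnot(inherits(k, "kinship_matrix"))
  pan <- subset_panel(k$panel, labels)
  idx <- match(pan$labels, k$panel$labels)
  r <- centroid_project(k$r[idx, idx, drop = FALSE], pan$w)
  kinship_matrix(r, pan, h2 = k$h2, bias_corrected = k$bias_corrected,
                 source = k$source)
}
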