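# Permutation-based comparison of kinship structures. The tests operate
# on the G(G-1)/2 upper off-diagonal elements and build their null
# distributions by jointly permuting rows and columns of one matrix,
# which preserves its internal structure while breaking the pairing of
# populations.

as_square <- function(x, what = "matrix") {
  if (inherits(x, "kinship_matrix")) return(x$r)
  if (inherits(x, "distance_matrix")) return(x$d2)
  m <- as.matrix(x)
  if (nrow(m) != ncol(m)) stopf("%s must be square", what)
  m
}

check_alignment <- function(...) {
  ms <- list(...)
  labs <- lapply(ms, function(x) {
    if (inherits(x, c("kinship_matrix", "distance_matrix"))) x$panel$labels
    else rownames(as_square(x))
  })
  labs <- Filter(Negate(is.null), labs)
  if (length(labs) > 1 && !all(vapply(labs[-1], identical, logical(1), labs[[1]])))
    stopf("matrices are not on the same populations in the same order")
}

#' Mantel test between two kinship (or distance) matrices
#'
#' Pearson correlation of the upper off-diagonal elements, with a
#' two-tailed permutation p-value: rows and columns of the second matrix
#' are permuted simultaneously and the add-one estimator
#' `p = (#{|r_perm| >= |r_obs|} + 1) / (permutations + 1)` is used so p
#' never reaches 0. The statistic is invariant to affine transforms of
#' either matrix's off-diagonals.
#'
#' @param a,b [kinship_matrix()], `distance_matrix` or plain labeled
#'   square matrices on the same populations in the same order; at least 4
#'   populations (below that the permutation null is degenerate)
#' @param permutations number of random permutations (default 10000)
#' @param seed optional integer seed for the permutation stream
#' @return list of class `mantel_result`: `r`, `p`, `permutations`
#' @export
mantel <- function(a, b, permutations = 10000, seed = NULL) {
  check_alignment(a, b)
  ma <- as_square(a); mb <- as_square(b)
  G <- nrow(ma)
  if (G < 4) stopf("Mantel test needs at least 4 populations")
  if (nrow(mb) != G) stopf("matrices differ in size")
  av <- off_diagonal(ma)
  if (sd(av) == 0 || sd(off_diagonal(mb)) == 0)
    stopf("constant off-diagonals; correlation undefined")
  r_obs <- cor(av, off_diagonal(mb))
  if (!is.null(seed)) withr::local_seed(seed)
  hits <- 0L
  for (i in seq_len(permutations)) {
    pm <- sample.int(G)
    r_perm <- cor(av, off_diagonal(mb[pm, pm]))
    if (abs(r_perm) >= abs(r_obs)) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (hits + 1) / (permutations + 1),
                 permutations = permutations),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, two-tailed p = %.4g (%d permutations)\n",
              x$r, x$p, x$permutations))
  invisible(x)
}

#' Dow-Cheverud test: which of two predictor matrices tracks an outcome?
#'
#' Standardizes the off-diagonals of predictors `a` and `b` to mean 0 and
#' SD 1, forms their difference `D = a_std - b_std`, and correlates D with
#' the outcome's off-diagonals. A positive statistic means `a` is more
#' strongly correlated with the outcome; swapping `a` and `b` flips the
#' sign exactly. Significance comes from jointly permuting rows and
#' columns of the outcome matrix, two-tailed with the add-one correction.
#'
#' @param a,b predictor matrices (e.g. two phenotypic R-matrices)
#' @param outcome outcome matrix (e.g. a neutral genetic R-matrix)
#' @param permutations number of permutations (default 10000)
#' @param seed optional integer seed
#' @return list of class `dow_cheverud_result`: `statistic`, `p`,
#'   `permutations`
#' @export
dow_cheverud <- function(a, b, outcome, permutations = 10000, seed = NULL) {
  check_alignment(a, b, outcome)
  ma <- as_square(a); mb <- as_square(b); mo <- as_square(outcome)
  G <- nrow(ma)
  av <- off_diagonal(ma); bv <- off_diagonal(mb)
  if (sd(av) == 0 || sd(bv) == 0)
    stopf("constant off-diagonals in a predictor; standardization undefined")
  D <- as.numeric(scale(av)) - as.numeric(scale(bv))
  stat <- if (sd(D) == 0) 0 else cor(D, off_diagonal(mo))
  if (!is.null(seed)) withr::local_seed(seed)
  hits <- 0L
  if (sd(D) > 0) {
    for (i in seq_len(permutations)) {
      pm <- sample.int(G)
      s <- cor(D, off_diagonal(mo[pm, pm]))
      if (abs(s) >= abs(stat)) hits <- hits + 1L
    }
  } else {
    hits <- permutations
  }
  structure(list(statistic = stat, p = (hits + 1) / (permutations + 1),
                 permutations = permutations),
            class = "dow_cheverud_result")
}

#' @export
print.dow_cheverud_result <- function(x, ...) {
  cat(sprintf("Dow-Cheverud: statistic = %.4f, two-tailed p = %.4g (%d permutations)\n",
              x$statistic, x$p, x$permutations))
  invisible(x)
}

#' Principal coordinates analysis of a squared-distance matrix
#'
#' Classical metric scaling: the squared-distance matrix is
#' double-centered (B = -1/2 J D2 J, J = I - 11'/G) and
#' eigendecomposed; coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues. Negative eigenvalues (non-Euclidean
#' residue) are dropped and their absolute mass reported via a message.
#' Computation is delegated to [stats::cmdscale()].
#'
#' @param d a `distance_matrix` from [rmatrix_to_distance()] or a plain
#'   square matrix of squared distances; at least 3 populations
#' @return list of class `pcoa_result`: `coordinates` (G x m),
#'   `eigenvalues` (descending), `proportion` (share of the positive
#'   eigenvalue sum per retained axis)
#' @export
pcoa <- function(d) {
  d2 <- if (inherits(d, "distance_matrix")) d$d2 else as_square(d)
  G <- nrow(d2)
  if (G < 3) stopf("PCoA needs at least 3 populations")
  labels <- rownames(d2) %||% as.character(seq_len(G))
  # cmdscale warns when fewer than k axes have positive eigenvalues; the
  # eigenvalue screen below handles that case explicitly
  fit <- suppressWarnings(cmdscale(as.dist(sqrt(pmax(d2, 0))), k = G - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-12 * max(abs(eig), 1e-300)
  neg_mass <- sum(abs(eig[eig < 0]))
  if (neg_mass > 0)
    message(sprintf("pcoa: dropped negative eigenvalue mass %.3g (non-Euclidean residue)", neg_mass))
  m <- sum(pos)
  coords <- fit$points[, seq_len(min(m, ncol(fit$points))), drop = FALSE]
  rownames(coords) <- labels
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion = eig[pos][seq_len(ncol(coords))] / sum(eig[pos])
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d axes; first axes explain %s of positive eigenvalue mass\n",
              ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion, 3)), collapse = ", ")))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level (default 0.05)
#' @param m number of comparisons (>= 1)
#' @return adjusted per-test level `alpha / m`
#' @examples
#' bonferroni(0.05, 2)  # 0.025
#' @export
bonferroni <- function(alpha = 0.05, m) {
  if (!is_count(m) || m < 1) stopf("m must be a positive integer")
  alpha / m
}

#' Paired off-diagonal table with OLS fit
#'
#' Emits the paired off-diagonal kinship coefficients of two matrices
#' together with the ordinary least-squares slope, intercept and 95%
#' confidence limits — the numbers behind a kinship-kinship regression
#' plot. Rendering is left to the caller.
#'
#' @param a,b matrices on one panel
#' @return list: `pairs` (data frame pop_i, pop_j, a, b), `slope`,
#'   `intercept`, `conf_int` (2 x 2 matrix)
#' @export
offdiag_regression <- function(a, b) {
  check_alignment(a, b)
  ma <- as_square(a); mb <- as_square(b)
  G <- nrow(ma)
  labels <- rownames(ma) %||% as.character(seq_len(G))
  ut <- which(upper.tri(ma), arr.ind = TRUE)
  df <- data.frame(pop_i = labels[ut[, 1]], pop_j = labels[ut[, 2]],
                   a = ma[ut], b = mb[ut], stringsAsFactors = FALSE)
  fit <- stats::lm(b ~ a, data = df)
  ci <- stats::confint(fit, level = 0.95)
  list(pairs = df, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), conf_int = ci)
}
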