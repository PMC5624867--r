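# Relethford-Blangero R-matrix from individual-level metric traits. The
# model scales the pooled within-group phenotypic covariance by a scalar
# heritability to approximate the additive genetic covariance, forms
# codivergence values from population means in that metric, and converts
# them to kinship coefficients about the weighted centroid.

#' Pooled within-group covariance and population means
#'
#' @param t complete metric trait data frame (`id`, `population`, trait
#'   columns); every population needs at least 2 individuals
#' @return list with `means` (G x t matrix of population means, rows in
#'   order of first appearance unless reordered downstream), `W` (t x t
#'   pooled within-group covariance, divisor N - G), `n` (per-population
#'   counts, named)
#' @export
pooled_within_cov <- function(t) {
  vals <- trait_values(t)
  if (anyNA(vals)) stopf("trait table must be complete (impute first)")
  pops <- unique(t$population)
  G <- length(pops)
  N <- nrow(vals)
  p <- ncol(vals)
  n <- table(factor(t$population, levels = pops))
  if (any(n < 2))
    stopf("population(s) with a single individual: %s",
          paste(names(n)[n < 2], collapse = ", "))
  if (N - G < p)
    warnf("only %d within-group degrees of freedom for %d traits; W may be poorly estimated", N - G, p)
  means <- matrix(NA_real_, G, p, dimnames = list(pops, colnames(vals)))
  SS <- matrix(0, p, p)
  for (g in pops) {
    x <- vals[t$population == g, , drop = FALSE]
    means[g, ] <- colMeans(x)
    SS <- SS + crossprod(sweep(x, 2, means[g, ]))
  }
  W <- SS / (N - G)
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stopf("pooled within-group covariance is singular; reduce the variable set")
  list(means = means, W = W, n = as.numeric(n), pops = pops)
}

#' Codivergence matrix from population means
#'
#' With additive genetic covariance approximated as `G_W = h2 * W`, the
#' codivergence between populations i and j is the mean Mahalanobis-type
#' cross-product of their mean deviations from the weighted grand mean:
#'
#'   c_ij = (xbar_i - xbar)' (h2 W)^{-1} (xbar_j - xbar) / t
#'
#' Halving h2 doubles every entry (c is inversely proportional to h2), and
#' c is invariant to any affine transform applied consistently to all
#' individuals because of the quadratic form in W^{-1}.
#'
#' @param means G x t matrix of population trait means (rows in panel
#'   order)
#' @param W t x t pooled within-group phenotypic covariance (positive
#'   definite)
#' @param h2 heritability in (0, 1]
#' @param panel a [population_panel()]
#' @return list of class `codivergence_matrix`: `c` (G x G), `t`, `W`,
#'   `h2`, `n`
#' @export
codivergence <- function(means, W, h2, panel) {
  assert_panel(panel)
  if (!(h2 > 0 && h2 <= 1)) stopf("h2 must lie in (0, 1]")
  means <- as.matrix(means)
  if (!is.null(rownames(means))) {
    if (!setequal(rownames(means), panel$labels))
      stopf("means rows do not match panel populations")
    means <- means[panel$labels, , drop = FALSE]
  }
  G <- length(panel$labels)
  t_traits <- ncol(means)
  GW <- h2 * W
  ch <- tryCatch(chol(GW), error = function(e) NULL)
  if (is.null(ch)) stopf("h2 * W is not positive definite")
  grand <- as.numeric(panel$w %*% means)
  M <- sweep(means, 2, grand)
  # c = M (GW)^-1 M' / t via the Cholesky factor
  Y <- t(backsolve(ch, t(M), transpose = TRUE))
  cm <- tcrossprod(Y) / t_traits
  dimnames(cm) <- list(panel$labels, panel$labels)
  structure(list(c = cm, t = t_traits, W = W, h2 = h2, n = panel$n),
            class = "codivergence_matrix")
}

# Iterative verification path for the Fst fixed point
#   Fst = (1 - Fst) * S / 2,
# whose closed form is S / (2 + S). Damped (factor 1/2) so the affine map
# contracts for any S in (-2, 6); kept as an independent cross-check of
# the closed form.
fst_fixed_point <- function(S, tol = 1e-12, max_iter = 10000L) {
  fst <- 0
  for (i in seq_len(max_iter)) {
    new <- fst + 0.5 * ((1 - fst) * S / 2 - fst)
    if (abs(new - fst) < tol) return(new)
    fst <- new
  }
  stopf("Fst fixed-point iteration did not converge for S = %g", S)
}

#' Convert a codivergence matrix to an R-matrix
#'
#' Codivergence values are related to kinship coefficients by
#' `r_ij = c_ij (1 - Fst) / 2`, with `Fst = S / (2 + S)` where
#' `S = sum_i w_i c_ii` (the closed form of the fixed point
#' `Fst = (1 - Fst) S / 2`). When `bias_correct` is set the diagonal is
#' first reduced by the expected sampling inflation of the population
#' means, `1/(h2 n_i)` per population (approximate; its efficacy is
#' checked by simulation). A custom `diag_correction` vector can replace
#' that default, which is how the threshold-trait path supplies its
#' delta-method variances. The result is re-projected onto the centroid
#' constraint so weighted row sums vanish to machine precision; negative
#' diagonal entries arising from the correction are retained.
#'
#' @param cm a `codivergence_matrix` from [codivergence()] (or a plain
#'   G x G matrix, in which case `h2` and `n` are taken from the panel and
#'   arguments)
#' @param panel a [population_panel()]
#' @param bias_correct apply the small-sample diagonal correction
#'   (default TRUE)
#' @param diag_correction optional per-population vector subtracted from
#'   the diagonal instead of the default `1/(h2 n_i)`
#' @param source source tag for the resulting [kinship_matrix()]
#' @return a [kinship_matrix()]
#' @examples
#' pan <- population_panel(c("A", "B"), n = 100)
#' cm <- matrix(c(2, -2, -2, 2), 2, 2, dimnames = list(pan$labels, pan$labels))
#' k <- c_to_r(cm, pan, h2 = 1, bias_correct = FALSE)
#' k$fst  # 0.5; r = c / 4
#' @export
c_to_r <- function(cm, panel, h2 = NULL, bias_correct = TRUE,
                   diag_correction = NULL,
                   source = c("metric", "threshold")) {
  assert_panel(panel)
  source <- match.arg(source)
  if (inherits(cm, "codivergence_matrix")) {
    h2 <- cm$h2
    n <- cm$n
    cmat <- cm$c
  } else {
    cmat <- as.matrix(cm)
    n <- panel$n
    if (is.null(h2)) stopf("h2 must be supplied with a plain matrix")
  }
  G <- length(panel$labels)
  stopifnot(all(dim(cmat) == G))
  if (bias_correct) {
    corr <- diag_correction %||% (1 / (h2 * n))
    diag(cmat) <- diag(cmat) - corr
  }
  S <- sum(panel$w * diag(cmat))
  if (S <= -2) stopf("weighted codivergence sum S = %g <= -2; data pathological", S)
  fst <- S / (2 + S)
  r <- cmat * (1 - fst) / 2
  r <- centroid_project(r, panel$w)
  kinship_matrix(r, panel, h2 = h2, bias_corrected = bias_correct,
                 source = source)
}

#' R-matrix from individual-level metric traits
#'
#' Convenience wrapper chaining [pooled_within_cov()], [codivergence()]
#' and [c_to_r()]. Accepts either an individual-level table or
#' precomputed summary statistics (means, W, n), the latter supporting
#' published summaries.
#'
#' @param t complete metric trait data frame (ignored when `means` is
#'   given)
#' @param panel a [population_panel()]
#' @param h2 heritability (default 0.5, the approximate average of twin
#'   and family estimates for dental metrics)
#' @param bias_correct apply the small-sample diagonal correction
#' @param means,W optional precomputed population means and pooled
#'   within-group covariance
#' @return a [kinship_matrix()] with `source = "metric"`
#' @export
metric_rmatrix <- function(t = NULL, panel, h2 = 0.5, bias_correct = TRUE,
                           means = NULL, W = NULL) {
  assert_panel(panel)
  if (is.null(means)) {
    if (is.null(t)) stopf("supply either a trait table or (means, W)")
    pw <- pooled_within_cov(t)
    if (!setequal(pw$pops, panel$labels))
      stopf("trait table populations do not match panel")
    means <- pw$means
    W <- pw$W
  }
  cm <- codivergence(means, W, h2, panel)
  c_to_r(cm, panel, bias_correct = bias_correct, source = "metric")
}
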