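# R-matrix from binary (non-metric) trait frequencies under the liability
# threshold model: each trait reflects an unobserved, normally distributed
# liability with unit within-population SD; the trait is present when the
# liability exceeds a fixed threshold, so observed frequencies map to mean
# liabilities by the probit transform.

liability_from_counts <- function(x, n) {
  f <- x / n
  boundary <- x == 0 | x == n
  f[boundary] <- (x[boundary] + 0.5) / (n[boundary] + 1)
  z <- qnorm(f)
  v <- f * (1 - f) / (n * dnorm(z)^2)
  list(f = f, z = z, v = v)
}

#' Probit liability transform of binary trait data
#'
#' For every (population, trait) cell with `x` of `n` scoreable
#' individuals expressing the trait, the frequency is `f = x/n` (with the
#' continuity correction `f = (x + 0.5)/(n + 1)` applied only at the
#' boundaries `x = 0` and `x = n`, keeping the transform finite), the mean
#' liability is `z = qnorm(f)` and its delta-method sampling variance is
#' `v = f(1 - f) / (n dnorm(z)^2)`. Because scoreability varies by cell,
#' missing individual scores simply reduce that cell's `n` — the method
#' tolerates incomplete tables.
#'
#' @param b binary trait data frame (`id`, `population`, 0/1/NA trait
#'   columns), or a pre-aggregated data frame with columns `population`,
#'   `trait`, `f`, `n` (published frequency tables)
#' @param panel a [population_panel()]
#' @return a `liability_table`: list of G x t matrices `z`, `v`, `f`, `n`
#' @export
liability_transform <- function(b, panel) {
  assert_panel(panel)
  G <- length(panel$labels)
  if (all(c("trait", "f", "n") %in% names(b))) {
    traits <- unique(b$trait)
    shape <- function(col) {
      m <- matrix(NA_real_, G, length(traits),
                  dimnames = list(panel$labels, traits))
      m[cbind(match(b$population, panel$labels), match(b$trait, traits))] <- b[[col]]
      m
    }
    nmat <- shape("n")
    xmat <- round(shape("f") * nmat)
  } else {
    vals <- trait_values(b)
    bad <- !(vals %in% c(0, 1) | is.na(vals))
    if (any(bad)) stopf("binary trait values must be 0, 1 or NA")
    traits <- colnames(vals)
    pop <- factor(b$population, levels = panel$labels)
    nmat <- apply(vals, 2, function(col) tapply(!is.na(col), pop, sum))
    xmat <- apply(vals, 2, function(col) tapply(col, pop, sum, na.rm = TRUE))
    nmat[is.na(nmat)] <- 0
  }
  if (any(nmat < 1)) {
    bad <- which(nmat < 1, arr.ind = TRUE)
    stopf("no scoreable individuals for population %s, trait %s (reduce missingness upstream)",
          rownames(nmat)[bad[1, 1]] %||% bad[1, 1], colnames(nmat)[bad[1, 2]] %||% bad[1, 2])
  }
  lt <- liability_from_counts(xmat, nmat)
  structure(list(z = lt$z, v = lt$v, f = lt$f, n = nmat, panel = panel),
            class = "liability_table")
}

#' R-matrix from liability-transformed binary traits
#'
#' Treating traits as independent liabilities with unit within-population
#' variance, the codivergence between populations is
#'
#'   c_ij = (1/t) sum_k (z_ik - zbar_k)(z_jk - zbar_k) / h2,
#'
#' with `zbar_k` the weighted centroid liability of trait k. The
#' bias correction subtracts the mean delta-method sampling variance
#' `(1/t) sum_k v_ik / h2` from each diagonal entry. Conversion to
#' kinship coefficients then follows the same `Fst = S/(2+S)`,
#' `r = c (1 - Fst)/2` path as the metric estimator ([c_to_r()]). A
#' global sign flip of the liabilities leaves the result unchanged
#' (quadratic form).
#'
#' @param l a `liability_table` from [liability_transform()], or a binary
#'   trait data frame (transformed internally)
#' @param panel a [population_panel()]
#' @param h2 heritability of the liabilities (default 0.5)
#' @param bias_correct subtract the sampling-variance diagonal term
#'   (default TRUE)
#' @return a [kinship_matrix()] with `source = "threshold"`
#' @export
threshold_rmatrix <- function(l, panel, h2 = 0.5, bias_correct = TRUE) {
  assert_panel(panel)
  if (!(h2 > 0 && h2 <= 1)) stopf("h2 must lie in (0, 1]")
  if (!inherits(l, "liability_table")) l <- liability_transform(l, panel)
  if (!same_panel(l$panel, panel)) stopf("liability table panel does not match")
  z <- l$z
  t_traits <- ncol(z)
  zbar <- as.numeric(panel$w %*% z)
  D <- sweep(z, 2, zbar)
  cmat <- tcrossprod(D) / (t_traits * h2)
  dimnames(cmat) <- list(panel$labels, panel$labels)
  corr <- if (bias_correct) rowMeans(l$v) / h2 else NULL
  c_to_r(cmat, panel, h2 = h2, bias_correct = bias_correct,
         diag_correction = corr, source = "threshold")
}
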