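#' R-matrix from allele frequencies
#'
#' Harpending-Ward estimator of the population kinship matrix. For each
#' locus l and allele a, with weighted centroid frequency
#' `pbar = sum_i w_i p_ila`, the standardized cross-product
#'
#'   (p_ila - pbar)(p_jla - pbar) / (pbar (1 - pbar))
#'
#' is averaged over every (locus, allele) combination that is polymorphic
#' at the centroid to give r_ij. Multiallelic loci contribute one term per
#' allele; a biallelic locus thus contributes its (identical) term twice,
#' which leaves the mean unchanged and makes SNP and STR input uniform.
#' Alleles fixed at the centroid carry no information and are skipped (the
#' count is reported). Fst is the weighted mean of the diagonal.
#'
#' @param f a [frequency_table()] with every (population, locus) present
#' @param panel a [population_panel()]; its weights (typically from
#'   effective population sizes) define the centroid
#' @return a [kinship_matrix()] with `source = "allele"`
#' @examples
#' pan <- population_panel(c("A", "B"), n = 50)
#' f <- data.frame(population = rep(c("A", "B"), each = 2),
#'                 locus = "L1", allele = c("a1", "a2", "a1", "a2"),
#'                 frequency = c(0.6, 0.4, 0.4, 0.6), n_obs = 50)
#' allele_rmatrix(frequency_table(f, pan), pan)  # r_AA = 0.04, Fst = 0.04
#' @export
allele_rmatrix <- function(f, panel) {
  assert_panel(panel)
  if (length(panel$labels) < 2) stopf("need at least 2 populations")
  f <- frequency_table(as.data.frame(f), panel = panel)
  # populations x (locus:allele) frequency matrix
  col_key <- paste(f$locus, f$allele, sep = "\r")
  cols <- unique(col_key)
  P <- matrix(NA_real_, nrow = length(panel$labels), ncol = length(cols),
              dimnames = list(panel$labels, cols))
  P[cbind(match(f$population, panel$labels), match(col_key, cols))] <- f$frequency
  if (anyNA(P)) {
    n_miss <- sum(apply(is.na(P), 1, any))
    stopf("frequency table must be complete: %d population(s) lack entries for some locus/allele; observed alleles must be listed (with frequency 0) for every population", n_miss)
  }
  w <- panel$w
  pbar <- as.numeric(w %*% P)
  poly <- pbar > 0 & pbar < 1
  n_skip <- sum(!poly)
  if (!any(poly)) stopf("all alleles are monomorphic at the centroid")
  if (n_skip > 0)
    message(sprintf("allele_rmatrix: skipped %d of %d centroid-monomorphic allele column(s)",
                    n_skip, length(pbar)))
  D <- sweep(P[, poly, drop = FALSE], 2, pbar[poly])
  X <- sweep(D, 2, sqrt(pbar[poly] * (1 - pbar[poly])), "/")
  r <- tcrossprod(X) / ncol(X)
  kinship_matrix(r, panel, source = "allele")
}
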