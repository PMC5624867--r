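# Long-term effective population size from the decay of linkage
# disequilibrium with recombination distance. Under drift-recombination
# equilibrium E[r2] ~ 1/(4 Ne c + 2), so each recombination distance class
# yields an estimate Ne = (1/4c)(1/r2 - 2) that reflects the effective
# size about 1/(2c) generations ago; the harmonic mean over classes gives
# a long-term Ne suitable for weighting kinship matrices.

#' Pairwise LD (r2) for SNP pairs within a recombination distance window
#'
#' Computes, for every same-chromosome marker pair whose map distance d
#' satisfies `min_cM <= d < max_cM`, the squared Pearson correlation of
#' the dosage vectors over individuals with both markers observed (a
#' composite, phase-free estimator). Monomorphic markers yield no pairs.
#'
#' @param gm a [genotype_matrix()] with chromosome labels and cM positions
#' @param min_cM lower distance bound, inclusive (default 0.005); closer
#'   pairs are dominated by gene conversion and typing artefacts and are
#'   not considered
#' @param max_cM upper distance bound, exclusive (default 0.25)
#' @return data frame of class `ld_pairs`: `marker1`, `marker2`,
#'   `distance_cM`, `r2`
#' @export
pairwise_r2 <- function(gm, min_cM = 0.005, max_cM = 0.25) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (min_cM >= max_cM) stopf("min_cM must be below max_cM")
  map <- gm$map
  out <- vector("list", 0L)
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    if (length(idx) < 2) next
    pos <- map$position_cM[idx]
    pairs <- which(
      outer(pos, pos, function(a, b) abs(a - b)) >= min_cM &
        outer(pos, pos, function(a, b) abs(a - b)) < max_cM,
      arr.ind = TRUE
    )
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs) == 0) next
    res <- matrix(NA_real_, nrow(pairs), 2)
    keep <- logical(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- idx[pairs[p, 1]]
      j <- idx[pairs[p, 2]]
      x <- gm$dosage[, i]
      y <- gm$dosage[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2) next
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      res[p, ] <- c(abs(map$position_cM[i] - map$position_cM[j]),
                    cor(x[ok], y[ok])^2)
      keep[p] <- TRUE
    }
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        marker1 = map$marker[idx[pairs[keep, 1]]],
        marker2 = map$marker[idx[pairs[keep, 2]]],
        distance_cM = res[keep, 1],
        r2 = res[keep, 2],
        stringsAsFactors = FALSE
      )
  }
  if (length(out) == 0) stopf("no eligible marker pairs in [%g, %g) cM", min_cM, max_cM)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("ld_pairs", "data.frame")
  df
}

#' Effective population size profile from binned LD
#'
#' Each pair's r2 is first adjusted for chromosome sample size by
#' subtracting `1/(2 n)` (the expectation under linkage equilibrium with
#' 2n sampled chromosomes). Class centers are evenly spaced across
#' `[min_cM, max_cM]`; each class collects the pairs within one center
#' spacing of its center, so adjacent classes overlap by about half.
#' Per class k the estimate is
#'
#'   Ne_k = (1/(4 c_k)) (1 / mean(r2_adj) - 2),   c_k in Morgans,
#'
#' interpreted as the effective size `1/(2 c_k)` generations ago. Classes
#' with no pairs, non-positive mean adjusted r2 or non-positive Ne are
#' flagged (`used = FALSE`) and excluded from the harmonic-mean long-term
#' Ne.
#'
#' @param pairs an `ld_pairs` data frame from [pairwise_r2()]
#' @param n_individuals diploid sample size the dosages come from
#' @param n_classes number of overlapping distance classes (default 250)
#' @param min_cM,max_cM range spanned by the class centers (defaults
#'   0.005 and 0.25)
#' @param adjust subtract the `1/(2n)` sample-size term (default TRUE)
#' @return list of class `ne_profile`: `classes` (data frame with
#'   `class_center_cM`, `n_pairs`, `mean_r2_adj`, `ne`, `generations_ago`,
#'   `used`), `ne_longterm` (harmonic mean over used classes),
#'   `n_individuals` and `n_pairs`
#' @examples
#' # a single class with mean adjusted r2 = 0.05 at 0.1 cM gives
#' # Ne = (1/0.004) * (20 - 2) = 4500, dated 500 generations ago
#' @export
estimate_ne <- function(pairs, n_individuals, n_classes = 250,
                        min_cM = 0.005, max_cM = 0.25, adjust = TRUE) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  r2_adj <- pairs$r2 - if (adjust) 1 / (2 * n_individuals) else 0
  centers <- seq(min_cM, max_cM, length.out = n_classes)
  spacing <- if (n_classes > 1) centers[2] - centers[1] else (max_cM - min_cM)
  cls <- data.frame(
    class_center_cM = centers,
    n_pairs = NA_integer_,
    mean_r2_adj = NA_real_,
    ne = NA_real_,
    generations_ago = 1 / (2 * centers / 100),
    used = FALSE
  )
  for (k in seq_len(n_classes)) {
    inb <- abs(pairs$distance_cM - centers[k]) <= spacing
    cls$n_pairs[k] <- sum(inb)
    if (!any(inb)) next
    m <- mean(r2_adj[inb])
    cls$mean_r2_adj[k] <- m
    if (m <= 0) next
    c_morgan <- centers[k] / 100
    ne_k <- (1 / (4 * c_morgan)) * (1 / m - 2)
    cls$ne[k] <- ne_k
    cls$used[k] <- ne_k > 0
  }
  if (!any(cls$used))
    stopf("no distance class yields a positive Ne estimate")
  used_ne <- cls$ne[cls$used]
  ne_lt <- length(used_ne) / sum(1 / used_ne)
  structure(list(classes = cls, ne_longterm = ne_lt,
                 n_individuals = n_individuals, n_pairs = nrow(pairs)),
            class = "ne_profile")
}

#' @export
print.ne_profile <- function(x, ...) {
  cat(sprintf("Ne profile: %d/%d classes used, long-term Ne (harmonic mean) = %.1f\n",
              sum(x$classes$used), nrow(x$classes), x$ne_longterm))
  invisible(x)
}
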