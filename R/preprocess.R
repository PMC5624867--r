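# Data cleaning applied before kinship estimation: marker filters and
# outlier screening on the genetic side; missingness handling, size
# correction and dichotomization on the dental side.

#' Remove strand-ambiguous markers
#'
#' A/T and C/G polymorphisms cannot be oriented unambiguously when panels
#' genotyped on different strands are merged, so they are removed before
#' any analysis.
#'
#' @param gm a [genotype_matrix()] whose map carries single-character
#'   alleles in \{A, C, G, T\}
#' @return a `genotype_matrix` without ambiguous markers
#' @export
filter_strand_ambiguous <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  a1 <- toupper(gm$map$allele1)
  a2 <- toupper(gm$map$allele2)
  ok_codes <- c("A", "C", "G", "T")
  if (!all(a1 %in% ok_codes) || !all(a2 %in% ok_codes))
    stopf("allele codes must be single characters in {A, C, G, T}")
  ambiguous <- (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
  message(sprintf("filter_strand_ambiguous: removed %d of %d markers",
                  sum(ambiguous), length(ambiguous)))
  if (all(ambiguous))
    warnf("all markers are strand-ambiguous; no markers remain")
  keep <- gm$map$marker[!ambiguous]
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$map[!ambiguous, , drop = FALSE],
                  gm$population)
}

#' Detect outlier individuals by principal components
#'
#' Runs a PCA on an individuals-by-allele-indicator matrix and flags any
#' individual whose score on one of the first `n_pcs` principal components
#' lies more than `sd_threshold` standard deviations from that component's
#' mean. The rule is invariant to component sign flips because only
#' absolute deviations are compared.
#'
#' @param indicator numeric matrix, individuals (rows, named) x allele
#'   indicators; at least 5 rows
#' @param sd_threshold flagging threshold in component standard deviations
#'   (default 6)
#' @param n_pcs number of leading components examined (default 4)
#' @return character vector of flagged individual ids (possibly empty)
#' @export
detect_outliers <- function(indicator, sd_threshold = 6, n_pcs = 4) {
  indicator <- as.matrix(indicator)
  if (nrow(indicator) < 5)
    stopf("need at least 5 individuals for PC outlier screening")
  pc <- prcomp(indicator, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  flagged <- rep(FALSE, nrow(indicator))
  for (j in seq_len(k)) {
    s <- pc$x[, j]
    sdj <- sd(s)
    if (sdj == 0) next
    flagged <- flagged | abs(s - mean(s)) > sd_threshold * sdj
  }
  ids <- rownames(indicator) %||% as.character(seq_len(nrow(indicator)))
  ids[flagged]
}

missing_fraction <- function(m) mean(is.na(m))

#' Drop individuals with excessive missingness
#'
#' Removes individuals missing strictly more than `max_missing_frac` of
#' their measurements (the default keeps anyone missing at most half).
#'
#' @param t trait data frame (`id`, `population`, trait columns)
#' @param max_missing_frac highest tolerated per-individual missing
#'   fraction (default 0.5)
#' @return the filtered table
#' @export
drop_sparse_individuals <- function(t, max_missing_frac = 0.5) {
  vals <- trait_values(t)
  frac <- rowMeans(is.na(vals))
  keep <- frac <= max_missing_frac
  message(sprintf("drop_sparse_individuals: removed %d of %d individuals",
                  sum(!keep), length(keep)))
  if (!any(keep)) warnf("all individuals removed; table is empty")
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-nearest-neighbor imputation of metric traits
#'
#' Each missing cell is replaced by the arithmetic mean of the values of
#' the `k` most similar individuals that have the variable observed.
#' Similarity is Euclidean distance over the variables observed in both
#' individuals, computed on per-variable standardized values (mean 0,
#' SD 1 over observed entries) and divided by the number of shared
#' variables; individuals sharing no observed variable are not eligible
#' neighbors. Observed cells are never altered.
#'
#' @param t trait data frame with missing values
#' @param k neighbor count (default 5)
#' @return the table with all missing cells imputed
#' @export
knn_impute <- function(t, k = 5) {
  vals <- trait_values(t)
  n <- nrow(vals)
  obs_per_var <- colSums(!is.na(vals))
  short <- obs_per_var < k
  if (any(short))
    stopf("variable(s) observed in fewer than k = %d individuals: %s", k,
          paste(colnames(vals)[short], collapse = ", "))
  mu <- colMeans(vals, na.rm = TRUE)
  sg <- apply(vals, 2, sd, na.rm = TRUE)
  sg[sg == 0 | is.na(sg)] <- 1
  z <- sweep(sweep(vals, 2, mu), 2, sg, "/")
  out <- vals
  need <- which(rowSums(is.na(vals)) > 0)
  for (i in need) {
    zi <- z[i, ]
    shared <- (!is.na(z)) & matrix(rep(!is.na(zi), each = n), nrow = n)
    m_shared <- rowSums(shared)
    diff2 <- sweep(z, 2, zi, `-`)^2
    diff2[!shared] <- 0
    d <- sqrt(rowSums(diff2)) / m_shared
    d[i] <- Inf
    d[m_shared == 0] <- Inf
    for (v in which(is.na(vals[i, ]))) {
      dv <- d
      dv[is.na(vals[, v])] <- Inf
      nb <- order(dv)[seq_len(k)]
      if (any(!is.finite(dv[nb])))
        stopf("too few eligible neighbors for variable %s", colnames(vals)[v])
      out[i, v] <- mean(vals[nb, v])
    }
  }
  t[colnames(vals)] <- out
  t
}

#' Geometric-mean size correction
#'
#' Converts raw crown diameters to shape variables by dividing each
#' measurement by the geometric mean of all measurements in that
#' individual. This removes gross size (and with it most sexual size
#' dimorphism) so that variables express proportionate contributions to
#' tooth size. Requires a complete, strictly positive table; the operation
#' is idempotent and invariant to rescaling any individual's row.
#'
#' @param t complete trait data frame with positive values
#' @return the table of shape variables (per-individual geometric mean 1)
#' @export
geometric_mean_shape <- function(t) {
  vals <- trait_values(t)
  if (anyNA(vals)) stopf("table must be complete before size correction")
  if (any(vals <= 0)) stopf("all measurements must be strictly positive")
  gm <- exp(rowMeans(log(vals)))
  t[colnames(vals)] <- vals / gm
  t
}

#' Stepwise missingness reduction for trait tables
#'
#' Iteratively removes whichever single variable or individual currently
#' has the highest missing fraction until the overall missing fraction of
#' the table falls below `target_frac`. Ties are broken in favor of
#' variables over individuals, then lexicographically. Keeping overall
#' missingness low protects the downstream dispersion estimates from
#' becoming non-positive-semidefinite.
#'
#' @param t trait data frame (typically binary traits)
#' @param target_frac overall missing fraction to get under (default 0.40)
#' @return the reduced table
#' @export
reduce_missingness <- function(t, target_frac = 0.40) {
  repeat {
    vals <- trait_values(t)
    if (nrow(vals) == 0 || ncol(vals) == 0)
      stopf("missingness target %.2f unreachable without emptying the table",
            target_frac)
    if (missing_fraction(vals) < target_frac) break
    var_frac <- colMeans(is.na(vals))
    ind_frac <- rowMeans(is.na(vals))
    vmax <- max(var_frac)
    imax <- max(ind_frac)
    if (vmax >= imax) {
      drop_var <- sort(colnames(vals)[var_frac == vmax])[1]
      t <- t[, names(t) != drop_var, drop = FALSE]
    } else {
      drop_id <- sort(t$id[ind_frac == imax])[1]
      t <- t[t$id != drop_id, , drop = FALSE]
    }
  }
  rownames(t) <- NULL
  t
}

#' Dichotomize graded ordinal traits
#'
#' Converts ASUDAS-style ordinal grades to presence/absence: a grade at or
#' above the trait's threshold scores 1, below it 0, missing stays
#' missing. Per-side columns (`trait__L` / `trait__R`) use their trait's
#' threshold.
#'
#' @param t ordinal trait data frame; trait columns may be plain trait
#'   names or per-side `trait__L` / `trait__R`
#' @param thresholds data frame with columns `trait`, `min_grade_present`
#' @return a binary table with the same columns
#' @export
dichotomize <- function(t, thresholds) {
  stopifnot(all(c("trait", "min_grade_present") %in% names(thresholds)))
  thr <- setNames(thresholds$min_grade_present, thresholds$trait)
  for (col in trait_columns(t)) {
    base <- sub("__[LR]$", "", col)
    if (!base %in% names(thr)) stopf("no dichotomization threshold for trait %s", base)
    t[[col]] <- as.numeric(t[[col]] >= thr[[base]])
  }
  t
}

#' Individual count scoring of bilateral traits
#'
#' Collapses per-side observations to one score per dentition, taking the
#' side with the highest expression; a side that is missing is ignored and
#' the score is missing only when both sides are.
#'
#' @param b binary per-side table with columns `trait__L` / `trait__R`
#' @return a binary table with one column per trait
#' @export
individual_count <- function(b) {
  cols <- trait_columns(b)
  traits <- unique(sub("__[LR]$", "", cols))
  out <- b[intersect(names(b), c("id", "population", "sex"))]
  for (tr in traits) {
    sides <- intersect(paste0(tr, c("__L", "__R")), cols)
    m <- as.matrix(b[sides])
    v <- apply(m, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    out[[tr]] <- v
  }
  out
}
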