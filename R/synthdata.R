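# Synthetic data with a known ground-truth kinship structure. Populations
# diverge from a common centroid so that deviations (of allele
# frequencies, trait means or liabilities) have covariance proportional
# to a target R-matrix; every estimator in the package can then be
# checked by parameter recovery. All generators are seed-deterministic.

#' Project a covariance matrix onto a centroid-constrained target R-matrix
#'
#' Any symmetric PSD matrix can serve as the raw between-population
#' covariance; projecting it with `P = I - 1 w'` (so `R = P cov P'`)
#' enforces the weighted-centroid constraint that defines an R-matrix.
#' The projection is idempotent: an already constrained matrix is
#' returned unchanged.
#'
#' @param panel a [population_panel()]
#' @param cov G x G symmetric positive semi-definite matrix
#' @return a [kinship_matrix()] with `source = "target"`
#' @examples
#' pan <- population_panel(c("A", "B"), n = 50)
#' make_rmatrix_target(pan, diag(0.08, 2))$r  # +/- 0.04
#' @export
make_rmatrix_target <- function(panel, cov) {
  assert_panel(panel)
  cov <- as.matrix(cov)
  G <- length(panel$labels)
  stopifnot(all(dim(cov) == G))
  if (max(abs(cov - t(cov))) > 1e-10) stopf("cov must be symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stopf("cov must be positive semi-definite (min eigenvalue %.3g)", min(ev))
  r <- centroid_project(cov, panel$w)
  kinship_matrix(r, panel, source = "target")
}

#' Island-model target R-matrix with an exact Fst
#'
#' Builds `cov = F I` with F chosen so that after centroid projection the
#' weighted mean diagonal equals `fst` exactly
#' (`F = fst / (1 - sum w_i^2)`). Convenient for recovery experiments.
#'
#' @param panel a [population_panel()]
#' @param fst target Fst (> 0)
#' @return a [kinship_matrix()] with `fst` equal to the target
#' @export
island_rmatrix <- function(panel, fst) {
  assert_panel(panel)
  stopifnot(fst > 0)
  FF <- fst / (1 - sum(panel$w^2))
  make_rmatrix_target(panel, diag(FF, length(panel$labels)))
}

# Population mean deviations for L replicate draws: L x G matrix with
# rows ~ N(0, sigma).
draw_deviations <- function(L, sigma) rmvnorm_psd(L, sigma)

#' Simulate SNP allele frequencies (and optional genotypes)
#'
#' Per locus the centroid frequency is drawn uniform on (0.1, 0.9) and
#' population deviations are multivariate normal with covariance
#' `R_true * pbar (1 - pbar)`, the first-order drift model under which
#' the allele-frequency R-matrix estimator is consistent. Frequencies are
#' clipped to \[0.01, 0.99\] (clip events are rare under moderate Fst and
#' reported). Optional genotypes are binomial(2, p) draws for `n_i`
#' individuals per population, laid out one locus per chromosome with
#' non-ambiguous alleles.
#'
#' @param R_true target [kinship_matrix()]
#' @param L number of biallelic loci
#' @param panel a [population_panel()]
#' @param seed integer seed
#' @param genotypes also return individual-level dosages (default FALSE)
#' @return a [frequency_table()]; with `genotypes = TRUE`, a list
#'   `list(freq, genotypes)`
#' @export
simulate_snp_frequencies <- function(R_true, L, panel, seed = NULL,
                                     genotypes = FALSE) {
  assert_panel(panel)
  stopifnot(inherits(R_true, "kinship_matrix"), L >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  G <- length(panel$labels)
  pbar <- runif(L, 0.1, 0.9)
  dev <- draw_deviations(L, R_true$r) * sqrt(pbar * (1 - pbar))
  p <- pbar + dev  # L x G
  n_clip <- sum(p < 0.01 | p > 0.99)
  if (n_clip > 0)
    message(sprintf("simulate_snp_frequencies: clipped %d of %d frequencies", n_clip, length(p)))
  p <- pmin(pmax(p, 0.01), 0.99)
  loci <- sprintf("snp%05d", seq_len(L))
  df <- data.frame(
    population = rep(panel$labels, each = 2 * L),
    locus = rep(rep(loci, each = 2), G),
    allele = rep(c("a1", "a2"), L * G),
    frequency = as.numeric(vapply(seq_len(G), function(i)
      rbind(p[, i], 1 - p[, i]), numeric(2 * L))),
    n_obs = rep(panel$n, each = 2 * L),
    stringsAsFactors = FALSE
  )
  ft <- frequency_table(df, panel = panel)
  if (!genotypes) return(ft)
  n_tot <- sum(panel$n)
  dosage <- matrix(NA_real_, n_tot, L)
  pop_lab <- rep(panel$labels, panel$n)
  row0 <- 0L
  for (i in seq_len(G)) {
    ni <- panel$n[i]
    dosage[row0 + seq_len(ni), ] <- matrix(
      rbinom(ni * L, 2, rep(p[, i], each = ni)), ni, L)
    row0 <- row0 + ni
  }
  colnames(dosage) <- loci
  rownames(dosage) <- sprintf("ind%05d", seq_len(n_tot))
  alle <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4, L, replace = TRUE)
  map <- data.frame(marker = loci,
                    chromosome = sprintf("chr%05d", seq_len(L)),
                    position_cM = 0,
                    allele1 = alle[pick, 1], allele2 = alle[pick, 2],
                    stringsAsFactors = FALSE)
  list(freq = ft, genotypes = genotype_matrix(dosage, map, pop_lab))
}

#' Simulate STR (multiallelic) frequencies
#'
#' Centroid allele-frequency vectors are symmetric Dirichlet(2) draws
#' over `A` alleles. Population deviations follow multiallelic drift: the
#' joint covariance of the deviation matrix is
#' `R_true (x) (diag(pbar) - pbar pbar')`, which gives every allele the
#' marginal drift variance `r_ij pbar_a (1 - pbar_a)` of the SNP
#' generator while keeping each population's deviations summing to zero
#' across alleles, so the simplex constraint is respected by
#' construction. Frequencies are clipped at 0.005 and renormalized (a
#' small correction affecting only clipped rare alleles). With `A = 2`
#' the generator reduces distributionally to the SNP case.
#'
#' @param R_true target [kinship_matrix()]
#' @param L number of loci
#' @param A alleles per locus (>= 2)
#' @param panel a [population_panel()]
#' @param seed integer seed
#' @return a [frequency_table()]
#' @export
simulate_str_frequencies <- function(R_true, L, A, panel, seed = NULL) {
  assert_panel(panel)
  stopifnot(inherits(R_true, "kinship_matrix"), L >= 1, A >= 2)
  if (!is.null(seed)) withr::local_seed(seed)
  G <- length(panel$labels)
  sqrt_R <- {
    eg <- eigen(R_true$r, symmetric = TRUE)
    eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  }
  rows <- vector("list", L)
  for (l in seq_len(L)) {
    g <- stats::rgamma(A, shape = 2)
    pbar <- g / sum(g)
    # multinomial drift covariance across alleles: deviations sum to 0
    M <- diag(pbar) - tcrossprod(pbar)
    egM <- eigen(M, symmetric = TRUE)
    sqrt_M <- egM$vectors %*% (sqrt(pmax(egM$values, 0)) * t(egM$vectors))
    dev <- sqrt_M %*% matrix(rnorm(A * G), A, G) %*% sqrt_R  # A x G
    p <- pmax(pbar + dev, 0.005)
    p <- sweep(p, 2, colSums(p), "/")
    rows[[l]] <- data.frame(
      population = rep(panel$labels, each = A),
      locus = sprintf("str%04d", l),
      allele = rep(sprintf("a%02d", seq_len(A)), G),
      frequency = as.numeric(p),
      n_obs = rep(panel$n, each = A),
      stringsAsFactors = FALSE
    )
  }
  frequency_table(do.call(rbind, rows), panel = panel)
}

# Between-population covariance of genetic trait means under which the
# quantitative estimator chain (codivergence -> c_to_r) is consistent:
# 2 R h2 / (1 - Fst) times the (unit) within-group phenotypic variance.
between_mean_cov <- function(R_true, h2) {
  2 * R_true$r * h2 / (1 - R_true$fst)
}

#' Simulate individual-level metric traits
#'
#' Traits are independent with within-population phenotypic variance 1
#' and additive genetic variance h2. Population genetic means per trait
#' are multivariate normal with covariance `2 R_true h2 / (1 - Fst)`, the
#' model under which the quantitative R-matrix chain recovers `R_true`
#' exactly in expectation. Individual values are population mean plus
#' standard normal noise, shifted by +20 onto a strictly positive
#' crown-diameter-like scale. An optional missingness mask supports
#' imputation experiments.
#'
#' @param R_true target [kinship_matrix()]
#' @param h2 heritability in (0, 1]
#' @param t number of traits
#' @param panel a [population_panel()]; `panel$n` individuals per
#'   population are drawn
#' @param seed integer seed
#' @param missing_frac fraction of cells set missing at random (default 0)
#' @return a metric trait data frame (`id`, `population`, `V1..Vt`)
#' @export
simulate_metric_traits <- function(R_true, h2, t, panel, seed = NULL,
                                   missing_frac = 0) {
  assert_panel(panel)
  stopifnot(inherits(R_true, "kinship_matrix"), h2 > 0, h2 <= 1, t >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  G <- length(panel$labels)
  mu <- draw_deviations(t, between_mean_cov(R_true, h2))  # t x G
  n_tot <- sum(panel$n)
  pop_lab <- rep(panel$labels, panel$n)
  vals <- 20 + base::t(mu)[rep(seq_len(G), panel$n), , drop = FALSE] +
    matrix(rnorm(n_tot * t), n_tot, t)
  if (missing_frac > 0)
    vals[runif(length(vals)) < missing_frac] <- NA
  df <- data.frame(id = sprintf("ind%05d", seq_len(n_tot)),
                   population = pop_lab, stringsAsFactors = FALSE)
  df[paste0("V", seq_len(t))] <- vals
  df
}

#' Simulate binary traits under the liability threshold model
#'
#' Liabilities have unit within-population variance: population genetic
#' means are drawn as in [simulate_metric_traits()] and each individual's
#' liability adds standard normal within-population noise (within-group
#' genetic and environmental components combined). A trait is present
#' when the liability exceeds its threshold. Thresholds near 0 give
#' frequencies near 0.5; extreme thresholds exercise the continuity
#' correction in [liability_transform()].
#'
#' @param R_true target [kinship_matrix()]
#' @param h2 liability heritability in (0, 1]
#' @param t number of traits
#' @param thresholds per-trait probit thresholds (finite; recycled)
#' @param panel a [population_panel()]
#' @param seed integer seed
#' @param missing_frac fraction of scores masked at random (default 0)
#' @return a binary trait data frame (`id`, `population`, `T1..Tt`)
#' @export
simulate_binary_traits <- function(R_true, h2, t, thresholds, panel,
                                   seed = NULL, missing_frac = 0) {
  assert_panel(panel)
  stopifnot(inherits(R_true, "kinship_matrix"), h2 > 0, h2 <= 1, t >= 1)
  thresholds <- rep_len(as.numeric(thresholds), t)
  if (any(!is.finite(thresholds))) stopf("thresholds must be finite")
  if (!is.null(seed)) withr::local_seed(seed)
  G <- length(panel$labels)
  mu <- draw_deviations(t, between_mean_cov(R_true, h2))  # t x G
  n_tot <- sum(panel$n)
  pop_lab <- rep(panel$labels, panel$n)
  liab <- base::t(mu)[rep(seq_len(G), panel$n), , drop = FALSE] +
    matrix(rnorm(n_tot * t), n_tot, t)
  vals <- 1 * (liab > matrix(thresholds, n_tot, t, byrow = TRUE))
  if (missing_frac > 0)
    vals[runif(length(vals)) < missing_frac] <- NA
  df <- data.frame(id = sprintf("ind%05d", seq_len(n_tot)),
                   population = pop_lab, stringsAsFactors = FALSE)
  df[paste0("T", seq_len(t))] <- vals
  df
}

#' Simulate genotype pairs with a target LD decay
#'
#' Emulates drift-recombination equilibrium: a pair of SNPs at distance c
#' Morgans has target `rho2 = 1/(4 Ne c + 2)`. For each pair, allele
#' frequencies are uniform on (0.2, 0.8) and the haplotype disequilibrium
#' `D = sign * sqrt(rho2 p(1-p) q(1-q))` must fit the feasible D range;
#' frequency draws that cannot accommodate the required D are resampled
#' (bounded retries). 2n haplotypes are drawn from the implied
#' four-haplotype multinomial and paired at random into diploid
#' genotypes. Each pair sits on its own chromosome so only intended
#' pairs enter the LD analysis.
#'
#' @param ne true effective population size (>= 1)
#' @param pair_distances_cM vector of pair distances in cM, in (0, 0.25]
#' @param n diploid individuals
#' @param seed integer seed
#' @param max_retries frequency resampling budget per pair (default 100)
#' @return a [genotype_matrix()] with `2 * length(pair_distances_cM)`
#'   markers
#' @export
simulate_ld_genotypes <- function(ne, pair_distances_cM, n, seed = NULL,
                                  max_retries = 100) {
  stopifnot(ne >= 1, n >= 2, length(pair_distances_cM) >= 1,
            all(pair_distances_cM > 0), all(pair_distances_cM <= 0.25))
  if (!is.null(seed)) withr::local_seed(seed)
  n_pairs <- length(pair_distances_cM)
  dosage <- matrix(NA_real_, n, 2 * n_pairs)
  map <- data.frame(marker = character(2 * n_pairs),
                    chromosome = character(2 * n_pairs),
                    position_cM = numeric(2 * n_pairs),
                    allele1 = "A", allele2 = "G",
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    c_morgan <- pair_distances_cM[k] / 100
    rho2 <- 1 / (4 * ne * c_morgan + 2)
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      p <- runif(1, 0.2, 0.8)
      q <- runif(1, 0.2, 0.8)
      sgn <- sample(c(-1, 1), 1)
      D <- sgn * sqrt(rho2 * p * (1 - p) * q * (1 - q))
      lo <- max(-p * q, -(1 - p) * (1 - q))
      hi <- min(p * (1 - q), (1 - p) * q)
      if (D >= lo && D <= hi) { ok <- TRUE; break }
    }
    if (!ok) stopf("could not find feasible haplotype frequencies for pair %d", k)
    hap_freq <- c(p * q + D, p * (1 - q) - D, (1 - p) * q - D,
                  (1 - p) * (1 - q) + D)
    counts <- rmultinom(1, 2 * n, hap_freq)[, 1]
    hap_a <- rep(c(1, 1, 0, 0), counts)
    hap_b <- rep(c(1, 0, 1, 0), counts)
    ord <- sample.int(2 * n)
    hap_a <- hap_a[ord]; hap_b <- hap_b[ord]
    i1 <- seq(1, 2 * n, by = 2); i2 <- seq(2, 2 * n, by = 2)
    dosage[, 2 * k - 1] <- hap_a[i1] + hap_a[i2]
    dosage[, 2 * k] <- hap_b[i1] + hap_b[i2]
    map$marker[c(2 * k - 1, 2 * k)] <- sprintf("pair%04d_m%d", k, 1:2)
    map$chromosome[c(2 * k - 1, 2 * k)] <- sprintf("pairchr%04d", k)
    map$position_cM[c(2 * k - 1, 2 * k)] <- c(0, pair_distances_cM[k])
  }
  colnames(dosage) <- map$marker
  rownames(dosage) <- sprintf("ind%05d", seq_len(n))
  genotype_matrix(dosage, map, rep("POP1", n))
}
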