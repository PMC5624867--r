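test_that("target projection matches the island-model hand calculation", {
  pan <- toy_panel()
  k <- make_rmatrix_target(pan, diag(0.08, 2))
  expect_equal(unname(k$r), matrix(c(0.04, -0.04, -0.04, 0.04), 2),
               tolerance = 1e-12)

  # idempotence: a constrained matrix passes through unchanged
  k2 <- make_rmatrix_target(pan, k$r)
  expect_equal(k2$r, k$r, tolerance = 1e-14)

  # weighted row sums vanish for random PSD inputs and uneven weights
  pan3 <- population_panel(c("A", "B", "C"), 10, ne = c(100, 300, 600))
  set.seed(101)
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3)
    k3 <- make_rmatrix_target(pan3, tcrossprod(A))
    expect_lt(max(abs(k3$r %*% pan3$w)), 1e-12)
  }
  expect_error(make_rmatrix_target(pan, matrix(c(1, 2, 2, -3), 2)),
               "semi-definite")
})

test_that("island and clustered targets hit their Fst exactly", {
  pan <- population_panel(sprintf("P%d", 1:7), 30, ne = c(2, 1, 3, 1, 2, 4, 1) * 400)
  expect_equal(island_rmatrix(pan, 0.1)$fst, 0.1, tolerance = 1e-12)
  k <- clustered_rmatrix(pan, 0.08, n_clusters = 3)
  expect_equal(k$fst, 0.08, tolerance = 1e-12)
  expect_gt(sd(k$r[upper.tri(k$r)]), 0)  # usable off-diagonal spread
})

test_that("generators are seed-deterministic", {
  pan <- toy_panel(G = 4, n = 20)
  R <- clustered_rmatrix(pan, 0.1)
  expect_identical(simulate_snp_frequencies(R, 20, pan, seed = 5),
                   simulate_snp_frequencies(R, 20, pan, seed = 5))
  expect_identical(simulate_str_frequencies(R, 5, 4, pan, seed = 5),
                   simulate_str_frequencies(R, 5, 4, pan, seed = 5))
  expect_identical(simulate_metric_traits(R, 0.5, 3, pan, seed = 5),
                   simulate_metric_traits(R, 0.5, 3, pan, seed = 5))
  expect_identical(simulate_binary_traits(R, 0.5, 3, 0, pan, seed = 5),
                   simulate_binary_traits(R, 0.5, 3, 0, pan, seed = 5))
  g1 <- simulate_ld_genotypes(500, c(0.05, 0.2), 30, seed = 5)
  g2 <- simulate_ld_genotypes(500, c(0.05, 0.2), 30, seed = 5)
  expect_identical(g1$dosage, g2$dosage)
})

test_that("zero kinship collapses all populations onto the centroid", {
  pan <- toy_panel(G = 3, n = 400)
  R0 <- kinship_matrix(matrix(0, 3, 3), pan, source = "target")
  f <- simulate_snp_frequencies(R0, 50, pan, seed = 31)
  wide <- tapply(f$frequency, list(f$population, paste(f$locus, f$allele)), mean)
  expect_lt(max(apply(wide, 2, sd)), 1e-12)

  m <- simulate_metric_traits(R0, 0.5, 4, pan, seed = 32)
  mm <- vapply(split(m$V1, m$population), mean, numeric(1))
  expect_lt(diff(range(mm)), 5 / sqrt(400))  # only residual noise separates means
})

test_that("SNP deviations match the target covariance structure", {
  pan <- toy_panel(G = 6, n = 50)
  R <- clustered_rmatrix(pan, 0.08, n_clusters = 3)
  f <- suppressMessages(simulate_snp_frequencies(R, 4000, pan, seed = 33))
  a1 <- f[f$allele == "a1", ]
  P <- matrix(a1$frequency[order(a1$locus, a1$population)],
              nrow = 6, dimnames = list(sort(pan$labels), NULL))
  pbar <- colMeans(P * pan$w * 6)
  dev <- sweep(P, 2, pbar)
  emp <- tcrossprod(sweep(dev, 2, sqrt(pbar * (1 - pbar)), "/")) / ncol(P)
  expect_gte(cor(as.numeric(emp), as.numeric(R$r)), 0.95)
})

# Independent oracle for the STR generator: closed-form moments of the
# floor-censored normal (the drift model actually emitted), renormalized
# per population and averaged over Dirichlet(2) centroid draws. Predicts
# the drift variance the generated frequencies really carry, which for
# rare multiallelic alleles is attenuated by the frequency floor.
censored_drift_fst <- function(rii, w, A, floor = 0.005, nrep = 1500, seed = 99) {
  cens <- function(mu, sig, a) {
    z <- (a - mu) / sig
    EY <- a * pnorm(z) + mu * (1 - pnorm(z)) + sig * dnorm(z)
    EY2 <- a^2 * pnorm(z) + (mu^2 + sig^2) * (1 - pnorm(z)) +
      sig * (mu + a) * dnorm(z)
    c(EY, EY2 - EY^2)
  }
  set.seed(seed)
  G <- length(rii)
  tot <- 0; m <- 0
  for (r in seq_len(nrep)) {
    g <- rgamma(A, 2); pbar <- g / sum(g)
    EY <- VY <- matrix(0, A, G)
    for (a in seq_len(A)) for (i in seq_len(G)) {
      cm <- cens(pbar[a], sqrt(rii[i] * pbar[a] * (1 - pbar[a])), floor)
      EY[a, i] <- cm[1]; VY[a, i] <- cm[2]
    }
    s <- colSums(EY)
    EY <- sweep(EY, 2, s, "/"); VY <- sweep(VY, 2, s^2, "/")
    for (a in seq_len(A)) {
      mr <- sum(w * EY[a, ])
      tot <- tot + sum(w * (VY[a, ] + (EY[a, ] - mr)^2)) / (mr * (1 - mr))
      m <- m + 1
    }
  }
  tot / m
}

test_that("STR frequencies are simplex-valued and match the censored-drift oracle", {
  pan <- toy_panel(G = 8, n = 40)
  R <- clustered_rmatrix(pan, 0.10)
  f <- simulate_str_frequencies(R, 645, 8, pan, seed = 35)
  sums <- tapply(f$frequency, paste(f$population, f$locus), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  k <- suppressMessages(allele_rmatrix(f, pan))
  target <- censored_drift_fst(diag(R$r), pan$w, A = 8)
  expect_lt(abs(k$fst - target), 0.015)
  # the kinship structure itself is recovered essentially exactly
  expect_gte(offdiag_cor(k, R), 0.95)
})

test_that("the A = 2 STR generator behaves like the SNP generator", {
  pan <- toy_panel(G = 8, n = 40)
  R <- clustered_rmatrix(pan, 0.10)
  f2 <- simulate_str_frequencies(R, 800, 2, pan, seed = 36)
  fsnp <- suppressMessages(simulate_snp_frequencies(R, 800, pan, seed = 36))
  fst2 <- suppressMessages(allele_rmatrix(f2, pan))$fst
  fstsnp <- suppressMessages(allele_rmatrix(fsnp, pan))$fst
  expect_lt(abs(fst2 - fstsnp), 0.012)
})

test_that("binary generator respects thresholds and exercises the continuity path", {
  pan <- toy_panel(G = 3, n = 200)
  R0 <- kinship_matrix(matrix(0, 3, 3), pan, source = "target")
  b <- simulate_binary_traits(R0, 0.5, 2, c(0, -10), pan, seed = 37)
  f1 <- mean(b$T1)
  expect_lt(abs(f1 - 0.5), 0.1)      # threshold 0: frequency near 1/2
  expect_equal(mean(b$T2), 1)        # threshold -Inf-like: monomorphic presence
  # the monomorphic trait still transforms finitely via continuity correction
  l <- liability_transform(b, pan)
  expect_true(all(is.finite(l$z)))
})

test_that("LD generator's unadjusted r2 exceeds adjusted by about 1/(2n)", {
  set.seed(39)
  d <- runif(300, 0.01, 0.25)
  gm <- simulate_ld_genotypes(800, d, 400, seed = 41)
  pr <- pairwise_r2(gm)
  prof_adj <- estimate_ne(pr, 400, n_classes = 5, adjust = TRUE)
  prof_raw <- estimate_ne(pr, 400, n_classes = 5, adjust = FALSE)
  both <- prof_adj$classes$used & prof_raw$classes$used
  gap <- prof_raw$classes$mean_r2_adj[both] - prof_adj$classes$mean_r2_adj[both]
  expect_equal(gap, rep(1 / 800, sum(both)), tolerance = 1e-12)
})

test_that("simulate_study writes a complete, consumable fixture", {
  dir <- withr::local_tempdir()
  out <- suppressMessages(simulate_study(
    dir, G = 6, str_subset = 4, n_per_pop = 25, snp_loci = 120,
    str_loci = 30, str_alleles = 4, t_metric = 6, t_binary = 5,
    ne_ld = 800, ld_pairs = 40, ld_n = 50, seed = 3))
  for (f in c("panel.tsv", "snp_freq.tsv", "str_freq.tsv", "metric.tsv",
              "binary.tsv", "ld_geno.tsv", "ld_map.tsv", "r_true.tsv",
              "config.yaml"))
    expect_true(file.exists(file.path(dir, f)), label = f)
  truth <- read_matrix_tsv(file.path(dir, "r_true.tsv"))
  expect_equal(truth, out$truth$r, tolerance = 1e-9)
  pan <- read_panel(file.path(dir, "panel.tsv"))
  expect_identical(pan$labels, out$panel$labels)
})
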