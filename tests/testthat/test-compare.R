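rand_sym <- function(G, seed) {
  set.seed(seed)
  m <- matrix(rnorm(G * G), G)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("P%02d", 1:G), sprintf("P%02d", 1:G))
  m
}

test_that("Mantel r is exact for identical matrices and matches vegan's statistic", {
  a <- rand_sym(6, 61)
  res <- mantel(a, a, permutations = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 100)  # minimum attainable with add-one

  b <- rand_sym(6, 62)
  r_ours <- mantel(a, b, permutations = 9, seed = 1)$r
  r_vegan <- suppressWarnings(
    vegan::mantel(as.dist(a), as.dist(b), permutations = 9))$statistic
  expect_equal(r_ours, r_vegan, tolerance = 1e-10)
})

test_that("Mantel permutation p approximates exhaustive enumeration at G = 4", {
  a <- rand_sym(4, 63)
  b <- rand_sym(4, 64)
  # exact two-tailed p over all 24 relabelings
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  av <- a[upper.tri(a)]
  r_obs <- cor(av, b[upper.tri(b)])
  r_all <- apply(perms, 1, function(pm) cor(av, b[pm, pm][upper.tri(b)]))
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  res <- mantel(a, b, permutations = 10000, seed = 2)
  expect_lt(abs(res$p - p_exact), 0.02)
})

test_that("Mantel test holds its type-I error on independent matrices", {
  pan <- toy_panel(G = 8)
  rej <- vapply(1:500, function(i) {
    a <- random_rmatrix(pan, 0.1, seed = 2 * i)
    b <- random_rmatrix(pan, 0.1, seed = 2 * i + 1)
    mantel(a, b, permutations = 199, seed = 90000 + i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Mantel is invariant to affine off-diagonal transforms and needs G >= 4", {
  a <- rand_sym(5, 65); b <- rand_sym(5, 66)
  r1 <- mantel(a, b, permutations = 9, seed = 3)$r
  r2 <- mantel(a, 3.2 * b + 7, permutations = 9, seed = 3)$r
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(mantel(a[1:3, 1:3], b[1:3, 1:3]), "at least 4")
  # mismatched labels are refused
  c2 <- b; rownames(c2) <- colnames(c2) <- letters[1:5]
  expect_error(mantel(a, c2), "same populations")
})

test_that("Dow-Cheverud statistic is antisymmetric and detects the stronger predictor", {
  a <- rand_sym(6, 71); b <- rand_sym(6, 72); o <- rand_sym(6, 73)
  r_ab <- dow_cheverud(a, b, o, permutations = 49, seed = 4)
  r_ba <- dow_cheverud(b, a, o, permutations = 49, seed = 4)
  expect_equal(r_ab$statistic, -r_ba$statistic, tolerance = 1e-12)

  # a identical to b: statistic exactly 0
  expect_equal(dow_cheverud(a, a, o, permutations = 9, seed = 5)$statistic, 0)

  # planted signal at G = 13: outcome = a + noise, b independent
  hits <- vapply(1:20, function(i) {
    a13 <- rand_sym(13, 100 + i)
    b13 <- rand_sym(13, 200 + i)
    o13 <- a13 + 0.5 * rand_sym(13, 300 + i)
    dow_cheverud(a13, b13, o13, permutations = 9, seed = i)$statistic > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  cc <- matrix(1, 6, 6); dimnames(cc) <- dimnames(a)
  expect_error(dow_cheverud(cc, b, o), "constant off-diagonals")
})

test_that("PCoA embeds collinear points in one axis and reconstructs Euclidean distances", {
  # three collinear points at coordinates 0, 1, 2
  x <- c(0, 1, 2)
  d2 <- outer(x, x, function(a, b) (a - b)^2)
  dimnames(d2) <- list(c("A", "B", "C"), c("A", "B", "C"))
  res <- pcoa(d2)
  expect_gte(res$proportion[1], 0.999)

  # full-dimensional reconstruction of a Euclidean configuration
  set.seed(81)
  pts <- matrix(rnorm(7 * 3), 7)
  D2 <- as.matrix(dist(pts))^2
  dimnames(D2) <- list(sprintf("P%d", 1:7), sprintf("P%d", 1:7))
  res2 <- pcoa(D2)
  D2_hat <- as.matrix(dist(res2$coordinates))^2
  expect_equal(unname(D2_hat), unname(D2), tolerance = 1e-8)
  expect_true(all(diff(res2$eigenvalues) <= 1e-8))  # sorted descending

  # coincident populations land on identical coordinates
  d3 <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 0), 3)
  dimnames(d3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  res3 <- pcoa(d3)
  expect_equal(res3$coordinates["A", ], res3$coordinates["B", ], tolerance = 1e-10)
})

test_that("bonferroni adjusts the significance level", {
  expect_equal(bonferroni(0.05, 2), 0.025)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 5), 0.01)
  expect_error(bonferroni(0.05, 0), "positive integer")
})

test_that("permutation p-values are seed-reproducible and in range", {
  a <- rand_sym(6, 91); b <- rand_sym(6, 92)
  p1 <- mantel(a, b, permutations = 199, seed = 7)$p
  p2 <- mantel(a, b, permutations = 199, seed = 7)$p
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 200)
  expect_lte(p1, 1)
})

test_that("off-diagonal regression returns the paired table and an OLS fit", {
  a <- rand_sym(5, 95)
  set.seed(96)
  noise <- rand_sym(5, 96) * 1e-3
  b <- 2 * a + 1 + noise
  reg <- offdiag_regression(a, b)
  expect_equal(nrow(reg$pairs), 10)
  expect_equal(reg$slope, 2, tolerance = 1e-2)
  expect_equal(reg$intercept, 1, tolerance = 1e-2)
  expect_true(all(reg$conf_int[, 1] <= c(1, 2) & c(1, 2) <= reg$conf_int[, 2]))
})
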