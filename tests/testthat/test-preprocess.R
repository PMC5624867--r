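test_that("strand-ambiguous marker pairs (A/T, C/G) are removed", {
  dos <- matrix(1, 3, 4)
  gm <- toy_genotypes(dos, "chr1", c(0, 1, 2, 3),
                      allele1 = c("A", "A", "C", "C"),
                      allele2 = c("G", "T", "G", "T"))
  expect_message(out <- filter_strand_ambiguous(gm), "removed 2 of 4")
  expect_identical(colnames(out$dosage), c("m01", "m04"))

  # no ambiguous markers: identity
  gm2 <- toy_genotypes(dos, "chr1", c(0, 1, 2, 3),
                       allele1 = "A", allele2 = "G")
  expect_identical(suppressMessages(filter_strand_ambiguous(gm2))$dosage, gm2$dosage)

  # all ambiguous: empty marker set with a warning
  gm3 <- toy_genotypes(dos, "chr1", c(0, 1, 2, 3),
                       allele1 = "A", allele2 = "T")
  expect_warning(out3 <- suppressMessages(filter_strand_ambiguous(gm3)), "no markers remain")
  expect_equal(ncol(out3$dosage), 0)

  gm4 <- toy_genotypes(dos, "chr1", c(0, 1, 2, 3), allele1 = "N", allele2 = "G")
  expect_error(filter_strand_ambiguous(gm4), "allele codes")
})

test_that("PC outlier screening recovers a planted extreme individual", {
  set.seed(31)
  n <- 100
  base <- matrix(rbinom(n * 40, 1, 0.4), n, 40,
                 dimnames = list(sprintf("i%03d", 1:n), NULL))
  # homogeneous panel: no outliers expected at 6 SD
  expect_length(detect_outliers(base), 0)

  # plant an individual far out along the first component
  pc1 <- prcomp(base)$rotation[, 1]
  planted <- base
  planted["i001", ] <- colMeans(base) + 12 * sd(prcomp(base)$x[, 1]) * pc1
  expect_true("i001" %in% detect_outliers(planted))

  # threshold 0 flags everyone
  expect_setequal(detect_outliers(base, sd_threshold = 0), rownames(base))

  expect_error(detect_outliers(base[1:4, ]), "at least 5")
})

test_that("sparse individuals are dropped strictly above the missingness cutoff", {
  vals <- matrix(1, 3, 28)
  vals[1, 1:15] <- NA  # 15/28 > 0.5 -> removed
  vals[2, 1:14] <- NA  # 14/28 == 0.5 -> kept
  t <- toy_traits(vals, "P")
  out <- suppressMessages(drop_sparse_individuals(t))
  expect_identical(out$id, c("i02", "i03"))

  complete <- toy_traits(matrix(1, 3, 4), "P")
  expect_identical(suppressMessages(drop_sparse_individuals(complete)), complete)

  allna <- toy_traits(matrix(NA_real_, 2, 3), "P")
  expect_warning(out2 <- suppressMessages(drop_sparse_individuals(allna)), "empty")
  expect_equal(nrow(out2), 0)
})

test_that("kNN imputation averages the k nearest neighbors and keeps observed cells", {
  # k = 1: unique nearest neighbor's value is copied
  vals <- rbind(c(1.0, 1.0, NA), c(1.1, 1.1, 5.0), c(9, 9, 7))
  t <- toy_traits(vals, "P")
  out <- knn_impute(t, k = 1)
  expect_equal(out$V3[1], 5.0)

  # k = 2: mean of the two nearest neighbors
  vals2 <- rbind(c(1.0, 1.0, NA), c(1.1, 1.0, 2.0), c(1.0, 1.1, 4.0), c(9, 9, 9))
  out2 <- knn_impute(toy_traits(vals2, "P"), k = 2)
  expect_equal(out2$V3[1], 3.0)
  # observed cells untouched
  expect_equal(as.matrix(out2[2:4, 3:5]), as.matrix(toy_traits(vals2, "P")[2:4, 3:5]))

  expect_error(knn_impute(toy_traits(rbind(c(1, NA), c(2, 3)), "P"), k = 2),
               "fewer than k")
})

test_that("kNN imputation beats grand-mean imputation on masked synthetic data", {
  pan <- toy_panel(G = 4, n = 50)
  R <- clustered_rmatrix(pan, 0.15)
  full <- simulate_metric_traits(R, 0.5, 28, pan, seed = 5)
  vals <- as.matrix(full[paste0("V", 1:28)])
  # raw crown diameters share an individual size factor (removed later by
  # the shape correction); that correlation is what kNN exploits
  set.seed(16)
  vals <- vals + rnorm(nrow(vals))
  full[paste0("V", 1:28)] <- vals
  set.seed(17)
  mask <- matrix(runif(length(vals)) < 0.10, nrow(vals))
  masked <- full
  mvals <- vals; mvals[mask] <- NA
  masked[paste0("V", 1:28)] <- mvals
  imp <- knn_impute(masked, k = 5)
  ivals <- as.matrix(imp[paste0("V", 1:28)])
  err_knn <- mean(abs(ivals[mask] - vals[mask]))
  gmeans <- matrix(colMeans(mvals, na.rm = TRUE), nrow(vals), 28, byrow = TRUE)
  err_grand <- mean(abs(gmeans[mask] - vals[mask]))
  expect_lt(err_knn, err_grand)
})

test_that("geometric-mean shape correction normalizes, is idempotent and scale-invariant", {
  t <- toy_traits(rbind(c(2, 8), c(3, 3)), "P")
  out <- geometric_mean_shape(t)
  expect_equal(unlist(out[1, c("V1", "V2")], use.names = FALSE), c(0.5, 2))
  expect_equal(unlist(out[2, c("V1", "V2")], use.names = FALSE), c(1, 1))

  # row geometric means are 1 and the operation is idempotent
  set.seed(3)
  t2 <- toy_traits(matrix(exp(rnorm(60)), 10, 6), "P")
  s1 <- geometric_mean_shape(t2)
  gm <- exp(rowMeans(log(as.matrix(s1[paste0("V", 1:6)]))))
  expect_equal(gm, rep(1, 10), tolerance = 1e-12)
  expect_equal(geometric_mean_shape(s1), s1, tolerance = 1e-12)

  # scaling an individual's row leaves the output unchanged
  t3 <- t2
  t3[4, paste0("V", 1:6)] <- 7.3 * t3[4, paste0("V", 1:6)]
  expect_equal(geometric_mean_shape(t3), s1, tolerance = 1e-12)

  expect_error(geometric_mean_shape(toy_traits(rbind(c(1, NA)), "P")), "complete")
  expect_error(geometric_mean_shape(toy_traits(rbind(c(1, -2)), "P")), "positive")
})

test_that("stepwise missingness reduction reaches the target without emptying the table", {
  # already below target: identity
  t <- toy_traits(rbind(c(1, 0), c(0, 1)), "P")
  expect_identical(reduce_missingness(t), t)

  # one all-missing variable is exactly what gets dropped
  vals <- cbind(rep(NA_real_, 4), matrix(1, 4, 3))
  t2 <- toy_traits(vals, "P")
  out <- reduce_missingness(t2, target_frac = 0.10)
  expect_identical(setdiff(paste0("V", 1:4), names(out)), "V1")
  expect_equal(nrow(out), 4)

  # heavily missing random table ends under 40%
  set.seed(23)
  vals3 <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12)
  vals3[runif(length(vals3)) < 0.6] <- NA
  out3 <- reduce_missingness(toy_traits(vals3, "P"), target_frac = 0.40)
  m <- as.matrix(out3[setdiff(names(out3), c("id", "population"))])
  expect_lt(mean(is.na(m)), 0.40)
  expect_gt(nrow(m), 0)

  expect_error(reduce_missingness(toy_traits(matrix(NA_real_, 2, 2), "P"), 0.01),
               "unreachable")
})

test_that("dichotomization and individual count follow the scoring rules", {
  t <- data.frame(id = c("a", "b", "c"), population = "P",
                  cusp__L = c(3, 0, NA), cusp__R = c(0, NA, NA))
  thr <- data.frame(trait = "cusp", min_grade_present = 2)
  b <- dichotomize(t, thr)
  expect_equal(b$cusp__L, c(1, 0, NA))
  expect_equal(b$cusp__R, c(0, NA, NA))

  ic <- individual_count(b)
  expect_equal(ic$cusp, c(1, 0, NA))  # max side; one-sided kept; both-missing NA

  expect_error(dichotomize(t, data.frame(trait = "other", min_grade_present = 1)),
               "no dichotomization threshold")

  # dichotomize-then-count equals count-type max on per-side dichotomies
  t2 <- data.frame(id = "x", population = "P", shovel__L = 4, shovel__R = 1)
  thr2 <- data.frame(trait = "shovel", min_grade_present = 3)
  expect_equal(individual_count(dichotomize(t2, thr2))$shovel, 1)
})
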