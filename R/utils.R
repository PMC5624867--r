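# Internal helpers shared across modules.

#' @importFrom stats cor dnorm qnorm rnorm runif rbinom rmultinom sd cov
#'   complete.cases cmdscale prcomp setNames as.dist
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the upper off-diagonal elements of a square matrix
#'
#' Vectorizes the strict upper triangle column-by-column, so symmetric
#' matrices contribute each unordered pair exactly once.
#'
#' @param m square numeric matrix
#' @return numeric vector of length `G*(G-1)/2`
#' @keywords internal
off_diagonal <- function(m) {
  m[upper.tri(m)]
}

# Draw n iid vectors from N(0, sigma); sigma may be rank deficient (the
# centroid constraint makes kinship matrices singular), so the square root
# is taken by eigendecomposition with small negative eigenvalues clipped.
rmvnorm_psd <- function(n, sigma) {
  eg <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  rt <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
  z <- matrix(rnorm(n * nrow(sigma)), nrow = n)
  z %*% rt
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

# Deterministic per-stage seed streams derived from one pipeline seed.
# Offsets keep derived seeds well inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, outlier = 23L, impute = 37L, mantel = 53L,
               dow = 71L, ld = 89L, pipeline = 101L)
  off <- offsets[[stage]] %||% 997L
  as.integer((as.numeric(seed) * 131 + off) %% 2000000011)
}
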