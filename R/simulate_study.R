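# One call that emulates the full study design: a single ground-truth
# kinship structure, four data types derived from it, and a fixture
# directory that run_pipeline() consumes directly.

#' Random centroid-constrained target R-matrix with a given Fst
#'
#' Draws a random Wishart-style PSD matrix, projects it onto the centroid
#' constraint of the panel and rescales it so the weighted mean diagonal
#' equals `fst`. Unlike the island model ([island_rmatrix()]), the
#' off-diagonals vary, which is what matrix-comparison tests need.
#'
#' @param panel a [population_panel()]
#' @param fst target Fst
#' @param seed integer seed
#' @return a [kinship_matrix()] with `source = "target"` and `fst` equal
#'   to the target
#' @export
random_rmatrix <- function(panel, fst, seed = NULL) {
  assert_panel(panel)
  stopifnot(fst > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  G <- length(panel$labels)
  A <- matrix(rnorm(G * G), G, G)
  raw <- tcrossprod(A) / G
  r <- centroid_project(raw, panel$w)
  f0 <- sum(panel$w * diag(r))
  kinship_matrix(r * fst / f0, panel, source = "target")
}

#' Clustered target R-matrix (regional structure)
#'
#' Builds a ground-truth kinship matrix in which populations fall into
#' regional clusters: populations of a cluster share a fraction
#' `cluster_share` of their drift variance, the rest is
#' population-specific. After centroid projection, within-cluster pairs
#' get positive and between-cluster pairs negative kinship, mimicking the
#' dominant continental clustering of worldwide samples. This is the
#' default ground truth for recovery experiments: an unstructured island
#' model has constant (hence uninformative) off-diagonals, while a
#' clustered target gives the off-diagonal spread that correlation-based
#' checks need.
#'
#' @param panel a [population_panel()]
#' @param fst target Fst
#' @param n_clusters number of regional clusters (default 2); populations
#'   are assigned in contiguous blocks unless `clusters` is given
#' @param cluster_share fraction of drift variance shared within a
#'   cluster (default 0.7)
#' @param clusters optional explicit cluster assignment (integer vector)
#' @return a [kinship_matrix()] with `source = "target"`
#' @export
clustered_rmatrix <- function(panel, fst, n_clusters = 2,
                              cluster_share = 0.7, clusters = NULL) {
  assert_panel(panel)
  stopifnot(fst > 0, cluster_share >= 0, cluster_share < 1)
  G <- length(panel$labels)
  cl <- clusters %||% rep(seq_len(n_clusters), each = ceiling(G / n_clusters),
                          length.out = G)
  Z <- 1 * outer(cl, cl, `==`)
  cov <- cluster_share * Z + (1 - cluster_share) * diag(G)
  r <- centroid_project(cov, panel$w)
  kinship_matrix(r * fst / sum(panel$w * diag(r)), panel, source = "target")
}

#' Simulate a complete comparative biodistance study
#'
#' Generates one ground-truth kinship matrix for `G` populations (with
#' heterogeneous effective sizes driving the weights) and derives from it,
#' with independent noise: biallelic SNP frequencies, multiallelic STR
#' frequencies for a population subset, individual-level metric traits
#' and binary threshold traits, plus an LD genotype panel with a known
#' long-term Ne. All input TSVs, a YAML pipeline config and the ground
#' truth are written to `dir`, ready for [run_pipeline()].
#'
#' @param dir output directory
#' @param G number of populations (default 19)
#' @param str_subset number of populations with STR data (default 13)
#' @param fst true Fst of the target matrix (default 0.10)
#' @param h2 heritability used for both phenotypic generators (default
#'   0.5)
#' @param n_per_pop individuals per population for the trait tables
#'   (default 50)
#' @param snp_loci,str_loci,str_alleles marker counts (defaults 1778,
#'   645, 8 — SNP panel, STR panel, alleles per STR)
#' @param t_metric,t_binary trait counts (defaults 28, 15)
#' @param ne_ld true effective size for the LD panel (default 1000);
#'   set to NULL to skip LD genotypes
#' @param ld_pairs number of simulated SNP pairs (default 500)
#' @param ld_n diploid individuals in the LD panel (default 200)
#' @param seed integer seed; all generator streams derive from it
#' @return (invisibly) list with `config_path`, the `truth`
#'   [kinship_matrix()] and the panel
#' @export
simulate_study <- function(dir, G = 19, str_subset = 13, fst = 0.10,
                           h2 = 0.5, n_per_pop = 50,
                           snp_loci = 1778, str_loci = 645, str_alleles = 8,
                           t_metric = 28, t_binary = 15,
                           ne_ld = 1000, ld_pairs = 500, ld_n = 200,
                           seed = 1L) {
  stopifnot(str_subset <= G)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base_seed <- derive_seed(seed, "simulate")
  withr::local_seed(base_seed)
  labels <- sprintf("POP%02d", seq_len(G))
  ne <- round(exp(rnorm(G, log(1000), 0.5)))
  panel <- population_panel(labels, n = n_per_pop, ne = ne)
  truth <- clustered_rmatrix(panel, fst)

  pf <- file.path(dir, "panel.tsv")
  write_tsv(as.data.frame(panel), pf)

  snp <- simulate_snp_frequencies(truth, snp_loci, panel, seed = base_seed + 2L)
  write_frequency_table(snp, file.path(dir, "snp_freq.tsv"))

  sub_labels <- labels[seq_len(str_subset)]
  sub_panel <- subset_panel(panel, sub_labels)
  sub_truth <- subset_kinship(truth, sub_labels)
  str_f <- simulate_str_frequencies(sub_truth, str_loci, str_alleles,
                                    sub_panel, seed = base_seed + 3L)
  write_frequency_table(str_f, file.path(dir, "str_freq.tsv"))

  met <- simulate_metric_traits(truth, h2, t_metric, panel,
                                seed = base_seed + 4L)
  # onto a positive crown-diameter-like scale the shape transform accepts
  write_tsv(met, file.path(dir, "metric.tsv"))

  thr <- qnorm(runif(t_binary, 0.2, 0.8))
  bin <- simulate_binary_traits(truth, h2, t_binary, thr, panel,
                                seed = base_seed + 5L)
  write_tsv(bin, file.path(dir, "binary.tsv"))

  ld_geno_path <- ld_map_path <- NULL
  if (!is.null(ne_ld)) {
    dists <- runif(ld_pairs, 0.005, 0.25)
    gm <- simulate_ld_genotypes(ne_ld, dists, ld_n, seed = base_seed + 6L)
    ld_geno_path <- file.path(dir, "ld_geno.tsv")
    ld_map_path <- file.path(dir, "ld_map.tsv")
    gdf <- data.frame(id = rownames(gm$dosage), population = gm$population,
                      as.data.frame(gm$dosage, check.names = FALSE),
                      check.names = FALSE)
    write_tsv(gdf, ld_geno_path)
    write_tsv(gm$map, ld_map_path)
  }

  write_matrix_tsv(truth$r, file.path(dir, "r_true.tsv"))
  yaml::write_yaml(
    list(fst_true = fst, h2 = h2, G = G, str_subset = str_subset,
         ne_ld = ne_ld, seed = seed),
    file.path(dir, "truth.yaml")
  )

  cfg <- list(panel = "panel.tsv", snp_freq = "snp_freq.tsv",
              str_freq = "str_freq.tsv", metric = "metric.tsv",
              binary = "binary.tsv", out_dir = file.path(dir, "results"),
              h2 = h2, seed = seed)
  if (!is.null(ld_geno_path)) {
    cfg$ld_geno <- "ld_geno.tsv"
    cfg$ld_map <- "ld_map.tsv"
  }
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config_path)
  invisible(list(config_path = config_path, truth = truth, panel = panel))
}
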