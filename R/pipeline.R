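# Pipeline configuration and the end-to-end driver: read inputs, clean,
# estimate one R-matrix per data type, compare them, and write every
# result (plus a log of filter counts and seeds) as TSV.

#' Pipeline configuration
#'
#' Collects paths and analysis parameters for [run_pipeline()]. Any subset
#' of the data types may be supplied, but at least one genetic
#' (`snp_freq`/`str_freq`) and one phenotypic (`metric`/`binary`) input is
#' required.
#'
#' @param panel path to the population panel TSV (required)
#' @param snp_freq,str_freq paths to allele-frequency TSVs (optional)
#' @param metric,binary paths to trait-table TSVs (optional)
#' @param ld_geno,ld_map paths to genotype + map TSVs for the LD-based Ne
#'   profile (optional)
#' @param out_dir output directory (created if needed)
#' @param h2 heritability for the phenotypic R-matrices (default 0.5)
#' @param permutations permutations for Mantel / Dow-Cheverud tests
#'   (default 10000)
#' @param alpha family-wise significance level (default 0.05)
#' @param bonferroni_m number of comparisons the alpha is split over;
#'   default = number of genetic-vs-phenotypic Mantel tests performed
#' @param ld_min_cM,ld_max_cM LD window bounds in cM (defaults 0.005,
#'   0.25)
#' @param n_classes number of overlapping LD distance classes (default
#'   250)
#' @param knn_k neighbors for metric imputation (default 5)
#' @param max_missing_frac per-individual missingness cutoff for metric
#'   tables (default 0.5)
#' @param target_missing_frac overall missingness target for binary
#'   tables (default 0.40)
#' @param seed integer seed; all stage-specific random streams are
#'   derived deterministically from it
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(panel, snp_freq = NULL, str_freq = NULL,
                            metric = NULL, binary = NULL,
                            ld_geno = NULL, ld_map = NULL,
                            out_dir = "biodistr_out",
                            h2 = 0.5, permutations = 10000, alpha = 0.05,
                            bonferroni_m = NULL,
                            ld_min_cM = 0.005, ld_max_cM = 0.25,
                            n_classes = 250, knn_k = 5,
                            max_missing_frac = 0.5,
                            target_missing_frac = 0.40, seed = 1L) {
  cfg <- list(panel = panel, snp_freq = snp_freq, str_freq = str_freq,
              metric = metric, binary = binary,
              ld_geno = ld_geno, ld_map = ld_map, out_dir = out_dir,
              h2 = h2, permutations = permutations, alpha = alpha,
              bonferroni_m = bonferroni_m,
              ld_min_cM = ld_min_cM, ld_max_cM = ld_max_cM,
              n_classes = n_classes, knn_k = knn_k,
              max_missing_frac = max_missing_frac,
              target_missing_frac = target_missing_frac, seed = seed)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$panel)) stopf("config: a panel path is required")
  if (!(cfg$h2 > 0 && cfg$h2 <= 1)) stopf("config: h2 must lie in (0, 1]")
  if (!is.numeric(cfg$permutations) || cfg$permutations < 1)
    stopf("config: permutations must be >= 1")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stopf("config: alpha must lie in (0, 1)")
  if (cfg$ld_min_cM >= cfg$ld_max_cM)
    stopf("config: ld_min_cM must be below ld_max_cM")
  if (!is.null(cfg$bonferroni_m) && cfg$bonferroni_m < 1)
    stopf("config: bonferroni_m must be >= 1")
  has_genetic <- !is.null(cfg$snp_freq) || !is.null(cfg$str_freq)
  has_pheno <- !is.null(cfg$metric) || !is.null(cfg$binary)
  if (!has_genetic || !has_pheno)
    stopf("config: need at least one genetic and one phenotypic input")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments
#' @return a validated `pipeline_config`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (key in c("panel", "snp_freq", "str_freq", "metric", "binary",
                "ld_geno", "ld_map"))
    raw[[key]] <- resolve(raw[[key]])
  do.call(pipeline_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full biodistance pipeline
#'
#' Reads every configured input, applies the cleaning steps, estimates one
#' R-matrix per data type, derives distances and PCoA coordinates, runs
#' all pairwise Mantel tests (genetic vs phenotypic, at the
#' Bonferroni-adjusted level) plus Dow-Cheverud tests of which phenotypic
#' matrix better tracks each genetic one, and writes everything under
#' `out_dir`:
#' `rmatrix_<type>.tsv`, `distance_<type>.tsv`, `pcoa_<type>.tsv`,
#' `ne_profile.tsv` (when LD input is given), `comparisons.tsv` and
#' `pipeline_log.txt`. Outputs are a pure function of (inputs, config,
#' seed). When SNP and STR panels differ, matrices are re-projected onto
#' the common subset for each comparison.
#'
#' @param config a `pipeline_config` or path to a YAML config file
#' @return (invisibly) a list with the estimated matrices, comparison
#'   table, Ne profile and output paths
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %s", cfg$seed),
                 sprintf("h2: %g", cfg$h2),
                 sprintf("permutations: %d", as.integer(cfg$permutations)))
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  note <- function(expr) {
    withCallingHandlers(expr, message = function(m) {
      logf("%s", sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  panel <- with_stage("panel", read_panel(cfg$panel))
  logf("panel: %d populations", length(panel$labels))

  # Ne profile (reported; the panel's ne column drives the weights)
  ne_prof <- NULL
  if (!is.null(cfg$ld_geno)) {
    ne_prof <- with_stage("ne_ld", {
      gm <- read_genotypes(cfg$ld_geno, cfg$ld_map)
      gm <- note(filter_strand_ambiguous(gm))
      pr <- pairwise_r2(gm, cfg$ld_min_cM, cfg$ld_max_cM)
      logf("ld: %d marker pairs", nrow(pr))
      estimate_ne(pr, n_individuals = nrow(gm$dosage),
                  n_classes = cfg$n_classes,
                  min_cM = cfg$ld_min_cM, max_cM = cfg$ld_max_cM)
    })
    write_tsv(ne_prof$classes, file.path(cfg$out_dir, "ne_profile.tsv"))
    logf("ne_longterm: %.6g", ne_prof$ne_longterm)
  }

  kin <- list()
  if (!is.null(cfg$snp_freq)) {
    kin$snp <- with_stage("rmatrix_snp", {
      f <- read_frequency_table(cfg$snp_freq, panel = panel)
      note(allele_rmatrix(f, panel))
    })
  }
  if (!is.null(cfg$str_freq)) {
    kin$str <- with_stage("rmatrix_str", {
      f <- read_frequency_table(cfg$str_freq)
      sub <- subset_panel(panel, unique(f$population))
      note(allele_rmatrix(frequency_table(as.data.frame(f), sub), sub))
    })
  }
  if (!is.null(cfg$metric)) {
    kin$metric <- with_stage("rmatrix_metric", {
      t <- read_trait_table(cfg$metric)
      t <- note(drop_sparse_individuals(t, cfg$max_missing_frac))
      if (anyNA(trait_values(t))) t <- knn_impute(t, k = cfg$knn_k)
      t <- geometric_mean_shape(t)
      sub <- subset_panel(panel, unique(t$population))
      metric_rmatrix(t, sub, h2 = cfg$h2)
    })
  }
  if (!is.null(cfg$binary)) {
    kin$threshold <- with_stage("rmatrix_threshold", {
      b <- read_trait_table(cfg$binary)
      b <- reduce_missingness(b, cfg$target_missing_frac)
      logf("binary: %d individuals x %d traits after missingness reduction",
           nrow(b), length(trait_columns(b)))
      sub <- subset_panel(panel, unique(b$population))
      threshold_rmatrix(b, sub, h2 = cfg$h2)
    })
  }

  for (nm in names(kin)) {
    k <- kin[[nm]]
    write_matrix_tsv(k$r, file.path(cfg$out_dir, sprintf("rmatrix_%s.tsv", nm)))
    d <- note(rmatrix_to_distance(k))
    write_matrix_tsv(d$d2, file.path(cfg$out_dir, sprintf("distance_%s.tsv", nm)))
    if (length(k$panel$labels) >= 3) {
      pc <- note(pcoa(d))
      co <- data.frame(population = rownames(pc$coordinates),
                       pc$coordinates, check.names = FALSE)
      write_tsv(co, file.path(cfg$out_dir, sprintf("pcoa_%s.tsv", nm)))
    }
    logf("rmatrix_%s: G = %d, Fst = %.6g", nm, length(k$panel$labels), k$fst)
  }

  genetic <- intersect(names(kin), c("snp", "str"))
  pheno <- intersect(names(kin), c("metric", "threshold"))
  align <- function(k, labels) {
    if (identical(k$panel$labels, labels)) k else subset_kinship(k, labels)
  }
  comp_rows <- list()
  # each genetic outcome is tested against m phenotypic matrices; that is
  # the comparison family the alpha is split over (0.025 when both dental
  # data types are present)
  alpha_adj <- bonferroni(cfg$alpha, cfg$bonferroni_m %||% max(length(pheno), 1))
  ci <- 0L
  for (g in genetic) for (p in pheno) {
    common <- intersect(kin[[g]]$panel$labels, kin[[p]]$panel$labels)
    ka <- align(kin[[g]], common); kp <- align(kin[[p]], common)
    ci <- ci + 1L
    mt <- mantel(kp, ka, permutations = cfg$permutations,
                 seed = derive_seed(cfg$seed, "mantel") + ci)
    comp_rows[[length(comp_rows) + 1L]] <- data.frame(
      test = "mantel", pair = sprintf("%s~%s", p, g),
      statistic = mt$r, p = mt$p, permutations = mt$permutations,
      alpha_adjusted = alpha_adj, significant = mt$p < alpha_adj,
      stringsAsFactors = FALSE
    )
  }
  if (length(pheno) == 2) {
    for (g in genetic) {
      common <- Reduce(intersect, lapply(kin[c(pheno, g)], function(k) k$panel$labels))
      dc <- dow_cheverud(align(kin$metric, common), align(kin$threshold, common),
                         align(kin[[g]], common),
                         permutations = cfg$permutations,
                         seed = derive_seed(cfg$seed, "dow") + match(g, genetic))
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        test = "dow_cheverud", pair = sprintf("metric-threshold~%s", g),
        statistic = dc$statistic, p = dc$p, permutations = dc$permutations,
        alpha_adjusted = cfg$alpha, significant = dc$p < cfg$alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  comparisons <- do.call(rbind, comp_rows)
  write_tsv(comparisons, file.path(cfg$out_dir, "comparisons.tsv"))

  writeLines(log_lines, file.path(cfg$out_dir, "pipeline_log.txt"))
  invisible(list(kinship = kin, comparisons = comparisons, ne = ne_prof,
                 panel = panel, out_dir = cfg$out_dir))
}
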