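# Readers and writers. One dialect everywhere: TSV with a header row,
# UTF-8, "." decimal point, NA for missing values.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = "NA")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stopf("%s file %s is missing column(s): %s", what, path,
          paste(miss, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.10g", x)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Allele-frequency table
#'
#' Long-format allele frequencies: one row per (population, locus, allele)
#' with the observed frequency and the number of individuals typed. Within
#' each (population, locus) the frequencies must sum to 1; sums off by at
#' most 1e-3 are renormalized with a warning, larger discrepancies are
#' errors.
#'
#' @param df data frame with columns `population`, `locus`, `allele`,
#'   `frequency`, `n_obs`
#' @param panel optional [population_panel()] fixing population order; by
#'   default order of first appearance is used
#' @return a `frequency_table` (a validated data frame)
#' @export
frequency_table <- function(df, panel = NULL) {
  req <- c("population", "locus", "allele", "frequency", "n_obs")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stopf("frequency table is missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[req]
  df$population <- as.character(df$population)
  df$locus <- as.character(df$locus)
  df$allele <- as.character(df$allele)
  if (any(!is.finite(df$frequency)) || any(df$frequency < 0 | df$frequency > 1))
    stopf("allele frequencies must lie in [0, 1]")
  key <- paste(df$population, df$locus, df$allele, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (population, locus, allele) row(s) in frequency table")
  grp <- paste(df$population, df$locus, sep = "\r")
  sums <- tapply(df$frequency, grp, sum)
  off <- abs(sums - 1)
  if (any(off > 1e-3))
    stopf("frequencies do not sum to 1 for %d (population, locus) group(s); worst |sum - 1| = %.3g",
          sum(off > 1e-3), max(off))
  if (any(off > 1e-6)) {
    warnf("renormalizing %d (population, locus) group(s) with |sum - 1| up to %.3g",
          sum(off > 1e-6), max(off))
    df$frequency <- df$frequency / as.numeric(sums[grp])
  }
  if (!is.null(panel)) {
    assert_panel(panel)
    extra <- setdiff(unique(df$population), panel$labels)
    if (length(extra) > 0)
      stopf("frequency table has population(s) not in panel: %s",
            paste(extra, collapse = ", "))
    df$population <- factor(df$population, levels = panel$labels)
    df <- df[order(df$population, df$locus, df$allele), ]
    df$population <- as.character(df$population)
  }
  rownames(df) <- NULL
  class(df) <- c("frequency_table", "data.frame")
  df
}

#' Read an allele-frequency table from TSV
#'
#' @param path TSV file with columns `population`, `locus`, `allele`,
#'   `frequency`, `n_obs`
#' @inheritParams frequency_table
#' @return a [frequency_table()]
#' @export
read_frequency_table <- function(path, panel = NULL) {
  df <- read_tsv_checked(path, c("population", "locus", "allele", "frequency", "n_obs"),
                         "frequency table")
  frequency_table(df, panel = panel)
}

#' Write an allele-frequency table to TSV
#'
#' Values are formatted with 10 significant digits so a write/read
#' round-trip reproduces the table.
#'
#' @param f a [frequency_table()]
#' @param path output TSV path
#' @export
write_frequency_table <- function(f, path) {
  write_tsv(as.data.frame(f), path)
}

#' Genotype dosage matrix with a genetic map
#'
#' @param dosage individuals x markers numeric matrix with entries in
#'   \{0, 1, 2, NA\} (rownames = individual ids, colnames = marker ids)
#' @param map data frame with columns `marker`, `chromosome`,
#'   `position_cM`, `allele1`, `allele2`; markers are reordered to map order
#' @param population character vector of population labels, one per
#'   individual
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosage, map, population) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stopf("dosages must be 0, 1, 2 or NA")
  req <- c("marker", "chromosome", "position_cM", "allele1", "allele2")
  miss <- setdiff(req, names(map))
  if (length(miss) > 0)
    stopf("genetic map is missing column(s): %s", paste(miss, collapse = ", "))
  map$marker <- as.character(map$marker)
  unmapped <- setdiff(colnames(dosage), map$marker)
  if (length(unmapped) > 0)
    stopf("marker(s) absent from map: %s", paste(unmapped, collapse = ", "))
  map <- map[map$marker %in% colnames(dosage), req]
  dosage <- dosage[, map$marker, drop = FALSE]
  if (length(population) != nrow(dosage))
    stopf("need one population label per individual")
  rownames(map) <- NULL
  structure(
    list(dosage = dosage, map = map, population = as.character(population)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d markers, %d population(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$population))))
  invisible(x)
}

#' Read genotypes and a genetic map from TSV
#'
#' The genotype file holds one row per individual with an `id` column, a
#' `population` column and one dosage column per marker (values 0/1/2/NA).
#' The map file carries `marker`, `chromosome`, `position_cM`, `allele1`,
#' `allele2`; markers are aligned to map order regardless of column order
#' in the genotype file.
#'
#' @param geno_path genotype TSV
#' @param map_path map TSV
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(geno_path, map_path) {
  g <- read_tsv_checked(geno_path, c("id", "population"), "genotype")
  map <- read_tsv_checked(map_path,
                          c("marker", "chromosome", "position_cM", "allele1", "allele2"),
                          "genetic map")
  markers <- setdiff(names(g), c("id", "population"))
  if (length(markers) == 0) stopf("genotype file has no marker columns")
  dosage <- as.matrix(g[markers])
  rownames(dosage) <- as.character(g$id)
  genotype_matrix(dosage, map, g$population)
}

#' Write a labeled square matrix to TSV
#'
#' First column `population` carries row labels; remaining columns are the
#' matrix entries at 10 significant digits.
#'
#' @param m square numeric matrix with dimnames
#' @param path output TSV path
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(population = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read a labeled square matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path
#' @return numeric matrix with dimnames
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_checked(path, "population", "matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$population
  m
}

#' Read a population panel from TSV
#'
#' Columns: `population`, `n`, optionally `ne` (all-NA `ne` is treated as
#' absent, giving uniform weights).
#'
#' @param path TSV path
#' @return a [population_panel()]
#' @export
read_panel <- function(path) {
  df <- read_tsv_checked(path, c("population", "n"), "panel")
  ne <- if ("ne" %in% names(df) && !all(is.na(df$ne))) df$ne else NULL
  population_panel(df$population, df$n, ne = ne)
}

#' Read an individual-level trait table from TSV
#'
#' Expects an `id` column, a `population` column and one column per trait
#' variable. Used for metric (positive real), ordinal (integer grades) and
#' binary (0/1) tables alike; type checks are applied downstream by the
#' operations that consume each kind. When an `age` column is present,
#' individuals older than `max_age` are dropped (temporal-bias filter);
#' the column is then removed. A `sex` column is carried along as metadata.
#'
#' @param path TSV path
#' @param max_age upper age bound in years applied when an `age` column
#'   exists (default 2000)
#' @return data frame with attributes preserved; trait columns are
#'   everything except `id`, `population`, `sex`
#' @export
read_trait_table <- function(path, max_age = 2000) {
  df <- read_tsv_checked(path, c("id", "population"), "trait table")
  df$id <- as.character(df$id)
  df$population <- as.character(df$population)
  if ("age" %in% names(df)) {
    keep <- is.na(df$age) | df$age <= max_age
    if (any(!keep))
      message(sprintf("read_trait_table: dropped %d individual(s) older than %g years",
                      sum(!keep), max_age))
    df <- df[keep, names(df) != "age", drop = FALSE]
  }
  if (anyDuplicated(df$id)) stopf("duplicate individual id(s) in %s", path)
  rownames(df) <- NULL
  df
}

trait_columns <- function(df) {
  setdiff(names(df), c("id", "population", "sex"))
}

trait_values <- function(df) {
  m <- as.matrix(df[trait_columns(df)])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}
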