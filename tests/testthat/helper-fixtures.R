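# Shared fixture builders. Everything is generated in code; no stored data.

toy_panel <- function(G = 2, n = 50, labels = NULL, ...) {
  population_panel(labels %||% sprintf("P%02d", seq_len(G)), n = n, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the 2-population, 1-locus frequency fixture used by the hand oracles
toy_freq <- function(panel = toy_panel()) {
  frequency_table(data.frame(
    population = rep(panel$labels, each = 2),
    locus = "L1",
    allele = c("a1", "a2", "a1", "a2"),
    frequency = c(0.6, 0.4, 0.4, 0.6),
    n_obs = 50
  ), panel)
}

# small metric trait table with explicit values
toy_traits <- function(values, pops, ids = NULL) {
  values <- as.matrix(values)
  df <- data.frame(
    id = ids %||% sprintf("i%02d", seq_len(nrow(values))),
    population = pops,
    stringsAsFactors = FALSE
  )
  df[paste0("V", seq_len(ncol(values)))] <- values
  df
}

toy_genotypes <- function(dosage, chromosomes, positions_cM,
                          allele1 = "A", allele2 = "G",
                          population = NULL) {
  dosage <- as.matrix(dosage)
  colnames(dosage) <- colnames(dosage) %||% sprintf("m%02d", seq_len(ncol(dosage)))
  map <- data.frame(marker = colnames(dosage),
                    chromosome = rep_len(chromosomes, ncol(dosage)),
                    position_cM = positions_cM,
                    allele1 = rep_len(allele1, ncol(dosage)),
                    allele2 = rep_len(allele2, ncol(dosage)),
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, map, population %||% rep("A", nrow(dosage)))
}

offdiag_cor <- function(a, b) {
  ma <- if (inherits(a, "kinship_matrix")) a$r else a
  mb <- if (inherits(b, "kinship_matrix")) b$r else b
  cor(ma[upper.tri(ma)], mb[upper.tri(mb)])
}
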