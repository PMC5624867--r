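# biodistr

Comparative biodistance analysis in R: do dental phenotypes and neutral
genetic markers tell the same story about how human populations are
related?

`biodistr` estimates population kinship (R) matrices from three kinds of
data — allele frequencies (SNPs or STRs), individual-level metric traits
under the Relethford–Blangero quantitative-genetic model, and binary
non-metric traits under the liability threshold model — weights them by
LD-derived effective population sizes, and compares the resulting
kinship structures with permutation-based Mantel and Dow–Cheverud tests
and principal coordinates analysis. It is aimed at dental
anthropologists and population geneticists who need affinity estimates
from different data types on one quantitative footing.

## The model in brief

For `G` populations with weights `w_i` (uniform or `∝ N_e`), the
R-matrix is the standardized covariance of population deviations from
the weighted regional centroid. Its off-diagonal entries are average
kinship coefficients `r_ij` (positive: more similar than the regional
average), its diagonal gives `Fst = Σ_i w_i r_ii`, and squared
population distances follow as `d²_ij = r_ii + r_jj − 2 r_ij`.

* **Allele frequencies** (Harpending–Ward):
  `r_ij = mean over (locus, allele) of (p_i − p̄)(p_j − p̄) / (p̄(1 − p̄))`.
* **Metric traits** (Relethford–Blangero): codivergence
  `c_ij = (x̄_i − x̄)' (h² W)⁻¹ (x̄_j − x̄) / t` with pooled within-group
  covariance `W`, then `r_ij = c_ij (1 − Fst)/2`, `Fst = S/(2+S)`,
  `S = Σ w_i c_ii`, with a small-sample diagonal correction `1/(h² n_i)`.
* **Binary traits** (threshold model): trait frequencies map to mean
  liabilities `z = Φ⁻¹(f)`; the same codivergence machinery runs on `z`
  with delta-method variances as the diagonal correction.
* **Effective size from LD**: `N_e = (1/4c)(1/r² − 2)` per overlapping
  recombination distance class on [0.005, 0.25] cM, harmonic-mean
  long-term `N_e`.
* **Comparison**: Mantel correlation of off-diagonal `r_ij` with
  two-tailed permutation p (add-one correction), Dow–Cheverud tests of
  which phenotypic matrix better tracks a genetic one, Bonferroni
  control, PCoA of R-derived distances.

A synthetic-data module generates all data types from a known
ground-truth kinship matrix (correlated drift, trait means with
covariance `2R h²/(1 − Fst)`, thresholded liabilities, LD pairs with
`E[r²] = 1/(4N_e c + 2)`), so every estimator is validated by parameter
recovery in the test suite.

## Worked example

```r
library(biodistr)

panel <- population_panel(sprintf("POP%d", 1:8), n = 150,
                          ne = c(1200, 900, 1500, 700, 1100, 1300, 800, 1000))
truth <- clustered_rmatrix(panel, fst = 0.10)    # two regional clusters
snp <- simulate_snp_frequencies(truth, L = 2000, panel, seed = 42)
met <- simulate_metric_traits(truth, h2 = 0.5, t = 20, panel, seed = 43)

k_snp <- allele_rmatrix(snp, panel)
k_met <- metric_rmatrix(met, panel, h2 = 0.5)
k_snp
#> R-matrix (allele), 8 populations, Fst = 0.09453
#>         POP1    POP2    POP3    POP4    POP5    POP6    POP7    POP8
#> POP1  0.0903  0.0474  0.0459  0.0497 -0.0607 -0.0630 -0.0575 -0.0600
#> POP2  0.0474  0.0947  0.0459  0.0517 -0.0591 -0.0594 -0.0569 -0.0594
#> ...

mantel(k_met, k_snp, permutations = 10000, seed = 44)
#> Mantel: r = 0.9426, two-tailed p = 0.0123 (10000 permutations)

pcoa(rmatrix_to_distance(k_snp))
#> PCoA: 7 axes; first axes explain 64.0%, 6.3%, 6.2% of positive eigenvalue mass
```

The estimated Fst (0.095) recovers the generator's 0.10 up to boundary
clipping; the two-cluster structure shows up as the positive
within-cluster / negative between-cluster kinship blocks and as one
dominant PCoA axis. The Mantel correlation between the metric-trait and
SNP kinship matrices is strong and significant at the Bonferroni level
0.025 — the dental phenotypes track the neutral genetic structure they
were generated to share.

A full pipeline (reading TSV inputs, preprocessing, all matrices, Ne
profile, comparison table, PCoA coordinates, log) runs from a YAML
config via `run_pipeline()`; `simulate_study()` writes a complete
synthetic input bundle for it. See the vignette
(`vignettes/biodistance-methods.Rmd`) for models, parameter defaults
and design decisions.

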