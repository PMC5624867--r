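---
title: "Kinship matrices from genetic markers and dental phenotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship matrices from genetic markers and dental phenotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodistr)
```

## The problem

Biodistance analysis asks whether the affinity structure among a set of
populations, estimated independently from different data types — here
neutral genetic markers (SNP and STR allele frequencies) and dental
phenotypes (metric crown diameters and binary non-metric crown traits) —
tells the same story. The package estimates one population kinship
matrix per data type, places all of them in the same quantitative
framework, and compares them with permutation tests. Because the data
types come from different individuals and even different sources, the
comparison has to run through a population-level summary; the R-matrix
is that summary.

## The R-matrix

For `G` populations with normalized weights `w` (uniform, or
proportional to effective population sizes), the R-matrix `R = (r_ij)`
is the standardized covariance of population deviations from the
weighted regional centroid. Off-diagonal `r_ij` is the average kinship
between populations `i` and `j`: positive when they are more similar
than the regional average, negative when more distinct. Diagonal `r_ii`
measures the population's own divergence from the centroid, and

    Fst = sum_i w_i r_ii

is the among-population fraction of variance. Every R-matrix in the
package satisfies the centroid constraint `sum_j w_j r_ij = 0` to
machine precision, is symmetric, and carries its panel so that rows can
never silently fall out of alignment between data types. Squared
population distances follow as `d2_ij = r_ii + r_jj - 2 r_ij`.

### From allele frequencies

For locus `l`, allele `a`, population frequency `p_ila` and weighted
centroid frequency `pbar_la`,

    r_ij = mean over (l, a) of
           (p_ila - pbar_la)(p_jla - pbar_la) / (pbar_la (1 - pbar_la))

averaged over every allele column that is polymorphic at the centroid.
Averaging over each allele of every locus (rather than per-locus
normalization) treats biallelic and multiallelic input uniformly: a
biallelic locus contributes its two — algebraically identical — allele
terms, leaving the mean unchanged. Monomorphic-at-centroid alleles are
skipped and counted, not errors, because population subsets can fix
alleles. No small-sample correction is applied to frequency-based
matrices; sample sizes are retained for diagnostics.

### From metric traits

The quantitative model assumes all traits share a scalar heritability
`h2`, so the additive genetic covariance within groups is `G_W = h2 W`
with `W` the pooled within-group phenotypic covariance (divisor
`N - G`). With population means `xbar_i` and weighted grand mean `xbar`,
the codivergence matrix is

    c_ij = (xbar_i - xbar)' G_W^{-1} (xbar_j - xbar) / t

over `t` traits. Codivergence relates to kinship through
`r_ij = c_ij (1 - Fst) / 2`, where Fst solves the fixed point
`Fst = (1 - Fst) S / 2` with `S = sum_i w_i c_ii`; the closed form is
`Fst = S / (2 + S)`. A damped iteration (step factor 1/2, so the affine
map contracts for any `S` in (-2, 6)) is kept purely as a verification
path. Because `c` is a quadratic form in `W^{-1}`, the estimate is
invariant to any affine transform of the traits applied consistently to
all individuals — measurement units and linear recombinations of
variables do not matter.

Sampling inflates the diagonal: an estimated mean based on `n_i`
individuals adds roughly `1/(h2 n_i)` to `c_ii` (per-trait sampling
variance `1/n_i` on the phenotypic scale, `1/(h2 n_i)` after the genetic
rescaling, averaged over traits). The bias correction subtracts exactly
that term. It is approximate — the refinement accounting for the
grand-mean's own sampling covariance (a factor of about `1 - w_i`) is
omitted — and its adequacy is established by simulation: at 25
individuals per population the corrected mean Fst estimate is
measurably closer to truth than the uncorrected one (part of the test
suite). Corrected diagonals may dip slightly below zero; they are kept
(preserving unbiasedness of Fst) and only clamped when converting to
distances.

### From binary traits

Binary crown traits are modeled as threshold characters: a trait is
present when an unobserved, normally distributed liability (unit
within-population SD, threshold fixed at 0) exceeds zero. A cell with
`x` of `n` scoreable individuals expressing the trait gives frequency
`f = x/n` — with the continuity correction `f = (x + 0.5)/(n + 1)`
applied only at the boundaries `x = 0` and `x = n`, the minimal
perturbation that keeps the transform finite — mean liability
`z = qnorm(f)` and delta-method variance `v = f(1 - f)/(n dnorm(z)^2)`.
Liabilities are treated as mutually independent with unit phenotypic
variance; tetrachoric correlation estimation is deliberately out of
scope, the standard simplification when individual-level multivariate
scoring is sparse. Codivergence is then

    c_ij = (1/t) sum_k (z_ik - zbar_k)(z_jk - zbar_k) / h2

with the delta-method variances `mean_k v_ik / h2` subtracted from the
diagonal as bias correction, and the same `S/(2+S)` conversion reused.
A global sign flip of the liabilities leaves the result unchanged. The
per-cell `n` adjusts automatically to missing scores, which is why the
estimator tolerates incomplete tables; the test suite verifies that
randomly masking 30% of scores moves Fst by less than 0.02 in the
recovery setting.

### Heritability

`h2 = 0.5` is the package default for both phenotypic estimators,
reflecting the approximate average of published twin and family
estimates for dental dimensions and crown traits. It is a scalar: trait
specific heritabilities and genetic correlations are not modeled.
Halving `h2` doubles every codivergence value, so misspecification
inflates or deflates Fst but moves all comparisons of matrix *structure*
much less.

## Effective population size from LD decay

Under drift-recombination equilibrium the expected squared correlation
between loci at recombination distance `c` Morgans is about
`1/(4 Ne c + 2)`. Inverting,

    Ne = (1/(4c)) (1/r2 - 2),

interpretable as the effective size `1/(2c)` generations ago. The
implementation: squared Pearson correlation of dosage vectors (a
composite, phase-free estimator — deterministic, no EM haplotyping) for
all same-chromosome pairs in `[0.005, 0.25)` cM; subtraction of
`1/(2n)` from each pair's r2 (the expectation under linkage equilibrium
with `2n` sampled chromosomes), applied per pair before binning, which
for equal-weight class means is arithmetically identical to adjusting
after; 250 class centers evenly spaced over the window, each class
collecting pairs within one center spacing (about 50% overlap with each
neighbor — the class geometry is configurable because only the count
and the overlap property are fixed by the recipe); and the long-term Ne
as the harmonic mean over classes with positive estimates, which
weights ancient bottlenecks the way long-term drift does. Classes with
no pairs or non-positive estimates are flagged and excluded. The cM to
Morgan conversion happens exactly once, inside the Ne formula. Pairs
closer than 0.005 cM are excluded because gene conversion and assay
artefacts dominate there.

## Comparing kinship structures

The Mantel statistic is the Pearson correlation of the
`G(G-1)/2` upper off-diagonal kinship coefficients (the upper triangle
once — symmetric inputs make this lossless). The null distribution
jointly permutes rows and columns of one matrix; the p-value is
two-tailed with the add-one correction `(hits + 1)/(B + 1)`, so `p` is
never 0 and the smallest attainable value is `1/(B + 1)`. The test
operates on kinship matrices directly (the quantities of scientific
interest); a distance-matrix entry point works identically. At least 4
populations are required — below that the permutation null is
degenerate.

The Dow-Cheverud test asks which of two predictor matrices tracks an
outcome matrix more strongly: standardize both predictors'
off-diagonals, correlate their difference with the outcome, and permute
the outcome for significance. Positive values mean the first predictor
correlates more strongly; swapping predictors flips the sign exactly.

Multiple comparisons are handled by Bonferroni division; the pipeline's
default family is the set of phenotypic matrices tested against each
genetic outcome (`alpha = 0.05/2 = 0.025` when both dental data types
are present). PCoA of the derived distances uses classical metric
scaling (Gower double-centering, delegated to `stats::cmdscale`);
negative eigenvalue mass — non-Euclidean residue, possible after bias
correction — is dropped and reported.

## Preprocessing decisions

* **Strand-ambiguity filter.** A/T and C/G markers are removed before
  analysis, as their strand cannot be resolved across merged panels.
* **PC outlier screen.** An individual is an outlier when a score on one
  of the first four principal components of the allele-indicator matrix
  lies more than six SDs from that component's mean; the rule uses
  absolute deviations and is therefore invariant to sign flips of the
  components.
* **Metric missingness.** Individuals missing strictly more than half
  their measurements are removed; the remainder is completed by kNN
  imputation with `k = 5` (the customary default of kNN imputation
  tools). The neighbor metric — Euclidean distance over variables
  observed in both individuals, on per-variable standardized values,
  divided by the number of shared variables — is a declared design
  choice pinned by a masking experiment in the test suite: on data with
  a shared size factor (as raw crown diameters have) kNN imputation
  beats grand-mean imputation in mean absolute error. Individuals
  sharing no observed variable are not eligible neighbors. Observed
  cells are never altered.
* **Size correction.** Raw diameters become shape variables by division
  with the individual's geometric mean; this removes gross size (and
  most sexual size dimorphism, which is why no sex stratification is
  applied anywhere — sex is carried as metadata only). The operation is
  idempotent and scale-invariant per individual.
* **Binary missingness.** A greedy loop removes whichever single
  variable or individual currently has the highest missing fraction
  until overall missingness falls below 40%, keeping dispersion
  estimates well-conditioned. Ties resolve variables before individuals,
  then lexicographically — an arbitrary but deterministic order.
* **Dichotomization and individual count.** Ordinal grades become
  presence/absence at per-trait thresholds supplied as data (thresholds
  are conventions of the scoring system, not constants of the method);
  bilateral traits are scored once per dentition using the side with the
  highest expression, ignoring a missing side.
* **Age filter.** When an age column exists, individuals older than
  2000 years are dropped at read time to avoid temporal bias; otherwise
  the filter is a no-op.

## The synthetic-data generator

Every estimator is validated by parameter recovery against a known
ground truth, since the data the methods are designed for are typically
restricted. The generator draws, for a panel with weights `w`, a target
kinship matrix `R_true` (any PSD matrix projected onto the centroid
constraint via `P = I - 1 w'`), then derives all data types from it with
independent noise:

* **SNP frequencies.** Centroid frequency uniform on (0.1, 0.9) per
  locus; population deviations multivariate normal with covariance
  `R_true pbar(1 - pbar)`; frequencies clipped to [0.01, 0.99]. Because
  `R_true w = 0`, the weighted deviation sum is zero almost surely, so
  the realized centroid equals the generator's and the estimator is
  exactly consistent — up to boundary clipping, which attenuates drift
  variance slightly (about -0.008 on an Fst of 0.10 under the default
  conditions; clip events are reported so self-checks can condition on
  them).
* **STR frequencies.** Centroid vectors are symmetric Dirichlet(2)
  draws over `A` alleles; deviations follow multiallelic drift with
  joint covariance `R_true (x) (diag(pbar) - pbar pbar')` — the same
  per-allele marginal variance as the SNP model, but with each
  population's deviations summing to zero across alleles so the simplex
  is respected by construction (independent per-allele deviations would
  be shrunk wholesale by the renormalization, destroying drift
  variance). The 0.005 frequency floor censors the drift of rare
  alleles, which visibly attenuates realized Fst at high allele counts
  (roughly 0.06 realized for a nominal 0.10 at `A = 8`); the test suite
  validates the estimator against a closed-form censored-normal oracle
  that predicts exactly this attenuation, and the kinship *structure*
  is still recovered with off-diagonal correlation above 0.99.
  Alternatives (angular transform, Gaussian copula with
  Balding-Nichols marginals) were evaluated and carry attenuations of
  their own from nonlinearity and centroid estimation, so the simpler
  Gaussian design was kept and its bias documented.
* **Metric traits.** Traits are independent with unit within-population
  phenotypic variance and additive variance `h2`; per trait, population
  genetic means are multivariate normal with covariance
  `2 R_true h2 / (1 - Fst_true)` — precisely the model under which the
  codivergence-to-kinship conversion is consistent, making recovery
  tests sharp rather than approximate. Individual values add standard
  normal noise and a +20 shift onto a positive, crown-diameter-like
  scale.
* **Binary traits.** Liabilities are built exactly like metric traits
  (population genetic mean plus standard normal within-population
  residual, total within-variance 1) and thresholded per trait;
  thresholds near 0 give frequencies near 1/2, extreme thresholds
  exercise the continuity correction.
* **LD genotype pairs.** Each SNP pair at distance `c` Morgans targets
  `rho2 = 1/(4 Ne c + 2)`; allele frequencies are uniform on (0.2, 0.8),
  the haplotype disequilibrium `D = sign sqrt(rho2 p(1-p)q(1-q))` must
  fit the feasible range (frequency draws that cannot accommodate it
  are resampled, with a bounded retry budget), `2n` haplotypes are
  drawn multinomially and paired at random into diploids. Pairs sit on
  distinct chromosomes so only intended pairs enter the analysis.

The default ground truth for recovery experiments is a two-cluster
regional structure (70% of drift variance shared within a cluster),
emulating the dominant continental clustering of worldwide samples. The
choice is forced in kind, if not in number, by the logic of the
recovery checks themselves: an island-model target has constant
off-diagonals, so off-diagonal correlation with an estimate is
undefined — recovering *structure* requires a target that has some. The
70% share gives an off-diagonal kinship spread comparable to the
diagonal's magnitude, as strongly structured global samples show.

What the generator does **not** emulate: linkage between trait loci and
markers, genetic correlations among traits, STR mutation processes
(stepwise mutation), SNP ascertainment bias, observer error in trait
scoring, and non-random missingness. Passing recovery tests therefore
demonstrates correctness of the estimators under their own model
assumptions, not robustness to every failure mode of real data.

## Problem sizes and reproducibility

The test suite runs recovery at the sizes the methods are designed for:
`G = 8` populations for single-estimator recovery (5000 SNP loci; 20
metric traits at 200 individuals per population; 15 binary traits at
150 per population; 2000 LD pairs at 200 individuals), 100 replicates
at 25 individuals per population for the bias-correction comparisons,
and a full study replica with `G = 19`, a 13-population STR subset,
1778 SNP loci, 645 STR loci, 28 metric and 15 binary traits at 10,000
permutations. Every random draw flows from a single integer seed;
stage-specific streams are derived deterministically from it, so
pipeline outputs are a pure function of inputs, configuration and seed.

## Known limitations

* The diagonal bias term `1/(h2 n_i)` omits the grand-mean covariance
  refinement; at very small `G` the correction is slightly conservative.
* Scalar heritability: no trait-specific `h2`, no estimation of `h2`
  from data.
* Liability independence: correlated trait batteries will overstate the
  effective trait count `t`.
* The LD-based Ne assumes unlinked pair layout and a closed population;
  migration and admixture bias it like any drift-based estimator.
* Frequency-floor censoring in the STR generator attenuates realized
  drift variance for rare alleles (documented above); estimates of
  multiallelic Fst from real data are not affected — this is purely a
  property of the synthetic generator at its boundary.
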