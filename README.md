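# EcoStates

Discovery of **cellular states** and multicellular **ecotypes** from
cell-type-specific expression profiles, with recovery in single-cell and
spatial transcriptomics data and the accompanying survival and
signaling statistics.

## What problem this solves, and for whom

Bulk tumor cohorts can be computationally deconvolved (e.g. with
CIBERSORTx HiRes) into one gene-by-sample expression matrix per cell
population. Two questions follow for anyone studying the tumor
microenvironment:

1. Within one cell type, how many transcriptionally distinct
   **cellular states** are there, and which samples carry which state?
2. Which states from *different* cell types co-occur across samples
   often enough to form a multicellular community — an **ecotype** —
   and do ecotypes stratify patient survival?

EcoStates implements the full post-deconvolution pipeline for these
questions, for computational biologists who have (or simulate)
cell-type-specific matrices. Deconvolution itself is not included; a
seeded synthetic-cohort generator plants known states, ecotypes and
survival structure so every stage can be validated against ground
truth without any external data.

## The model in brief

Per cell type, states are found by consensus non-negative matrix
factorization: X ≈ WH with W, H ≥ 0, run `n_runs` times from random
initialisations (multiplicative updates, Frobenius objective). Each run
labels sample *j* with argmax of H[, j]; the consensus matrix holds the
fraction of runs co-labelling each sample pair, and its **cophenetic
coefficient** (correlation between 1 − consensus and the average-linkage
dendrogram distances) scores the stability of each candidate rank k.
States keep ≥ 10 marker genes (2-fold basis dominance) and an adjusted
false-positive index (AFI) < 1, a permutation-based artifact score.

Ecotypes come from the binary matrix **A** (A[i, j] = 1 iff state i is
sample j's dominant state in its cell type): pairwise Jaccard indices
of state supports, hypergeometric significance with BH correction,
average-linkage clustering of 1 − J with the cluster number maximising
the mean silhouette width, and removal of clusters with ≤ 3 states.
Samples are assigned to ecotypes by Welch t-tests of member- versus
non-member-state abundances (BH within sample, q ≤ 0.25, plus
allocation to ≥ 1 member state). Recovery in single-cell/spatial data
uses marker scores against size-matched backgrounds, permutation
z-scores combined by Stouffer's method (Σz/√n), one-hot dominant states
per spot weighted by cell-type fractions, and 99th-percentile-scaled
spot ecotype abundances. Survival uses Kaplan–Meier curves and log-rank
tests; intercellular signaling uses one-sided Mann–Whitney tests on
ligand–receptor pairs.

See `vignettes/EcoStates-methods.Rmd` for assumptions, parameter
defaults and the design decisions taken where the method literature is
silent — including an analysis of why the conventional
"cophenetic closest to 0.97" rank rule cannot identify planted ranks in
clean simulations and the stability-based alternative the package
provides.

## Worked example

Simulate a 4-cell-type cohort of 120 samples with two planted ecotypes,
rediscover states and ecotypes, and test ecotype survival:

```r
library(EcoStates)

specs <- c(Fibroblasts = 2L, Epithelial = 2L, Tcells = 2L, Myeloid = 2L)
ecotypes <- list(
  c("Fibroblasts_S01", "Epithelial_S01", "Tcells_S01", "Myeloid_S01"),
  c("Fibroblasts_S02", "Epithelial_S02", "Tcells_S02", "Myeloid_S02"))
cohort <- generateCohort(specs, ecotypes, nSamples = 120, noiseSd = 0.1,
                         seed = 42, coocProb = 0.9)

res <- discoverStates(cohort@expression$Fibroblasts, kRange = 2:4,
                      nRuns = 20, seed = 1, preprocess = FALSE,
                      rankMethod = "stability")
round(res$cophenetics, 4)
#>      2      3      4
#> 1.0000 0.9969 0.9884
res$model
#> StateModel: Fibroblasts with 2 states
#>   retained: 2 / 2
#>   markers per state: 30, 31
```

The cophenetic trace is exactly 1 at the planted rank (k = 2) and drops
above it; both states survive the marker and AFI filters. Repeating per
cell type and clustering co-occurrence:

```r
models <- lapply(names(specs), function(ct)
  discoverStates(cohort@expression[[ct]], kRange = 2:4, nRuns = 20,
                 seed = 1, preprocess = FALSE,
                 rankMethod = "stability")$model)
eco <- discoverEcotypes(models)
eco$model
#> EcotypeModel: 2 ecotypes over 8 states
#>   assigned samples: 105 / 120
table(ecotypeAssignment(eco$model), useNA = "ifany")
#>   E1   E2 <NA>
#>   55   50   15
```

Both planted ecotypes are recovered (all 8 states correctly
partitioned); 105/120 samples pass the q ≤ 0.25 assignment rule, the
rest are reported unassigned. Attaching ecotype-dependent survival
(hazards 0.05 vs 0.4 per time unit) and testing:

```r
clin <- generateSurvivalTable(na.omit(ecotypeAssignment(eco$model)),
                              c(E1 = 0.05, E2 = 0.4),
                              censorRate = 0.02, horizon = 60, seed = 9)
logrankTest(clin)
#> statistic 46.8, p = 7.7e-12
```

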