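## Shared fixture builders. Everything is generated in code at test time;
## expensive planted-cohort pipelines are cached per session.

# Four-cell-type cohort with one k-state ecotype structure: ecotype e is
# {<ct>_S0e for every cell type}, so each ecotype has 4 member states.
ecoSpecs <- function(nEco, cellTypes = c("Fibroblasts", "Epithelial",
                                         "Tcells", "Myeloid")) {
  specs <- stats::setNames(rep(as.integer(nEco), length(cellTypes)),
                           cellTypes)
  eco <- lapply(seq_len(nEco), function(e)
    sprintf("%s_S%02d", cellTypes, e))
  list(celltypes = specs, ecotypes = eco)
}

# Run state discovery at the planted rank for every cell type of a
# cohort (rank selection is exercised by its own tests), then map each
# discovered state to its planted state by sample-label majority.
fitCohortStates <- function(cohort, nRuns = 20L, seed = 5L,
                            afiBackground = 10L) {
  specs <- vapply(cohort@truth$coefficients, nrow, integer(1))
  models <- list()
  stateMap <- character(0)   # discovered qualified name -> planted name
  for (ct in names(specs)) {
    X <- cohort@expression[[ct]]
    cr <- suppressWarnings(consensusNMF(X, specs[[ct]], nRuns, seed))
    m <- EcoStates:::stateModelFromConsensus(ct, cr)
    m@markers <- extractMarkerGenes(m)
    m@afi <- computeAFI(m, X, nBackground = afiBackground, seed = seed + 1L)
    m <- filterStates(m)
    models[[ct]] <- m
    tab <- table(sampleStates(m), cohort@truth$stateLabels[[ct]])
    mp <- apply(tab, 1L, which.max)
    for (i in seq_along(mp))
      stateMap[sprintf("%s_S%02d", ct, as.integer(rownames(tab)[i]))] <-
        sprintf("%s_S%02d", ct, mp[i])
  }
  list(models = models, stateMap = stateMap)
}

# Full planted-cohort pipeline: generate, fit states at planted ranks,
# discover ecotypes; returns everything needed for recovery scoring.
runPlantedPipeline <- function(nEco, noiseSd, nSamples = 300L, seed = 11L,
                               coocProb = 0.9) {
  es <- ecoSpecs(nEco)
  cohort <- generateCohort(es$celltypes, es$ecotypes, nSamples, noiseSd,
                           seed = seed, coocProb = coocProb)
  fit <- fitCohortStates(cohort, seed = seed + 1L)
  eco <- discoverEcotypes(fit$models)
  part <- ecotypePartition(eco$model)
  truthPart <- cohort@truth$ecotypePartition[fit$stateMap[names(part)]]
  asg <- ecotypeAssignment(eco$model)
  truthEco <- cohort@truth$sampleEcotype[names(asg)]
  assigned <- !is.na(asg)
  accAssigned <- if (any(assigned))
    sum(apply(table(asg[assigned], truthEco[assigned]), 1L, max)) /
      sum(assigned) else NA_real_
  accAll <- sum(apply(table(asg[assigned], truthEco[assigned]), 1L, max)) /
    length(asg)
  list(cohort = cohort, fit = fit, eco = eco,
       ari = bfARI(part, truthPart),
       accAssigned = accAssigned, accAll = accAll,
       assignedFrac = mean(assigned))
}

# Session cache for the expensive pipelines (shared between the ecotype
# unit tests and the acceptance tests).
.pipelineCache <- new.env(parent = emptyenv())
cachedPipeline <- function(nEco, noiseSd, ...) {
  key <- paste0("e", nEco, "_n", noiseSd)
  if (is.null(.pipelineCache[[key]]))
    .pipelineCache[[key]] <- runPlantedPipeline(nEco, noiseSd, ...)
  .pipelineCache[[key]]
}

# Qualified marker list from a cohort's planted basis matrices.
plantedMarkers <- function(truth, foldThreshold = 2) {
  out <- list()
  for (ct in names(truth$basis)) {
    mk <- extractMarkerGenes(truth$basis[[ct]], foldThreshold)
    names(mk) <- paste0(ct, "_", names(mk))
    out <- c(out, mk)
  }
  out
}
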