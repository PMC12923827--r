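## Synthetic-cohort generator: plants low-rank state structure per cell
## type, sample-level co-occurrence of states forming ecotypes,
## ecotype-dependent survival, and matching single-cell / spatial
## fixtures, so that every downstream stage can be verified against known
## ground truth.

# Planted coefficient margins: the dominant state's coefficient is at
# least 2.5x any other state's, so the "dominant state" of every sample
# is unambiguous under the 2-fold margin used throughout the pipeline.
.DOM_LO <- 1.0; .DOM_HI <- 1.2   # dominant coefficient range
.OFF_LO <- 0.05; .OFF_HI <- 0.40 # non-dominant coefficient range
.MARK_LO <- 0.8; .MARK_HI <- 1.2 # marker-block basis loadings
.BG_HI <- 0.10                   # background basis loadings

#' Generate one cell type's expression matrix with planted states
#'
#' Constructs X = W H + noise, truncated at zero: W carries one disjoint
#' high-loading marker block per state over a low background, every
#' column of H has a planted dominant state (coefficient at least 2.5x
#' any other), and the noise is i.i.d. Gaussian with standard deviation
#' \code{noiseSd}. The planted factors and labels are returned alongside
#' the expression object.
#'
#' @param nGenes,nSamples matrix dimensions; \code{nGenes} must be at
#'   least \code{kStates * markerBlock} and \code{nSamples} at least
#'   \code{3 * kStates} (unless explicit \code{stateLabels} are given).
#' @param kStates number of planted states (>= 2).
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param markerBlock marker genes per state.
#' @param seed RNG seed.
#' @param cellType name attached to the output.
#' @param stateLabels optional integer vector of planted dominant states
#'   (one per sample); balanced random labels are drawn when NULL.
#' @param sampleNames,genePrefix optional identifier overrides.
#' @return List with \code{expr} ([CellTypeExpression-class]), \code{W},
#'   \code{H}, \code{labels}.
#' @export
generateStateProfiles <- function(nGenes, nSamples, kStates, noiseSd,
                                  markerBlock = 20L, seed = 1L,
                                  cellType = "CellType",
                                  stateLabels = NULL, sampleNames = NULL,
                                  genePrefix = "g") {
  nGenes <- assertCount(nGenes, "nGenes")
  nSamples <- assertCount(nSamples, "nSamples")
  kStates <- assertCount(kStates, "kStates", min = 2L)
  markerBlock <- assertCount(markerBlock, "markerBlock")
  noiseSd <- assertScalar(noiseSd, "noiseSd", min = 0)
  if (nGenes < kStates * markerBlock)
    stop("'nGenes' must be at least kStates * markerBlock")
  if (is.null(stateLabels) && nSamples < 3L * kStates)
    stop("'nSamples' must be at least 3 * kStates")
  if (!is.null(stateLabels)) {
    stopifnot(length(stateLabels) == nSamples,
              all(stateLabels %in% seq_len(kStates)))
  }
  genes <- sprintf("%s%04d", genePrefix, seq_len(nGenes))
  if (is.null(sampleNames))
    sampleNames <- sprintf("Smp%04d", seq_len(nSamples))
  withSeed(seed, {
    if (is.null(stateLabels))
      stateLabels <- sample(rep_len(seq_len(kStates), nSamples))
    W <- matrix(stats::runif(nGenes * kStates, 0, .BG_HI), nGenes, kStates,
                dimnames = list(genes, stateNames(kStates)))
    for (s in seq_len(kStates)) {
      block <- ((s - 1L) * markerBlock + 1L):(s * markerBlock)
      W[block, s] <- stats::runif(markerBlock, .MARK_LO, .MARK_HI)
    }
    H <- matrix(stats::runif(kStates * nSamples, .OFF_LO, .OFF_HI),
                kStates, nSamples,
                dimnames = list(stateNames(kStates), sampleNames))
    H[cbind(stateLabels, seq_len(nSamples))] <-
      stats::runif(nSamples, .DOM_LO, .DOM_HI)
    X <- W %*% H
    if (noiseSd > 0)
      X <- pmax(X + matrix(stats::rnorm(length(X), sd = noiseSd),
                           nrow(X), ncol(X)), 0)
    list(expr = CellTypeExpression(cellType, X), W = W, H = H,
         labels = stats::setNames(stateLabels, sampleNames))
  })
}

#' Generate a multi-cell-type cohort with planted ecotypes
#'
#' Each sample first draws a latent ecotype; each member state of that
#' ecotype then becomes the sample's dominant state in its cell type with
#' probability \code{coocProb} (otherwise a uniformly random non-member
#' state of that cell type), and cell types without a member state get a
#' uniformly random dominant state. Expression per cell type is generated
#' as in [generateStateProfiles()] conditional on these labels; gene
#' identifiers are prefixed by cell type so that all cell types share one
#' disjoint gene universe. Optionally attaches ecotype-dependent survival
#' via [generateSurvivalTable()].
#'
#' @param celltypeSpecs named integer vector, cell type -> number of
#'   states.
#' @param ecotypeSpec list of character vectors of qualified state names
#'   ("<cellType>_S<k>"); the groups must be disjoint and every named
#'   state must exist.
#' @param nSamples cohort size.
#' @param noiseSd expression noise standard deviation.
#' @param seed master seed.
#' @param coocProb probability that a member state is made dominant in
#'   its cell type, in (0.5, 1].
#' @param nGenes,markerBlock per-cell-type matrix sizing.
#' @param ecotypeProbs latent ecotype frequencies (uniform when NULL).
#' @param hazards optional named per-ecotype hazard rates; when given,
#'   \code{censorRate} and \code{horizon} drive the clinical table.
#' @param censorRate,horizon censoring process parameters.
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(celltypeSpecs, ecotypeSpec, nSamples, noiseSd,
                           seed = 1L, coocProb = 0.9, nGenes = 150L,
                           markerBlock = 20L, ecotypeProbs = NULL,
                           hazards = NULL, censorRate = 0.02,
                           horizon = 100) {
  nSamples <- assertCount(nSamples, "nSamples")
  if (is.null(names(celltypeSpecs)) || anyDuplicated(names(celltypeSpecs)))
    stop("'celltypeSpecs' must be uniquely named by cell type")
  if (coocProb <= 0.5 || coocProb > 1)
    stop("'coocProb' must lie in (0.5, 1]")
  allStates <- unlist(lapply(names(celltypeSpecs), function(ct)
    qualifiedStateNames(ct, stateNames(celltypeSpecs[[ct]]))))
  flat <- unlist(ecotypeSpec)
  if (!all(flat %in% allStates))
    stop("ecotype spec names unknown states: ",
         paste(setdiff(flat, allStates), collapse = ", "))
  if (anyDuplicated(flat))
    stop("ecotype groups share a state; the partition must be disjoint")
  nEco <- length(ecotypeSpec)
  if (is.null(ecotypeProbs)) ecotypeProbs <- rep(1 / nEco, nEco)
  samples <- sprintf("Smp%04d", seq_len(nSamples))
  seeds <- spawnSeeds(seed, length(celltypeSpecs) + 2L)
  sampleEcotype <- withSeed(seeds[1L], stats::setNames(
    sample.int(nEco, nSamples, replace = TRUE, prob = ecotypeProbs),
    samples))
  # member state of each ecotype within each cell type (or NA)
  memberState <- matrix(NA_integer_, nEco, length(celltypeSpecs),
                        dimnames = list(NULL, names(celltypeSpecs)))
  for (e in seq_len(nEco)) for (st in ecotypeSpec[[e]]) {
    ct <- sub("_S[0-9]+$", "", st)
    memberState[e, ct] <- as.integer(sub("^.*_S", "", st))
  }
  expression <- list(); basis <- list(); coef <- list(); labels <- list()
  for (i in seq_along(celltypeSpecs)) {
    ct <- names(celltypeSpecs)[i]
    k <- celltypeSpecs[[i]]
    lab <- withSeed(seeds[i + 1L], {
      lab <- integer(nSamples)
      for (j in seq_len(nSamples)) {
        ms <- memberState[sampleEcotype[j], ct]
        lab[j] <- if (!is.na(ms) && stats::runif(1) <= coocProb) ms
                  else sample(setdiff(seq_len(k), ms), 1L)
      }
      lab
    })
    gp <- generateStateProfiles(nGenes, nSamples, k, noiseSd,
                                markerBlock = markerBlock,
                                seed = seeds[i + 1L], cellType = ct,
                                stateLabels = lab, sampleNames = samples,
                                genePrefix = paste0(ct, "_g"))
    expression[[ct]] <- gp$expr
    basis[[ct]] <- gp$W; coef[[ct]] <- gp$H; labels[[ct]] <- gp$labels
  }
  fractions <- withSeed(seeds[length(seeds)], {
    g <- matrix(stats::rgamma(nSamples * length(celltypeSpecs), shape = 2),
                nSamples, length(celltypeSpecs),
                dimnames = list(samples, names(celltypeSpecs)))
    g / rowSums(g)
  })
  partition <- integer(0)
  for (e in seq_len(nEco)) partition[ecotypeSpec[[e]]] <- e
  clinical <- data.frame(sample_id = character(), time = numeric(),
                         event = integer())
  if (!is.null(hazards)) {
    clinical <- generateSurvivalTable(
      stats::setNames(as.character(sampleEcotype), samples),
      hazards, censorRate, horizon, seed = seeds[length(seeds)] + 1L)
  }
  new("SyntheticCohort", expression = expression, fractions = fractions,
      clinical = clinical,
      truth = list(basis = basis, coefficients = coef, stateLabels = labels,
                   ecotypePartition = partition,
                   sampleEcotype = sampleEcotype,
                   survivalParams = list(hazards = hazards,
                                         censorRate = censorRate,
                                         horizon = horizon),
                   seed = seed))
}

#' Generate a clinical table with ecotype-dependent survival
#'
#' Event times are exponential with the sample's ecotype-specific hazard;
#' censoring times are exponential with \code{censorRate}, truncated at
#' \code{horizon}. The observed time is the minimum of the two and the
#' event indicator is 1 when the event precedes censoring.
#'
#' @param ecotypeAssignment named character vector, sample -> ecotype id.
#' @param hazardByEcotype named positive rates (events per time unit),
#'   covering every id in the assignment.
#' @param censorRate positive censoring rate.
#' @param horizon positive administrative censoring horizon.
#' @param seed RNG seed.
#' @return data.frame with columns sample_id, time, event, group.
#' @export
generateSurvivalTable <- function(ecotypeAssignment, hazardByEcotype,
                                  censorRate, horizon, seed = 1L) {
  censorRate <- assertScalar(censorRate, "censorRate")
  horizon <- assertScalar(horizon, "horizon")
  if (censorRate <= 0 || horizon <= 0)
    stop("'censorRate' and 'horizon' must be positive")
  if (any(hazardByEcotype <= 0)) stop("all hazards must be positive")
  ids <- as.character(ecotypeAssignment)
  if (!all(ids %in% names(hazardByEcotype)))
    stop("unknown ecotype id(s) in assignment: ",
         paste(unique(setdiff(ids, names(hazardByEcotype))), collapse = ", "))
  n <- length(ids)
  withSeed(seed, {
    eventTime <- stats::rexp(n, rate = hazardByEcotype[ids])
    censorTime <- pmin(stats::rexp(n, rate = censorRate), horizon)
    data.frame(
      sample_id = if (is.null(names(ecotypeAssignment)))
        sprintf("Smp%04d", seq_len(n)) else names(ecotypeAssignment),
      time = pmin(eventTime, censorTime),
      event = as.integer(eventTime <= censorTime),
      group = ids)
  })
}

#' Generate an annotated single-cell fixture from planted states
#'
#' Draws \code{cellsPerState} cells for every planted state of every cell
#' type; each cell's counts are multinomial with total \code{depth} over
#' the gene distribution proportional to the state's basis column.
#' Cell-type and true-state annotations are attached.
#'
#' @param truth the \code{truth} list of a [SyntheticCohort-class]
#'   (needs \code{basis}), or any list with a \code{basis} element
#'   mapping cell type -> gene-by-state matrix.
#' @param cellsPerState cells per state (>= 5).
#' @param depth total counts per cell (>= 1).
#' @param seed RNG seed.
#' @return List with \code{counts} (gene-by-cell integer matrix over the
#'   union of all cell types' genes) and \code{annotation} (data.frame
#'   barcode, cell_type, true_state).
#' @export
generateSingleCellFixture <- function(truth, cellsPerState, depth,
                                      seed = 1L) {
  cellsPerState <- assertCount(cellsPerState, "cellsPerState", min = 5L)
  depth <- assertCount(depth, "depth", min = 1L)
  basis <- truth$basis
  stopifnot(is.list(basis), length(basis) >= 1L)
  allGenes <- unique(unlist(lapply(basis, rownames)))
  seeds <- spawnSeeds(seed, length(basis))
  blocks <- list(); ann <- list()
  for (i in seq_along(basis)) {
    ct <- names(basis)[i]
    W <- basis[[i]]
    k <- ncol(W)
    cnt <- withSeed(seeds[i], {
      do.call(cbind, lapply(seq_len(k), function(s) {
        pr <- W[, s] / sum(W[, s])
        stats::rmultinom(cellsPerState, size = depth, prob = pr)
      }))
    })
    full <- matrix(0L, length(allGenes), ncol(cnt),
                   dimnames = list(allGenes, NULL))
    full[rownames(W), ] <- cnt
    blocks[[ct]] <- full
    ann[[ct]] <- data.frame(cell_type = ct,
                            true_state = rep(stateNames(k),
                                             each = cellsPerState))
  }
  counts <- do.call(cbind, blocks)
  annotation <- do.call(rbind, ann)
  annotation$barcode <- sprintf("cell%05d", seq_len(nrow(annotation)))
  rownames(annotation) <- NULL
  colnames(counts) <- annotation$barcode
  list(counts = counts,
       annotation = annotation[, c("barcode", "cell_type", "true_state")])
}

#' Generate a spatial fixture from planted states and ecotypes
#'
#' Each spot draws a latent ecotype and a Dirichlet cell-type fraction
#' row; within each cell type the spot expresses the ecotype's member
#' state (a uniformly random state where the ecotype has no member in
#' that cell type), and the spot expression mixes the chosen states'
#' normalised basis profiles weighted by the fraction row.
#'
#' @param truth the \code{truth} list of a [SyntheticCohort-class]
#'   (needs \code{basis} and \code{ecotypePartition}).
#' @param nSpots number of spots (>= 4).
#' @param seed RNG seed.
#' @param scale expression scale of a pure profile (default 1e4,
#'   CPM-like).
#' @return List with \code{expr} (gene-by-spot matrix), \code{coords}
#'   (data.frame spot, x, y on a square grid), \code{fractions}
#'   (spot-by-cell-type, rows summing to 1), \code{spotEcotype} (named
#'   integer truth) and \code{stateChoice} (spot-by-cell-type planted
#'   state names).
#' @export
generateSpatialFixture <- function(truth, nSpots, seed = 1L, scale = 1e4) {
  nSpots <- assertCount(nSpots, "nSpots", min = 4L)
  basis <- truth$basis
  partition <- truth$ecotypePartition
  stopifnot(is.list(basis), length(partition) > 0L)
  cts <- names(basis)
  nEco <- length(unique(partition))
  memberState <- matrix(NA_character_, nEco, length(cts),
                        dimnames = list(NULL, cts))
  for (st in names(partition)) {
    ct <- sub("_S[0-9]+$", "", st)
    memberState[partition[st], ct] <- sub("^.*_(S[0-9]+)$", "\\1", st)
  }
  allGenes <- unique(unlist(lapply(basis, rownames)))
  spots <- sprintf("spot%04d", seq_len(nSpots))
  withSeed(seed, {
    spotEcotype <- stats::setNames(sample.int(nEco, nSpots, replace = TRUE),
                                   spots)
    g <- matrix(stats::rgamma(nSpots * length(cts), shape = 2), nSpots,
                length(cts), dimnames = list(spots, cts))
    fractions <- g / rowSums(g)
    stateChoice <- matrix(NA_character_, nSpots, length(cts),
                          dimnames = list(spots, cts))
    expr <- matrix(0, length(allGenes), nSpots,
                   dimnames = list(allGenes, spots))
    for (j in seq_len(nSpots)) for (i in seq_along(cts)) {
      ct <- cts[i]
      k <- ncol(basis[[ct]])
      ms <- memberState[spotEcotype[j], ct]
      st <- if (!is.na(ms)) ms else stateNames(k)[sample.int(k, 1L)]
      stateChoice[j, i] <- st
      prof <- basis[[ct]][, st]
      expr[rownames(basis[[ct]]), j] <-
        expr[rownames(basis[[ct]]), j] +
        fractions[j, ct] * scale * prof / sum(prof)
    }
    side <- ceiling(sqrt(nSpots))
    coords <- data.frame(spot = spots,
                         x = (seq_len(nSpots) - 1L) %% side,
                         y = (seq_len(nSpots) - 1L) %/% side)
    list(expr = expr, coords = coords, fractions = fractions,
         spotEcotype = spotEcotype, stateChoice = stateChoice)
  })
}
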