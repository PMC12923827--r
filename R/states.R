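#' Extract per-state marker genes from an NMF basis
#'
#' A gene is a marker of a state when its basis loading on that state
#' dominates its loading on every other state by at least
#' \code{foldThreshold}-fold (and is positive). With a threshold above 1
#' the marker sets are disjoint by construction; the conventional
#' threshold of 2 matches the dominant-margin semantics used elsewhere in
#' the pipeline.
#'
#' @param result a [ConsensusResult-class], [StateModel-class], or a
#'   gene-by-state basis matrix W.
#' @param foldThreshold positive dominance factor (default 2).
#' @return Named list, state -> character vector of marker genes.
#' @export
extractMarkerGenes <- function(result, foldThreshold = 2) {
  if (foldThreshold <= 0) stop("'foldThreshold' must be positive")
  W <- if (is.matrix(result)) result else stateBasis(result)
  k <- ncol(W)
  states <- colnames(W)
  if (is.null(states)) states <- stateNames(k)
  out <- stats::setNames(vector("list", k), states)
  genes <- rownames(W)
  for (s in seq_len(k)) {
    otherMax <- if (k > 1L)
      apply(W[, -s, drop = FALSE], 1L, max) else 0
    hit <- W[, s] > 0 & W[, s] >= foldThreshold * otherMax
    out[[s]] <- genes[hit]
  }
  out
}

# Dominance assignment used by the AFI: a sample counts as assigned to a
# state only when that state's coefficient dominates every other state's
# by `margin`-fold -- the same margin that defines an unambiguous dominant
# state. Returns an integer state index per sample, NA when no state
# dominates.
dominantAssignment <- function(H, margin = 2) {
  idx <- max.col(t(H), ties.method = "first")
  n <- ncol(H)
  out <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    s <- idx[j]
    others <- H[-s, j]
    if (H[s, j] > 0 && (length(others) == 0L || H[s, j] >= margin * max(others)))
      out[j] <- s
  }
  out
}

#' Adjusted false-positive index (AFI) per state
#'
#' Scores each state for artifact-likeness by comparing how often it is
#' confidently (2-fold) dominant in the real data versus in background
#' data with the gene-sample structure destroyed. Each background
#' replicate independently permutes the gene values within every sample,
#' projects the scrambled matrix onto the fitted basis (multiplicative
#' coefficient updates with W fixed), and records each state's
#' dominance-assignment frequency. The AFI of a state is the mean
#' background frequency divided by its real-data frequency: a state as
#' frequent in scrambled data as in real data scores >= 1 and is treated
#' as a deconvolution artifact; a state never dominant in real data
#' scores +Inf and is always filtered.
#'
#' This index is an operational artifact score with the standard decision
#' boundary (filter at AFI >= 1); see the package vignette for its exact
#' construction and rationale.
#'
#' @param model a [StateModel-class] fitted on \code{X}.
#' @param X the [CellTypeExpression-class] (or matrix) the model was
#'   fitted on.
#' @param nBackground number of scrambled replicates (default 20).
#' @param seed master seed for the permutations.
#' @param margin dominance margin defining a confident assignment.
#' @return Named numeric vector, state -> AFI (possibly \code{Inf}).
#' @export
computeAFI <- function(model, X, nBackground = 20L, seed = 1L, margin = 2) {
  if (is(X, "CellTypeExpression")) X <- exprValues(X)
  stopifnot(is(model, "StateModel"), is.matrix(X))
  nBackground <- assertCount(nBackground, "nBackground", min = 1L)
  W <- stateBasis(model)
  H <- stateCoefficients(model)
  if (nrow(W) != nrow(X) || ncol(H) != ncol(X))
    stop("'model' dimensions do not match 'X'")
  k <- model@rank
  realAssign <- dominantAssignment(H, margin = margin)
  fReal <- tabulate(realAssign, nbins = k) / ncol(X)
  seeds <- spawnSeeds(seed, nBackground)
  fBg <- matrix(0, nBackground, k)
  sc <- mean(X) / max(mean(W), .Machine$double.eps) / k
  for (b in seq_len(nBackground)) {
    Xp <- withSeed(seeds[b],
                   apply(X, 2L, sample))  # scramble genes within each sample
    H0 <- matrix(sc, k, ncol(X))
    pr <- nmf_project_cpp(Xp, W, H0, 500L, 1e-5)
    fBg[b, ] <- tabulate(dominantAssignment(pr$H, margin = margin),
                         nbins = k) / ncol(X)
  }
  afi <- colMeans(fBg) / fReal
  afi[fReal == 0] <- Inf
  stats::setNames(afi, rownames(H))
}

#' Filter low-quality states and re-assign orphaned samples
#'
#' Applies the two retention rules: a state is kept only if it has at
#' least \code{minMarkers} marker genes and its AFI is below
#' \code{afiCut}. Samples whose dominant state was dropped are
#' re-assigned to their best (highest-coefficient) retained state.
#'
#' @param model a [StateModel-class] with markers and AFI populated.
#' @param minMarkers minimum marker-gene count (default 10).
#' @param afiCut AFI threshold; states with AFI >= this are dropped
#'   (default 1).
#' @return The filtered [StateModel-class].
#' @export
filterStates <- function(model, minMarkers = 10L, afiCut = 1) {
  stopifnot(is(model, "StateModel"))
  if (!length(model@markers) || !length(model@afi))
    stop("markers and AFI must be computed before filtering")
  keep <- lengths(model@markers) >= minMarkers & model@afi < afiCut
  if (!any(keep))
    stop(sprintf("all states of cell type '%s' were filtered out",
                 model@cellType))
  model@retained <- stats::setNames(unname(keep), names(model@markers))
  kept <- which(keep)
  Hk <- model@coefficients[kept, , drop = FALSE]
  model@sampleStates <- stats::setNames(
    kept[max.col(t(Hk), ties.method = "first")],
    colnames(model@coefficients))
  validObject(model)
  model
}

# Build a StateModel from the best run of a consensus sweep.
stateModelFromConsensus <- function(cellType, result) {
  H <- stateCoefficients(result)
  new("StateModel", cellType = cellType, rank = result@rank,
      basis = stateBasis(result), coefficients = H, markers = list(),
      sampleStates = stats::setNames(max.col(t(H), ties.method = "first"),
                                     colnames(H)),
      afi = numeric(), retained = logical())
}

#' Discover cellular states for one cell type
#'
#' The full state-discovery stage: preprocess the expression matrix,
#' sweep consensus NMF over the candidate rank range, select the rank by
#' the cophenetic criterion, extract marker genes, compute the AFI, and
#' filter low-quality states.
#'
#' @param X a [CellTypeExpression-class] with raw (TPM-like) or already
#'   preprocessed values.
#' @param kRange contiguous integer vector of candidate ranks
#'   (default 2:8; the conventional production range extends to 20).
#' @param nRuns NMF restarts per rank (default 100, the production
#'   setting; simulations typically use 20).
#' @param seed master seed.
#' @param target cophenetic target for rank selection (default 0.97).
#' @param foldThreshold marker dominance factor (default 2).
#' @param minMarkers,afiCut state retention thresholds (defaults 10 and 1).
#' @param nBackground AFI background replicates (default 20).
#' @param preprocess apply [preprocessProfiles()] first (default TRUE;
#'   set FALSE for data already on a unit-like scale, e.g. simulated
#'   cohorts).
#' @param rankMethod rank-selection rule passed to [selectRank()].
#' @param maxIter,tol NMF iteration controls.
#' @return A list with elements \code{model} (the filtered
#'   [StateModel-class]), \code{traces} (per-rank
#'   [ConsensusResult-class]), and \code{cophenetics} (named numeric).
#' @export
discoverStates <- function(X, kRange = 2:8, nRuns = 100L, seed = 1L,
                           target = 0.97, foldThreshold = 2,
                           minMarkers = 10L, afiCut = 1,
                           nBackground = 20L, preprocess = TRUE,
                           rankMethod = c("target", "stability"),
                           maxIter = 2000L, tol = 1e-6) {
  stopifnot(is(X, "CellTypeExpression"))
  rankMethod <- match.arg(rankMethod)
  Xp <- if (preprocess) preprocessProfiles(X) else X
  kRange <- sort(unique(as.integer(kRange)))
  seeds <- spawnSeeds(seed, length(kRange) + 1L)
  traces <- vector("list", length(kRange))
  names(traces) <- kRange
  for (i in seq_along(kRange))
    traces[[i]] <- consensusNMF(Xp, kRange[i], nRuns, seeds[i],
                                maxIter = maxIter, tol = tol)
  coph <- vapply(traces, copheneticCoeff, numeric(1))
  k <- selectRank(traces, target = target, method = rankMethod)
  model <- stateModelFromConsensus(cellType(X), traces[[as.character(k)]])
  model@markers <- extractMarkerGenes(model, foldThreshold = foldThreshold)
  model@afi <- computeAFI(model, Xp, nBackground = nBackground,
                          seed = seeds[length(seeds)])
  model <- filterStates(model, minMarkers = minMarkers, afiCut = afiCut)
  list(model = model, traces = traces, cophenetics = coph)
}
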