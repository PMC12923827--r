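## Recovery of previously discovered cellular states and ecotypes in
## single-cell and spatial transcriptomics data.

#' Log-normalise a count matrix
#'
#' Library-size normalisation to \code{scale} total counts per cell
#' followed by log1p; columns with zero total are left at zero.
#'
#' @param counts gene-by-cell (or gene-by-spot) nonnegative matrix.
#' @param scale target total (default 1e4).
#' @return Matrix of the same shape.
#' @export
logNormalize <- function(counts, scale = 1e4) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log1p(sweep(counts, 2L, tot / scale, "/"))
}

# Mean marker score of a gene set over a set of cells: mean expression of
# the set minus mean expression of a size-matched seeded background set.
.markerScore <- function(logexpr, genes, seed) {
  bgPool <- setdiff(rownames(logexpr), genes)
  bg <- withSeed(seed, sample(bgPool, min(length(genes), length(bgPool))))
  colMeans(logexpr[genes, , drop = FALSE]) -
    colMeans(logexpr[bg, , drop = FALSE])
}

#' Score annotated cells against cellular states
#'
#' For every state, cells whose cell-type annotation matches the state's
#' parent cell type are scored as the mean log-normalised expression of
#' the state's marker genes minus the mean of a size-matched random
#' background gene set (seeded); cells of other cell types get
#' \code{NA}. States whose markers intersect the gene universe in fewer
#' than 3 genes are excluded with a warning.
#'
#' @param counts gene-by-cell count matrix (raw counts; log-normalised
#'   internally).
#' @param annotation data.frame with columns \code{barcode} and
#'   \code{cell_type}, one row per cell, matching the columns of
#'   \code{counts}.
#' @param markers named list of marker gene vectors; names are qualified
#'   "<cellType>_S<k>" state labels.
#' @param seed seed for the background gene draws.
#' @return Cell-by-state numeric matrix (NA where the cell type does not
#'   match).
#' @export
scoreCellsAgainstStates <- function(counts, annotation, markers, seed = 1L) {
  stopifnot(is.matrix(counts) || is(counts, "Matrix"),
            all(c("barcode", "cell_type") %in% colnames(annotation)),
            ncol(counts) == nrow(annotation))
  logexpr <- logNormalize(as.matrix(counts))
  stateCT <- sub("_S[0-9]+$", "", names(markers))
  present <- lapply(markers, intersect, x = rownames(counts))
  usable <- lengths(present) >= 3L
  if (!all(usable))
    warning("state(s) with < 3 markers in the gene universe excluded: ",
            paste(names(markers)[!usable], collapse = ", "))
  if (!any(usable)) stop("no state has >= 3 usable marker genes")
  seeds <- spawnSeeds(seed, length(markers))
  scores <- matrix(NA_real_, ncol(counts), length(markers),
                   dimnames = list(annotation$barcode, names(markers)))
  for (s in which(usable)) {
    cells <- which(annotation$cell_type == stateCT[s])
    if (!length(cells)) next
    scores[cells, s] <- .markerScore(
      logexpr[, cells, drop = FALSE], present[[s]], seeds[s])
  }
  scores
}

#' Permutation z-score for one state's marker set
#'
#' Measures the specificity of a marker set: the observed mean marker
#' score over the given cells is compared with a null distribution
#' obtained by redrawing the marker set uniformly from the gene universe
#' \code{nPerm} times and recomputing the same score. The z-score is
#' (observed - null mean) / null standard deviation.
#'
#' @param counts gene-by-cell count matrix.
#' @param markerGenes the state's marker genes (character).
#' @param cells column indices or names of the cells to score (default
#'   all).
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return A single z-score (NA with a warning when the null is
#'   degenerate).
#' @export
permutationZ <- function(counts, markerGenes, cells = NULL, nPerm = 1000L,
                         seed = 1L) {
  nPerm <- assertCount(nPerm, "nPerm", min = 100L)
  logexpr <- logNormalize(as.matrix(counts))
  if (!is.null(cells)) logexpr <- logexpr[, cells, drop = FALSE]
  genes <- intersect(markerGenes, rownames(logexpr))
  if (length(genes) < 3L) stop("fewer than 3 marker genes in the universe")
  seeds <- spawnSeeds(seed, nPerm + 1L)
  obs <- mean(.markerScore(logexpr, genes, seeds[1L]))
  universe <- rownames(logexpr)
  null <- vapply(seq_len(nPerm), function(b) {
    fake <- withSeed(seeds[b + 1L], sample(universe, length(genes)))
    mean(.markerScore(logexpr, fake, seeds[b + 1L]))
  }, numeric(1))
  s <- stats::sd(null)
  if (s == 0) {
    warning("degenerate permutation null (zero variance); z undefined")
    return(NA_real_)
  }
  (obs - mean(null)) / s
}

#' Stouffer's combined z-score
#'
#' Combines z-scores as their sum divided by the square root of their
#' count. Non-finite values are dropped with a warning.
#'
#' @param z numeric vector of z-scores (at least one finite value).
#' @return The combined z.
#' @examples
#' stoufferMetaZ(c(1, 1, 1, 1))  # 2
#' @export
stoufferMetaZ <- function(z) {
  if (length(z) == 0L) stop("no z-scores to combine")
  keep <- is.finite(z)
  if (!all(keep)) {
    warning(sum(!keep), " non-finite z-score(s) dropped")
    z <- z[keep]
  }
  if (length(z) == 0L) stop("no finite z-scores to combine")
  sum(z) / sqrt(length(z))
}

#' Recover cellular states in annotated single-cell data
#'
#' Scores every cell against every state ([scoreCellsAgainstStates()]),
#' derives a permutation z-score per state over the cells of its parent
#' cell type ([permutationZ()]), and combines the per-state z-scores
#' into a meta z ([stoufferMetaZ()]).
#'
#' @inheritParams scoreCellsAgainstStates
#' @param nPerm permutations per state.
#' @return List with \code{scores} (cell-by-state), \code{z} (named
#'   per-state z-scores) and \code{metaZ}.
#' @export
recoverStatesSingleCell <- function(counts, annotation, markers,
                                    nPerm = 1000L, seed = 1L) {
  scores <- scoreCellsAgainstStates(counts, annotation, markers,
                                    seed = seed)
  stateCT <- sub("_S[0-9]+$", "", names(markers))
  seeds <- spawnSeeds(seed, length(markers))
  z <- stats::setNames(rep(NA_real_, length(markers)), names(markers))
  for (s in seq_along(markers)) {
    cells <- which(annotation$cell_type == stateCT[s])
    genes <- intersect(markers[[s]], rownames(counts))
    if (length(cells) == 0L || length(genes) < 3L) next
    z[s] <- permutationZ(counts[, cells, drop = FALSE], genes,
                         nPerm = nPerm, seed = seeds[s])
  }
  list(scores = scores, z = z, metaZ = stoufferMetaZ(z[is.finite(z)]))
}

#' Recover cellular states in spatial spots
#'
#' For each spot and cell type, the cell type's states are scored on the
#' spot's log-normalised expression as in [scoreCellsAgainstStates()];
#' the most abundant (highest-scoring) state receives indicator 1 and
#' the rest 0, and the indicator is multiplied by the spot's fraction of
#' that parent cell type to give the state abundance.
#'
#' @param spotExpr gene-by-spot expression matrix.
#' @param fractions spot-by-cell-type fraction matrix, rows on the
#'   simplex.
#' @param markers named list of marker sets with qualified
#'   "<cellType>_S<k>" names.
#' @param seed seed for background gene draws.
#' @return Spot-by-state abundance matrix.
#' @export
recoverStatesSpatial <- function(spotExpr, fractions, markers, seed = 1L) {
  stopifnot(is.matrix(spotExpr), is.matrix(fractions),
            ncol(spotExpr) == nrow(fractions))
  if (any(abs(rowSums(fractions) - 1) > 1e-6))
    stop("fraction rows must sum to 1")
  zeroSpot <- colSums(spotExpr) == 0
  if (any(zeroSpot))
    warning(sum(zeroSpot), " spot(s) with zero counts get all-zero rows")
  logexpr <- logNormalize(spotExpr)
  stateCT <- sub("_S[0-9]+$", "", names(markers))
  seeds <- spawnSeeds(seed, length(markers))
  spots <- colnames(spotExpr)
  scores <- matrix(NA_real_, ncol(spotExpr), length(markers),
                   dimnames = list(spots, names(markers)))
  for (s in seq_along(markers)) {
    genes <- intersect(markers[[s]], rownames(spotExpr))
    if (length(genes) < 3L) {
      warning("state ", names(markers)[s], " has < 3 markers; excluded")
      next
    }
    scores[, s] <- .markerScore(logexpr, genes, seeds[s])
  }
  abundance <- matrix(0, ncol(spotExpr), length(markers),
                      dimnames = list(spots, names(markers)))
  for (ct in unique(stateCT)) {
    idx <- which(stateCT == ct & !apply(is.na(scores), 2L, all))
    if (length(idx) == 0L) next
    sub <- scores[, idx, drop = FALSE]
    top <- max.col(sub, ties.method = "first")
    for (j in seq_len(nrow(sub)))
      if (!zeroSpot[j] && ct %in% colnames(fractions))
        abundance[j, idx[top[j]]] <- fractions[j, ct]
  }
  abundance
}

#' Recover ecotypes in spatial spots
#'
#' The ecotype abundance of a spot is the mean abundance of the
#' ecotype's member states; the resulting spot-by-ecotype matrix is
#' rescaled so that its 99th percentile (across all spot-ecotype values)
#' equals 1, with values above 1 clipped to 1. The percentile is the
#' empirical (inverse-ECDF, type 1) quantile, which keeps the scaled
#' matrix's 99th percentile at exactly 1 after clipping.
#'
#' @param stateAbund spot-by-state abundance matrix from
#'   [recoverStatesSpatial()].
#' @param partition named integer vector, state -> ecotype id.
#' @param coords optional spot coordinate data.frame carried through.
#' @return List with \code{ecotypeAbundance} (spot-by-ecotype, 99th
#'   percentile 1), \code{stateAbundance} and \code{coords}.
#' @export
recoverEcotypesSpatial <- function(stateAbund, partition, coords = NULL) {
  stopifnot(is.matrix(stateAbund), length(partition) >= 1L)
  ids <- sort(unique(partition))
  eco <- vapply(ids, function(e) {
    members <- intersect(names(partition)[partition == e],
                         colnames(stateAbund))
    if (!length(members)) return(rep(0, nrow(stateAbund)))
    rowMeans(stateAbund[, members, drop = FALSE])
  }, numeric(nrow(stateAbund)))
  eco <- matrix(eco, ncol = length(ids),
                dimnames = list(rownames(stateAbund), paste0("E", ids)))
  p99 <- stats::quantile(eco, 0.99, names = FALSE, type = 1)
  if (p99 <= 0) stop("all-zero ecotype abundance; nothing to scale")
  eco <- pmin(eco / p99, 1)
  list(ecotypeAbundance = eco, stateAbundance = stateAbund,
       coords = coords)
}
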