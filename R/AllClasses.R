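#' @useDynLib EcoStates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' CellTypeExpression: expression matrix for one cell type
#'
#' A nonnegative gene-by-sample expression matrix (TPM-like units, or the
#' log/unit-scaled values produced by [preprocessProfiles()]) attributed to a
#' single cell population, e.g. the output of an in-silico purification of
#' bulk profiles. This is the input to consensus NMF state discovery.
#'
#' @slot cellType single character, the cell population name.
#' @slot values numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames and no negative entries.
#'
#' @seealso [CellTypeExpression()] for the constructor.
#' @export
setClass("CellTypeExpression",
  slots = c(cellType = "character", values = "matrix"))

setValidity("CellTypeExpression", function(object) {
  v <- object@values
  msg <- character()
  if (length(object@cellType) != 1L || is.na(object@cellType) ||
      !nzchar(object@cellType))
    msg <- c(msg, "'cellType' must be a single non-empty string")
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  else {
    if (anyNA(v)) msg <- c(msg, "'values' contains missing entries")
    else if (any(v < 0)) msg <- c(msg, "'values' contains negative entries")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "'values' must carry gene rownames and sample colnames")
    else {
      if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate gene identifiers")
      if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate sample identifiers")
    }
    if (ncol(v) < 2L) msg <- c(msg, "at least 2 samples are required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellTypeExpression object
#'
#' @param cellType cell population name.
#' @param values nonnegative gene-by-sample numeric matrix with dimnames.
#' @return A [CellTypeExpression-class] object.
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' CellTypeExpression("Fibroblasts", m)
#' @export
CellTypeExpression <- function(cellType, values) {
  new("CellTypeExpression", cellType = as.character(cellType),
      values = as.matrix(values))
}

#' ConsensusResult: one consensus-NMF sweep at a fixed rank
#'
#' Holds the sample co-clustering consensus matrix accumulated over repeated
#' NMF runs at rank \code{k}, the factor pair from the run with the lowest
#' reconstruction objective, and the cophenetic coefficient of the consensus
#' used for rank selection.
#'
#' @slot rank integer, the number of states k.
#' @slot consensus sample-by-sample matrix in [0,1]: the fraction of runs in
#'   which the two samples received the same dominant-state label.
#' @slot basis best-run gene-by-k basis matrix W (nonnegative).
#' @slot coefficients best-run k-by-sample coefficient matrix H (nonnegative).
#' @slot objective best (lowest) final squared-Frobenius objective.
#' @slot cophenetic cophenetic coefficient of the consensus matrix.
#' @slot nRuns number of NMF runs aggregated.
#' @slot nNotConverged number of runs that hit the iteration cap.
#' @export
setClass("ConsensusResult",
  slots = c(rank = "integer", consensus = "matrix", basis = "matrix",
            coefficients = "matrix", objective = "numeric",
            cophenetic = "numeric", nRuns = "integer",
            nNotConverged = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  C <- object@consensus
  if (!isSymmetric(unname(C), tol = 1e-8))
    msg <- c(msg, "consensus matrix must be symmetric")
  if (any(C < -1e-12) || any(C > 1 + 1e-12))
    msg <- c(msg, "consensus entries must lie in [0,1]")
  if (any(abs(diag(C) - 1) > 1e-12))
    msg <- c(msg, "consensus diagonal must be 1")
  if (any(object@basis < 0) || any(object@coefficients < 0))
    msg <- c(msg, "factors must be nonnegative")
  if (ncol(object@basis) != object@rank ||
      nrow(object@coefficients) != object@rank)
    msg <- c(msg, "factor dimensions disagree with 'rank'")
  if (length(msg)) msg else TRUE
})

#' StateModel: cellular states of one cell type
#'
#' The fitted state model for a cell type: the NMF factor pair at the
#' selected rank, per-state marker genes, the dominant state of each sample,
#' the per-state adjusted false-positive index (AFI), and the retention flag
#' combining the marker-count and AFI filters.
#'
#' @slot cellType cell population name.
#' @slot rank number of states k.
#' @slot basis gene-by-k basis matrix W; columns named by state.
#' @slot coefficients k-by-sample coefficient matrix H; rows named by state.
#' @slot markers named list, state -> character vector of marker genes.
#' @slot sampleStates named integer vector, sample -> dominant state index
#'   (per-column argmax of H).
#' @slot afi named numeric vector, state -> AFI (may be \code{Inf}).
#' @slot retained named logical vector, state -> retained after filtering.
#' @export
setClass("StateModel",
  slots = c(cellType = "character", rank = "integer", basis = "matrix",
            coefficients = "matrix", markers = "list",
            sampleStates = "integer", afi = "numeric", retained = "logical"))

setValidity("StateModel", function(object) {
  msg <- character()
  k <- object@rank
  if (ncol(object@basis) != k || nrow(object@coefficients) != k)
    msg <- c(msg, "factor dimensions disagree with 'rank'")
  if (length(object@markers) && length(object@markers) != k)
    msg <- c(msg, "'markers' must have one entry per state")
  if (length(object@sampleStates)) {
    if (length(object@sampleStates) != ncol(object@coefficients))
      msg <- c(msg, "'sampleStates' must cover every sample")
    # dominant state = per-column argmax of H, restricted to retained
    # states once filtering has run
    keep <- if (length(object@retained) == k && any(object@retained))
      which(object@retained) else seq_len(k)
    Hk <- object@coefficients[keep, , drop = FALSE]
    am <- keep[max.col(t(Hk), ties.method = "first")]
    if (!all(object@sampleStates == am))
      msg <- c(msg, "'sampleStates' must be the per-column argmax of H ",
               "over retained states")
  }
  if (length(msg)) msg else TRUE
})

#' BinaryAssignmentMatrix: dominant-state indicator matrix
#'
#' The 0/1 matrix A with one row per retained cellular state (across all
#' cell types) and one column per sample; A[i, j] = 1 iff state i is the
#' dominant state of sample j within state i's cell type. Within each cell
#' type every sample has exactly one 1 (or none if that cell type lacks the
#' sample).
#'
#' @slot A 0/1 integer matrix, states x samples, rownames
#'   "<cellType>_S<k>".
#' @slot stateCellType character vector, the parent cell type of each row.
#' @export
setClass("BinaryAssignmentMatrix",
  slots = c(A = "matrix", stateCellType = "character"))

setValidity("BinaryAssignmentMatrix", function(object) {
  msg <- character()
  A <- object@A
  if (!all(A %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
  if (length(object@stateCellType) != nrow(A))
    msg <- c(msg, "'stateCellType' must have one entry per row")
  for (ct in unique(object@stateCellType)) {
    cs <- colSums(A[object@stateCellType == ct, , drop = FALSE])
    if (any(cs > 1))
      msg <- c(msg, sprintf(
        "cell type '%s': a sample has more than one dominant state", ct))
  }
  if (length(msg)) msg else TRUE
})

#' JaccardMatrix: state co-occurrence with significance
#'
#' Pairwise Jaccard indices over the sample supports of cellular states,
#' with matching hypergeometric overlap p-values and BH-adjusted q-values.
#' Entries failing the significance gate are zeroed before clustering.
#'
#' @slot J state-by-state Jaccard matrix in [0,1], unit diagonal.
#' @slot p matching matrix of hypergeometric upper-tail p-values.
#' @slot q BH-adjusted p-values (adjusted over the strict upper triangle).
#' @slot alpha significance level used to zero non-significant entries.
#' @export
setClass("JaccardMatrix",
  slots = c(J = "matrix", p = "matrix", q = "matrix", alpha = "numeric"))

#' EcotypeModel: communities of co-occurring states
#'
#' The partition of retained cellular states into ecotypes (communities of
#' states co-occurring across samples), per-sample ecotype abundances
#' (rows on the simplex) and the per-sample ecotype assignment with its
#' supporting q-values.
#'
#' @slot partition named integer vector, state -> ecotype id; states in
#'   removed (undersized) clusters are absent.
#' @slot rawPartition named integer vector: the clustering partition before
#'   the minimum-size filter (useful for benchmarking against planted truth).
#' @slot nEcotypes number of ecotypes surviving the size filter.
#' @slot abundance sample-by-ecotype matrix, rows summing to 1.
#' @slot assignment named character vector, sample -> ecotype id or
#'   \code{NA} for unassigned samples.
#' @slot assignmentQ sample-by-ecotype matrix of BH q-values.
#' @export
setClass("EcotypeModel",
  slots = c(partition = "integer", rawPartition = "integer",
            nEcotypes = "integer", abundance = "matrix",
            assignment = "character", assignmentQ = "matrix"))

setValidity("EcotypeModel", function(object) {
  msg <- character()
  if (length(object@partition)) {
    sz <- table(object@partition)
    if (any(sz <= 3))
      msg <- c(msg, "every ecotype must keep >= 4 member states")
  }
  if (length(object@abundance) && nrow(object@abundance) > 0) {
    rs <- rowSums(object@abundance)
    if (any(abs(rs - 1) > 1e-9))
      msg <- c(msg, "abundance rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a simulated multi-cell-type cohort with known truth
#'
#' A cohort generated by [generateCohort()]: one expression matrix per cell
#' type, per-sample cell-type fractions on the simplex, a clinical table,
#' and the \code{truth} list holding the planted factors, dominant-state
#' labels, ecotype partition and survival parameters that downstream stages
#' are benchmarked against.
#'
#' @slot expression named list of [CellTypeExpression-class] objects.
#' @slot fractions sample-by-cell-type matrix, rows summing to 1.
#' @slot clinical data.frame with columns sample_id, time, event (may be
#'   empty when no survival structure was requested).
#' @slot truth list with elements \code{basis}, \code{coefficients},
#'   \code{stateLabels}, \code{ecotypePartition}, \code{sampleEcotype},
#'   \code{survivalParams}, \code{seed}.
#' @export
setClass("SyntheticCohort",
  slots = c(expression = "list", fractions = "matrix",
            clinical = "data.frame", truth = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!all(vapply(object@expression, is, logical(1), "CellTypeExpression")))
    msg <- c(msg, "'expression' must hold CellTypeExpression objects")
  if (length(object@fractions)) {
    if (any(abs(rowSums(object@fractions) - 1) > 1e-9))
      msg <- c(msg, "fraction rows must sum to 1")
  }
  if (nrow(object@clinical) && any(object@clinical$time <= 0))
    msg <- c(msg, "survival times must be positive")
  if (length(msg)) msg else TRUE
})
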