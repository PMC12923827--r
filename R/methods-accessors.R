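#' @rdname CellTypeExpression-class
#' @aliases cellType,CellTypeExpression-method
setMethod("cellType", "CellTypeExpression", function(object) object@cellType)

#' @rdname CellTypeExpression-class
#' @aliases exprValues,CellTypeExpression-method
setMethod("exprValues", "CellTypeExpression", function(object) object@values)

#' @rdname StateModel-class
#' @aliases cellType,StateModel-method
setMethod("cellType", "StateModel", function(object) object@cellType)

#' @rdname StateModel-class
#' @aliases stateBasis,StateModel-method
setMethod("stateBasis", "StateModel", function(object) object@basis)

#' @rdname StateModel-class
setMethod("stateCoefficients", "StateModel",
  function(object) object@coefficients)

#' @rdname StateModel-class
setMethod("stateMarkers", "StateModel", function(object) object@markers)

#' @rdname StateModel-class
setMethod("sampleStates", "StateModel", function(object) object@sampleStates)

#' @rdname StateModel-class
setMethod("stateAFI", "StateModel", function(object) object@afi)

#' @rdname StateModel-class
setMethod("retainedStates", "StateModel", function(object) object@retained)

#' @rdname ConsensusResult-class
setMethod("consensusMatrix", "ConsensusResult",
  function(object) object@consensus)

#' @rdname ConsensusResult-class
setMethod("copheneticCoeff", "ConsensusResult",
  function(object) object@cophenetic)

#' @rdname ConsensusResult-class
#' @aliases stateBasis,ConsensusResult-method
setMethod("stateBasis", "ConsensusResult", function(object) object@basis)

#' @rdname ConsensusResult-class
setMethod("stateCoefficients", "ConsensusResult",
  function(object) object@coefficients)

#' @rdname EcotypeModel-class
setMethod("ecotypePartition", "EcotypeModel", function(object) object@partition)

#' @rdname EcotypeModel-class
setMethod("ecotypeAbundance", "EcotypeModel", function(object) object@abundance)

#' @rdname EcotypeModel-class
setMethod("ecotypeAssignment", "EcotypeModel",
  function(object) object@assignment)

#' @rdname EcotypeModel-class
setMethod("nEcotypes", "EcotypeModel", function(object) object@nEcotypes)

setMethod("show", "CellTypeExpression", function(object) {
  v <- object@values
  cat("CellTypeExpression:", object@cellType, "\n",
      " ", nrow(v), "genes x", ncol(v), "samples;",
      "range [", format(min(v), digits = 4), ",",
      format(max(v), digits = 4), "]\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: rank", object@rank, "over", object@nRuns, "runs\n",
      " cophenetic coefficient:", format(object@cophenetic, digits = 6), "\n",
      " best objective:", format(object@objective, digits = 6), "\n")
})

setMethod("show", "StateModel", function(object) {
  nm <- lengths(object@markers)
  cat("StateModel:", object@cellType, "with", object@rank, "states\n")
  if (length(object@retained))
    cat("  retained:", sum(object@retained), "/", object@rank, "\n")
  if (length(nm)) cat("  markers per state:", paste(nm, collapse = ", "), "\n")
})

setMethod("show", "EcotypeModel", function(object) {
  cat("EcotypeModel:", object@nEcotypes, "ecotypes over",
      length(object@partition), "states\n")
  if (length(object@assignment)) {
    n <- length(object@assignment)
    cat("  assigned samples:", sum(!is.na(object@assignment)), "/", n, "\n")
  }
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", length(object@expression), "cell types,",
      nrow(object@fractions), "samples\n")
  if (length(object@truth$ecotypePartition))
    cat("  planted ecotypes:",
        length(unique(object@truth$ecotypePartition)), "\n")
})
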