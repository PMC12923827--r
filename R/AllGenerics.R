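#' @rdname CellTypeExpression-class
#' @param object an object.
#' @export
setGeneric("cellType", function(object) standardGeneric("cellType"))

#' @rdname CellTypeExpression-class
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname StateModel-class
#' @param object an object.
#' @export
setGeneric("stateBasis", function(object) standardGeneric("stateBasis"))

#' @rdname StateModel-class
#' @export
setGeneric("stateCoefficients",
  function(object) standardGeneric("stateCoefficients"))

#' @rdname StateModel-class
#' @export
setGeneric("stateMarkers", function(object) standardGeneric("stateMarkers"))

#' @rdname StateModel-class
#' @export
setGeneric("sampleStates", function(object) standardGeneric("sampleStates"))

#' @rdname StateModel-class
#' @export
setGeneric("stateAFI", function(object) standardGeneric("stateAFI"))

#' @rdname StateModel-class
#' @export
setGeneric("retainedStates",
  function(object) standardGeneric("retainedStates"))

#' @rdname ConsensusResult-class
#' @param object an object.
#' @export
setGeneric("consensusMatrix",
  function(object) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("copheneticCoeff",
  function(object) standardGeneric("copheneticCoeff"))

#' @rdname EcotypeModel-class
#' @param object an object.
#' @export
setGeneric("ecotypePartition",
  function(object) standardGeneric("ecotypePartition"))

#' @rdname EcotypeModel-class
#' @export
setGeneric("ecotypeAbundance",
  function(object) standardGeneric("ecotypeAbundance"))

#' @rdname EcotypeModel-class
#' @export
setGeneric("ecotypeAssignment",
  function(object) standardGeneric("ecotypeAssignment"))

#' @rdname EcotypeModel-class
#' @export
setGeneric("nEcotypes", function(object) standardGeneric("nEcotypes"))
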