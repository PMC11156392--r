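#' @rdname modelParams
#' @param object a fibrilseq S4 object.
#' @export
setGeneric("chainLength", function(object) standardGeneric("chainLength"))

#' @rdname modelParams
#' @export
setGeneric("wtProb", function(object) standardGeneric("wtProb"))

#' @rdname modelParams
#' @export
setGeneric("coupling", function(object) standardGeneric("coupling"))

#' @rdname modelParams
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' @rdname modelParams
#' @export
setGeneric("tempKelvin", function(object) standardGeneric("tempKelvin"))

#' @rdname enumerateDistribution
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))

#' @rdname enumerateDistribution
#' @export
setGeneric("partitionConstant",
           function(object) standardGeneric("partitionConstant"))

#' @rdname sweepOdds
#' @export
setGeneric("sweepFrame", function(object) standardGeneric("sweepFrame"))

#' @rdname simulateEnsemble
#' @export
setGeneric("empiricalFrequencies",
           function(object) standardGeneric("empiricalFrequencies"))
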