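#' @rdname ChaseDesign
#' @param x,object a \code{ChaseDesign}.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname ChaseDesign
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname ChaseDesign
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname ChaseDesign
#' @export
setGeneric("actdPretreat", function(x) standardGeneric("actdPretreat"))

#' @rdname SyntheticTruth
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname fitDecay
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname fitDecay
#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))

#' @rdname fitPvalue
#' @export
setGeneric("fitPvalue", function(fit, ...) standardGeneric("fitPvalue"))

#' @rdname halfLifeCI
#' @export
setGeneric("halfLifeCI", function(fit, confidence = 0.95, ...)
  standardGeneric("halfLifeCI"))

#' @rdname isReliable
#' @export
setGeneric("isReliable", function(fit, alpha = 0.05, ...)
  standardGeneric("isReliable"))

#' @rdname couplingScatter
#' @export
setGeneric("couplingTable", function(x) standardGeneric("couplingTable"))

#' @rdname couplingScatter
#' @export
setGeneric("couplingCorrelation", function(x) standardGeneric("couplingCorrelation"))

#' @rdname couplingScatter
#' @export
setGeneric("couplingCensus", function(x) standardGeneric("couplingCensus"))
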