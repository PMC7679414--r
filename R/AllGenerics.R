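#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @export
setGeneric("isDetected", function(x, ...) standardGeneric("isDetected"))

#' @export
setGeneric("proteinIds", function(x, ...) standardGeneric("proteinIds"))

#' @export
setGeneric("sampleFungus", function(x) standardGeneric("sampleFungus"))

#' @export
setGeneric("sampleSubstrate", function(x) standardGeneric("sampleSubstrate"))

#' @export
setGeneric("sampleReplicate", function(x) standardGeneric("sampleReplicate"))

#' @export
setGeneric("cazyFamilies", function(x) standardGeneric("cazyFamilies"))

#' @export
setGeneric("peptidaseFamilies", function(x) standardGeneric("peptidaseFamilies"))

#' @export
setGeneric("predictorCalls", function(x) standardGeneric("predictorCalls"))

#' @export
setGeneric("isSecreted", function(x) standardGeneric("isSecreted"))

#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @export
setGeneric("keptProteins", function(x, ...) standardGeneric("keptProteins"))

#' @export
setGeneric("presentOn", function(x, ...) standardGeneric("presentOn"))

#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @export
setGeneric("classSizes", function(x) standardGeneric("classSizes"))

#' @export
setGeneric("nodeStrength", function(x, ...) standardGeneric("nodeStrength"))

#' @export
setGeneric("edgePvalues", function(x) standardGeneric("edgePvalues"))

#' @export
setGeneric("integerWeights", function(x) standardGeneric("integerWeights"))

#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @export
setGeneric("trueClassOf", function(x) standardGeneric("trueClassOf"))
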