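#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @export
setGeneric("goTerms", function(x, protein, aspect) standardGeneric("goTerms"))

#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @export
setGeneric("classifierIds", function(x) standardGeneric("classifierIds"))

#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @export
setGeneric("aucValues", function(x) standardGeneric("aucValues"))

#' @export
setGeneric("aucMean", function(x) standardGeneric("aucMean"))

#' @export
setGeneric("aucSD", function(x) standardGeneric("aucSD"))
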