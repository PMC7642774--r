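#' @rdname nResidues
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("residueIndices", function(x) standardGeneric("residueIndices"))

#' @rdname accessors
#' @export
setGeneric("residueNames", function(x) standardGeneric("residueNames"))

#' @rdname accessors
#' @export
setGeneric("chainID", function(x) standardGeneric("chainID"))

#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname accessors
#' @export
setGeneric("cbCoords", function(x) standardGeneric("cbCoords"))

#' @rdname accessors
#' @export
setGeneric("oCoords", function(x) standardGeneric("oCoords"))

#' @rdname accessors
#' @export
setGeneric("bFactors", function(x) standardGeneric("bFactors"))

#' @rdname ensemble-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ensemble-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname ensemble-accessors
#' @export
setGeneric("frameEnergies", function(x) standardGeneric("frameEnergies"))

#' @rdname ensemble-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname rmsfValues
#' @export
setGeneric("rmsfValues", function(x) standardGeneric("rmsfValues"))

#' @rdname rmsfValues
#' @export
setGeneric("bfactorValues", function(x) standardGeneric("bfactorValues"))

#' @rdname trim-accessors
#' @export
setGeneric("removedResidues", function(x) standardGeneric("removedResidues"))

#' @rdname trim-accessors
#' @export
setGeneric("keptResidues", function(x) standardGeneric("keptResidues"))

#' @rdname trim-accessors
#' @export
setGeneric("fractionRemoved", function(x) standardGeneric("fractionRemoved"))

#' @rdname cluster-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname cluster-accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname cluster-accessors
#' @export
setGeneric("qMatrix", function(x) standardGeneric("qMatrix"))

#' @rdname contact-accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname contact-accessors
#' @export
setGeneric("nContacts", function(x) standardGeneric("nContacts"))

#' @rdname alignmentPairs
#' @export
setGeneric("alignmentPairs", function(x) standardGeneric("alignmentPairs"))
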