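#' @include AllClasses.R
NULL

#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @export
setGeneric("batchId", function(x) standardGeneric("batchId"))
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))
#' @export
setGeneric("gamMatrix", function(x) standardGeneric("gamMatrix"))
#' @export
setGeneric("reversedGam", function(x) standardGeneric("reversedGam"))
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setGeneric("diffusionDistances", function(x) standardGeneric("diffusionDistances"))
#' @export
setGeneric("distanceDistributionMatrix",
           function(x) standardGeneric("distanceDistributionMatrix"))
#' @export
setGeneric("embeddings", function(x) standardGeneric("embeddings"))
#' @export
setGeneric("pseudoRna", function(x) standardGeneric("pseudoRna"))
#' @export
setGeneric("trainingTrace", function(x) standardGeneric("trainingTrace"))
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @export
setGeneric("backboneEdges", function(x) standardGeneric("backboneEdges"))
#' @export
setGeneric("trueGam", function(x) standardGeneric("trueGam"))
#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))
#' @export
setGeneric("atacCounts", function(x) standardGeneric("atacCounts"))
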