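#' @include AllGenerics.R
NULL

#' Construct an OmicsBatch
#'
#' @param counts cells x features matrix with cell ids as rownames and feature
#'   ids as colnames. A sparse `Matrix` is kept sparse.
#' @param modality `"RNA"` or `"ATAC"`.
#' @param batchId single string identifying the batch.
#' @param featureRanges optional `GRanges`, one range per feature (genes need
#'   strand for gene activity matrix construction).
#' @return An \linkS4class{OmicsBatch}.
#' @examples
#' m <- matrix(rpois(6, 2), 3, 2,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:2)))
#' OmicsBatch(m, "RNA", "batch1")
#' @export
OmicsBatch <- function(counts, modality, batchId, featureRanges = NULL) {
    new("OmicsBatch", counts = counts, modality = modality,
        batchId = batchId, featureRanges = featureRanges)
}

#' Construct a GeneActivityMatrix
#'
#' @param A binary regions x genes matrix with dimnames.
#' @return A \linkS4class{GeneActivityMatrix}.
#' @export
GeneActivityMatrix <- function(A) new("GeneActivityMatrix", A = A)

#' @describeIn OmicsBatch counts matrix accessor
#' @param object,x an `OmicsBatch`
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "OmicsBatch", function(object) object@counts)

#' @describeIn OmicsBatch modality accessor
#' @exportMethod modality
setMethod("modality", "OmicsBatch", function(x) x@modality)

#' @describeIn OmicsBatch batch id accessor
#' @exportMethod batchId
setMethod("batchId", "OmicsBatch", function(x) x@batchId)

#' @describeIn OmicsBatch cell ids (rownames of counts)
#' @exportMethod cellIds
setMethod("cellIds", "OmicsBatch", function(x) rownames(x@counts))

#' @describeIn OmicsBatch feature ids (colnames of counts)
#' @exportMethod featureIds
setMethod("featureIds", "OmicsBatch", function(x) colnames(x@counts))

#' @describeIn OmicsBatch feature coordinates (GRanges or NULL)
#' @exportMethod featureRanges
setMethod("featureRanges", "OmicsBatch", function(x) x@featureRanges)

setMethod("dim", "OmicsBatch", function(x) dim(x@counts))

setMethod("show", "OmicsBatch", function(object) {
    cat(sprintf("OmicsBatch '%s' (%s): %d cells x %d features\n",
                object@batchId, object@modality,
                nrow(object@counts), ncol(object@counts)))
    if (!is.null(object@featureRanges))
        cat("  feature coordinates: present\n")
})

#' @describeIn GeneActivityMatrix the binary prior A (regions x genes)
#' @param object,x a `GeneActivityMatrix`
#' @exportMethod gamMatrix
setMethod("gamMatrix", "GeneActivityMatrix", function(x) x@A)

#' @describeIn GeneActivityMatrix the element-wise reversal 1 - A, masking
#'   disallowed region-gene pairs
#' @exportMethod reversedGam
setMethod("reversedGam", "GeneActivityMatrix", function(x) {
    Ahat <- 1 - as.matrix(x@A)
    dimnames(Ahat) <- dimnames(x@A)
    Ahat
})

#' @describeIn GeneActivityMatrix region ids (rownames)
#' @exportMethod regionIds
setMethod("regionIds", "GeneActivityMatrix", function(x) rownames(x@A))

#' @describeIn GeneActivityMatrix gene ids (colnames)
#' @exportMethod geneIds
setMethod("geneIds", "GeneActivityMatrix", function(x) colnames(x@A))

setMethod("dim", "GeneActivityMatrix", function(x) dim(x@A))

setMethod("show", "GeneActivityMatrix", function(object) {
    A <- object@A
    cat(sprintf("GeneActivityMatrix: %d regions x %d genes, %.1f%% allowed\n",
                nrow(A), ncol(A), 100 * sum(A) / length(A)))
})

#' @describeIn DiffusionGeometry diffusion distance matrix accessor
#' @param object,x a `DiffusionGeometry`
#' @exportMethod diffusionDistances
setMethod("diffusionDistances", "DiffusionGeometry", function(x) x@D)

#' @describeIn DiffusionGeometry normalised distance distribution Q accessor
#' @exportMethod distanceDistributionMatrix
setMethod("distanceDistributionMatrix", "DiffusionGeometry", function(x) x@Q)

setMethod("show", "DiffusionGeometry", function(object) {
    cat(sprintf(
        "DiffusionGeometry over %d cells (k_nn=%d, alpha=%g, t={%s})\n",
        nrow(object@D), object@params$k_nn, object@params$alpha,
        paste(object@params$t_list, collapse = ",")))
})

setMethod("show", "TrainedModel", function(object) {
    d <- object@dims
    cat(sprintf(
        "TrainedModel: gene activity %d regions -> %s -> %d genes; projection %d -> %s -> %d\n",
        d[["n_regions"]], paste(object@config$hidden_gact, collapse = " -> "),
        d[["n_genes"]], d[["n_genes"]],
        paste(object@config$hidden_proj, collapse = " -> "), d[["n_latent"]]))
})

#' @describeIn IntegrationResult per-batch latent embeddings
#' @param object,x an `IntegrationResult`
#' @exportMethod embeddings
setMethod("embeddings", "IntegrationResult", function(x) x@embeddings)

#' @describeIn IntegrationResult predicted expression for ATAC batches
#' @exportMethod pseudoRna
setMethod("pseudoRna", "IntegrationResult", function(x) x@pseudoRna)

#' @describeIn IntegrationResult per-epoch loss component trace
#' @exportMethod trainingTrace
setMethod("trainingTrace", "IntegrationResult", function(x) x@trace)

setMethod("show", "IntegrationResult", function(object) {
    cat(sprintf("IntegrationResult: %d batches, latent dim %d\n",
                length(object@embeddings),
                object@model@dims[["n_latent"]]))
    for (nm in names(object@embeddings))
        cat(sprintf("  %s: %d cells\n", nm, nrow(object@embeddings[[nm]])))
})

#' @describeIn TrajectoryResult per-cell pseudotime in [0, 1]
#' @param object,x a `TrajectoryResult`
#' @exportMethod pseudotime
setMethod("pseudotime", "TrajectoryResult", function(x) x@pseudotime)

#' @describeIn TrajectoryResult per-cell branch labels
#' @exportMethod branches
setMethod("branches", "TrajectoryResult", function(x) x@branches)

#' @describeIn TrajectoryResult per-cell cluster labels
#' @exportMethod clusterLabels
setMethod("clusterLabels", "TrajectoryResult", function(x) x@clusters)

#' @describeIn TrajectoryResult MST edges over cluster centroids
#' @exportMethod backboneEdges
setMethod("backboneEdges", "TrajectoryResult", function(x) x@backbone)

setMethod("show", "TrajectoryResult", function(object) {
    cat(sprintf(
        "TrajectoryResult: %d cells, %d clusters, %d branches, root '%s'\n",
        length(object@clusters), length(unique(object@clusters)),
        length(unique(object@branches)), object@root))
})

#' @describeIn SimulationTruth true region-to-gene coupling
#' @param object,x a `SimulationTruth`
#' @exportMethod trueGam
setMethod("trueGam", "SimulationTruth", function(x) x@trueGam)

#' @describeIn SimulationTruth matched expression counts (N x G)
#' @exportMethod rnaCounts
setMethod("rnaCounts", "SimulationTruth", function(x) x@rnaCounts)

#' @describeIn SimulationTruth matched binary accessibility (N x R)
#' @exportMethod atacCounts
setMethod("atacCounts", "SimulationTruth", function(x) x@atacCounts)

#' @describeIn SimulationTruth true pseudotime per cell
#' @exportMethod pseudotime
setMethod("pseudotime", "SimulationTruth", function(x) x@pseudotime)

#' @describeIn SimulationTruth true branch label per cell
#' @exportMethod branches
setMethod("branches", "SimulationTruth", function(x) x@branch)

setMethod("show", "SimulationTruth", function(object) {
    cat(sprintf(
        "SimulationTruth: %d matched cells, %d genes, %d regions, %d branches\n",
        nrow(object@rnaCounts), ncol(object@rnaCounts),
        ncol(object@atacCounts), length(unique(object@branch))))
})
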