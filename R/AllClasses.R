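#' @import methods
#' @importFrom Matrix Matrix t rowSums colSums
#' @importFrom BiocGenerics counts
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Matrix Matrix
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))
setClassUnion("matrixOrMatrix", c("matrix", "Matrix"))

#' OmicsBatch: one modality's cell-by-feature count matrix
#'
#' Container for a single batch of one modality. Rows are cells, columns are
#' features (genes for RNA, accessible regions for ATAC). Feature genomic
#' coordinates, when known, are carried as a \linkS4class{GRanges} parallel to
#' the columns.
#'
#' @slot counts cells x features matrix (base or Matrix), non-negative.
#' @slot modality `"RNA"` or `"ATAC"`.
#' @slot batchId single string identifying the batch.
#' @slot featureRanges `GRanges` with one range per feature, or `NULL`.
#'
#' @seealso [OmicsBatch()] for the user constructor.
#' @exportClass OmicsBatch
setClass("OmicsBatch",
    slots = c(
        counts = "matrixOrMatrix",
        modality = "character",
        batchId = "character",
        featureRanges = "GRangesOrNULL"
    )
)

setValidity("OmicsBatch", function(object) {
    msg <- NULL
    x <- object@counts
    if (is.null(rownames(x)) || is.null(colnames(x)))
        msg <- c(msg, "counts must carry cell (row) and feature (column) names")
    else {
        if (anyDuplicated(rownames(x))) msg <- c(msg, "duplicate cell ids")
        if (anyDuplicated(colnames(x))) msg <- c(msg, "duplicate feature ids")
    }
    if (min(x) < 0) msg <- c(msg, "counts must be non-negative")
    if (!(object@modality %in% c("RNA", "ATAC")))
        msg <- c(msg, "modality must be 'RNA' or 'ATAC'")
    if (length(object@batchId) != 1L)
        msg <- c(msg, "batchId must be a single string")
    if (!is.null(object@featureRanges) &&
        length(object@featureRanges) != ncol(x))
        msg <- c(msg, "featureRanges must have one range per feature")
    if (is.null(msg)) TRUE else msg
})

#' GeneActivityMatrix: binary regions-by-genes prior
#'
#' Binary matrix `A` with `A[r, g] = 1` when region `r` is allowed to regulate
#' gene `g` (by genomic proximity or by simulation ground truth). The
#' element-wise reversal `1 - A` masks the disallowed entries and drives the
#' sparsity penalty on the learned gene activity function.
#'
#' @slot A binary regions x genes matrix with region ids as rownames and gene
#'   ids as colnames.
#'
#' @seealso [constructGam()], [gamPenalty()], [reversedGam()]
#' @exportClass GeneActivityMatrix
setClass("GeneActivityMatrix", slots = c(A = "matrixOrMatrix"))

setValidity("GeneActivityMatrix", function(object) {
    A <- object@A
    msg <- NULL
    if (is.null(rownames(A)) || is.null(colnames(A)))
        msg <- c(msg, "A must carry region (row) and gene (column) ids")
    v <- if (inherits(A, "Matrix")) A@x else as.vector(A)
    if (length(v) && !all(v %in% c(0, 1)))
        msg <- c(msg, "A entries must be 0 or 1")
    if (is.null(msg)) TRUE else msg
})

#' DiffusionGeometry: per-batch diffusion distances and their distribution
#'
#' Holds the adaptive-kernel similarity `K`, the row-stochastic transition
#' matrix `P`, the norm-averaged diffused operator `Pbar`, the diffusion
#' distance matrix `D` (pairwise Euclidean distances between rows of `Pbar`)
#' and the normalised distribution `Q = D / sum(D)` that the distance
#' preservation loss targets.
#'
#' @slot K,P,Pbar,D,Q square matrices over the same ordered cell set.
#' @slot params list echoing `k_nn`, `alpha`, `t_list` and the matrix norm
#'   used when averaging powers of `P`.
#' @exportClass DiffusionGeometry
setClass("DiffusionGeometry",
    slots = c(K = "matrix", P = "matrix", Pbar = "matrix",
              D = "matrix", Q = "matrix", params = "list")
)

setValidity("DiffusionGeometry", function(object) {
    n <- nrow(object@K)
    for (s in c("K", "P", "Pbar", "D", "Q")) {
        m <- slot(object, s)
        if (nrow(m) != n || ncol(m) != n)
            return(sprintf("slot %s is not %d x %d", s, n, n))
    }
    if (n > 0) {
        if (max(abs(rowSums(object@P) - 1)) > 1e-8)
            return("P rows must sum to 1")
        if (max(abs(object@D - t(object@D))) > 1e-8)
            return("D must be symmetric")
        if (any(diag(object@D) != 0)) return("D diagonal must be zero")
        if (min(object@D) < 0) return("D must be non-negative")
        if (abs(sum(object@Q) - 1) > 1e-8) return("Q must sum to 1")
    }
    TRUE
})

#' TrainedModel: parameters of the gene activity and projection networks
#'
#' The gene activity module maps region accessibility to pseudo-expression
#' through a three-layer bias-free multilayer perceptron; the projection
#' module maps (pseudo-)expression into the shared latent space. Layer
#' parameters and batch-normalisation statistics are stored as plain lists of
#' numeric matrices/vectors so that checkpoints are portable.
#'
#' @slot gact,proj lists of layers; each layer holds a weight matrix `W`
#'   (out x in) and, for hidden layers, batch-normalisation state.
#' @slot dims named integer vector: `n_regions`, `n_genes`, `n_latent`.
#' @slot seed integer seed the parameters were initialised from.
#' @slot config list echoing architecture hyperparameters.
#' @exportClass TrainedModel
setClass("TrainedModel",
    slots = c(gact = "list", proj = "list", dims = "integer",
              seed = "integer", config = "list")
)

setValidity("TrainedModel", function(object) {
    d <- object@dims
    need <- c("n_regions", "n_genes", "n_latent")
    if (!all(need %in% names(d))) return("dims must name n_regions, n_genes, n_latent")
    if (any(d[need] < 1)) return("all dims must be >= 1")
    if (ncol(object@gact[[1]]$W) != d[["n_regions"]])
        return("gact input dim != n_regions")
    ng <- nrow(object@gact[[length(object@gact)]]$W)
    if (ng != d[["n_genes"]]) return("gact output dim != n_genes")
    if (ncol(object@proj[[1]]$W) != d[["n_genes"]])
        return("proj input dim != gact output dim")
    if (nrow(object@proj[[length(object@proj)]]$W) != d[["n_latent"]])
        return("proj output dim != n_latent")
    TRUE
})

#' IntegrationResult: embeddings and transferred expression after training
#'
#' @slot embeddings named list of cells x d matrices, one per input batch
#'   (evaluation-mode forward pass; refined versions added by
#'   [refineEmbedding()] workflows).
#' @slot model the fitted \linkS4class{TrainedModel}.
#' @slot pseudoRna named list of cells x genes matrices, one per ATAC batch:
#'   expression predicted from accessibility by the gene activity module.
#' @slot trace data.frame of per-epoch loss components.
#' @slot batchInfo data.frame with one row per batch (name, modality, n cells).
#' @exportClass IntegrationResult
setClass("IntegrationResult",
    slots = c(embeddings = "list", model = "TrainedModel",
              pseudoRna = "list", trace = "data.frame",
              batchInfo = "data.frame")
)

#' TrajectoryResult: clusters, backbone, pseudotime and branches
#'
#' @slot clusters integer cluster label per cell.
#' @slot backbone data.frame of MST edges over cluster centroids
#'   (`from`, `to`, `weight`).
#' @slot centroids clusters x d matrix of centroid coordinates.
#' @slot pseudotime numeric per cell, min-max scaled to `[0, 1]`, 0 at the root.
#' @slot branches character branch label per cell.
#' @slot root name of the root cell.
#' @exportClass TrajectoryResult
setClass("TrajectoryResult",
    slots = c(clusters = "integer", backbone = "data.frame",
              centroids = "matrix", pseudotime = "numeric",
              branches = "character", root = "character")
)

setValidity("TrajectoryResult", function(object) {
    k <- length(unique(object@clusters))
    if (k > 1 && nrow(object@backbone) != k - 1)
        return("backbone must be a spanning tree (|edges| = |clusters| - 1)")
    n <- length(object@clusters)
    if (length(object@pseudotime) != n || length(object@branches) != n)
        return("per-cell slots must have equal length")
    TRUE
})

#' SimulationTruth: matched multi-omic data with full ground truth
#'
#' Matched scRNA-seq and scATAC-seq profiles of the same cells (identical row
#' order across modalities) generated along a known branching trajectory, with
#' the true binary region-to-gene coupling, true pseudotime and branch labels,
#' the latent identity vectors and the kinetic parameters.
#'
#' @slot rnaCounts N x G integer matrix.
#' @slot atacCounts N x R binary matrix.
#' @slot trueGam \linkS4class{GeneActivityMatrix} (R x G).
#' @slot pseudotime,branch per-cell truth.
#' @slot cellIdentity N x v, regionIdentity R x v latent identity matrices.
#' @slot kinetics list of kinetic parameter matrices (`k_on`, `k_off`, `s`).
#' @slot params list echoing generator settings and the seed.
#' @exportClass SimulationTruth
setClass("SimulationTruth",
    slots = c(rnaCounts = "matrix", atacCounts = "matrix",
              trueGam = "GeneActivityMatrix",
              pseudotime = "numeric", branch = "character",
              cellIdentity = "matrix", regionIdentity = "matrix",
              kinetics = "list", params = "list")
)

setValidity("SimulationTruth", function(object) {
    n <- nrow(object@rnaCounts)
    if (nrow(object@atacCounts) != n)
        return("rnaCounts and atacCounts must describe the same cells")
    if (!identical(rownames(object@rnaCounts), rownames(object@atacCounts)))
        return("matched row order required across modalities")
    if (length(object@pseudotime) != n || length(object@branch) != n)
        return("pseudotime/branch must have one value per cell")
    A <- gamMatrix(object@trueGam)
    if (nrow(A) != ncol(object@atacCounts) || ncol(A) != ncol(object@rnaCounts))
        return("trueGam must be regions x genes")
    TRUE
})
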