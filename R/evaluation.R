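#' Neighbourhood overlap of matched cells
#'
#' Builds a k-nearest-neighbour graph over the pooled embedding of both
#' batches and returns the fraction of matched cells whose partner from the
#' other modality lies within their `k` neighbours (counted over both
#' directions).
#'
#' @param Za,Zb embeddings of the two batches.
#' @param matching 2-column index matrix (`Za` row, `Zb` row); `NULL` means
#'   row `i` of `Za` matches row `i` of `Zb`.
#' @param k neighbourhood size (< pooled size).
#' @return Fraction in `[0, 1]`, non-decreasing in `k`.
#' @export
neighborhoodOverlap <- function(Za, Zb, matching = NULL, k = 30) {
    Za <- as.matrix(Za); Zb <- as.matrix(Zb)
    if (is.null(matching))
        matching <- cbind(seq_len(nrow(Za)), seq_len(nrow(Zb)))
    pooled <- rbind(Za, Zb)
    .assert(k < nrow(pooled), "k must be smaller than the pooled size")
    kth <- FNN::get.knn(pooled, k = k)$nn.dist[, k]
    na <- nrow(Za)
    # a partner is inside the neighbourhood iff it is at most as far as the
    # k-th neighbour (tie- and duplicate-robust)
    pd <- sqrt(rowSums((Za[matching[, 1], , drop = FALSE] -
                        Zb[matching[, 2], , drop = FALSE])^2))
    hit_a <- pd <= kth[matching[, 1]] + 1e-12
    hit_b <- pd <= kth[na + matching[, 2]] + 1e-12
    mean(c(hit_a, hit_b))
}

#' Mean cosine similarity of matched cell pairs
#'
#' @inheritParams neighborhoodOverlap
#' @return Mean cosine in `[-1, 1]`.
#' @export
cosineMatchingScore <- function(Za, Zb, matching = NULL) {
    Za <- as.matrix(Za); Zb <- as.matrix(Zb)
    if (is.null(matching))
        matching <- cbind(seq_len(nrow(Za)), seq_len(nrow(Zb)))
    a <- Za[matching[, 1], , drop = FALSE]
    b <- Zb[matching[, 2], , drop = FALSE]
    na_ <- sqrt(rowSums(a^2)); nb_ <- sqrt(rowSums(b^2))
    bad <- which(na_ == 0 | nb_ == 0)
    if (length(bad))
        stop("zero-norm embedding for matched pair(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    mean(rowSums(a * b) / (na_ * nb_))
}

#' Branch-assignment F1 score
#'
#' Jaccard similarity between every pair of true and inferred branches;
#' `recovery` is the mean over true branches of their maximum Jaccard with
#' any inferred branch, `relevance` the mean over inferred branches of their
#' maximum Jaccard with any true branch; the score is their harmonic mean.
#'
#' @param trueBranches,inferredBranches branch labels over the same cells.
#' @return F1 in `[0, 1]`; 1 iff the partitions coincide.
#' @export
branchF1 <- function(trueBranches, inferredBranches) {
    .assert(length(trueBranches) == length(inferredBranches),
            "partitions must cover the same cells")
    .assert(length(trueBranches) > 0, "empty partition")
    tl <- split(seq_along(trueBranches), trueBranches)
    il <- split(seq_along(inferredBranches), inferredBranches)
    J <- matrix(0, length(tl), length(il))
    for (i in seq_along(tl)) for (j in seq_along(il)) {
        inter <- length(intersect(tl[[i]], il[[j]]))
        J[i, j] <- inter / (length(tl[[i]]) + length(il[[j]]) - inter)
    }
    recovery <- mean(apply(J, 1, max))
    relevance <- mean(apply(J, 2, max))
    if (recovery == 0 || relevance == 0) return(0)
    2 / (1 / recovery + 1 / relevance)
}

#' Kendall rank correlation of pseudotimes
#'
#' Kendall's tau-b (tie-aware) between inferred and reference pseudotime.
#'
#' @param tTrue,tInferred numeric vectors of equal length >= 2.
#' @return Tau in `[-1, 1]`.
#' @export
pseudotimeKendall <- function(tTrue, tInferred) {
    .assert(length(tTrue) == length(tInferred) && length(tTrue) >= 2,
            "need two aligned vectors of length >= 2")
    if (stats::var(tTrue) == 0 || stats::var(tInferred) == 0)
        stop("constant pseudotime vector: correlation undefined",
             call. = FALSE)
    stats::cor(tTrue, tInferred, method = "kendall")
}

#' Cross-modality k-means consistency (ARI)
#'
#' Runs k-means separately on the two embeddings and scores the agreement of
#' the two label vectors over matched cells with the adjusted Rand index.
#' `nClusters` should be the number of ground-truth cell groups.
#'
#' @inheritParams neighborhoodOverlap
#' @param nClusters number of k-means clusters.
#' @param seed integer seed for both k-means runs.
#' @return ARI (1 = identical partitions, ~0 = chance).
#' @export
kmeansMatchingAri <- function(Za, Zb, matching = NULL, nClusters, seed = 0L) {
    Za <- as.matrix(Za); Zb <- as.matrix(Zb)
    .assert(nClusters <= min(nrow(Za), nrow(Zb)),
            "nClusters exceeds the number of cells")
    if (is.null(matching))
        matching <- cbind(seq_len(nrow(Za)), seq_len(nrow(Zb)))
    la <- .with_seed(as.integer(seed),
                     stats::kmeans(Za, nClusters, nstart = 10)$cluster)
    lb <- .with_seed(as.integer(seed),
                     stats::kmeans(Zb, nClusters, nstart = 10)$cluster)
    mclust::adjustedRandIndex(la[matching[, 1]], lb[matching[, 2]])
}

#' Best ARI over a Leiden resolution scan
#'
#' Leiden-clusters the embedding at each resolution in the grid and returns
#' the highest adjusted Rand index against the reference labels.
#'
#' @param Z joint embedding.
#' @param trueLabels reference labels per cell.
#' @param resolutions resolution grid (default `seq(0.1, 1, by = 0.5)`,
#'   i.e. 0.1 and 0.6).
#' @param knnK neighbourhood size of the cell graph.
#' @param seed clustering seed.
#' @return Maximum ARI across the scan.
#' @export
clusterAriScan <- function(Z, trueLabels, resolutions = seq(0.1, 1, by = 0.5),
                           knnK = 15, seed = 0L) {
    .assert(length(trueLabels) == nrow(Z), "labels must cover all cells")
    aris <- vapply(resolutions, function(res) {
        bb <- inferBackbone(Z, resolution = res, knnK = knnK, seed = seed)
        mclust::adjustedRandIndex(bb$clusters, trueLabels)
    }, 0)
    max(aris)
}

#' Graph connectivity of cell groups
#'
#' Builds a k-nearest-neighbour graph over all cells; for each label the
#' induced subgraph's largest connected component fraction is computed and
#' the fractions are averaged. High values mean cells sharing a label are
#' mixed into contiguous neighbourhoods rather than split by batch.
#'
#' @param Z joint embedding.
#' @param labels cell-type label per cell.
#' @param k neighbourhood size (default 15).
#' @return Score in `(0, 1]`.
#' @export
graphConnectivity <- function(Z, labels, k = 15) {
    Z <- as.matrix(Z)
    n <- nrow(Z)
    .assert(k < n, "k must be smaller than the number of cells")
    .assert(length(labels) == n, "labels must cover all cells")
    nn <- FNN::get.knn(Z, k = k)$nn.index
    el <- cbind(rep(seq_len(n), k), as.vector(nn))
    g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    scores <- vapply(unique(labels), function(lb) {
        idx <- which(labels == lb)
        sub <- igraph::induced_subgraph(g, idx)
        max(igraph::components(sub)$csize) / length(idx)
    }, 0)
    mean(scores)
}

#' Normalised mean squared error between expression profiles
#'
#' Each cell's profile is scaled to unit Euclidean norm in both matrices;
#' the score is the mean squared distance between the normalised rows
#' (range `[0, 4]`; 0 for proportional profiles, 2 for orthogonal unit
#' profiles).
#'
#' @param Xpred,Xtrue cells x genes matrices of identical shape.
#' @return Non-negative scalar.
#' @export
normalizedMse <- function(Xpred, Xtrue) {
    Xpred <- .as_dense(Xpred); Xtrue <- .as_dense(Xtrue)
    .assert(all(dim(Xpred) == dim(Xtrue)), "shape mismatch")
    np <- sqrt(rowSums(Xpred^2)); nt <- sqrt(rowSums(Xtrue^2))
    bad <- which(np == 0 | nt == 0)
    if (length(bad))
        stop("zero-norm profile for cell(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    mean(rowSums((Xpred / np - Xtrue / nt)^2))
}
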