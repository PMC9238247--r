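#' Infer the trajectory backbone on a joint embedding
#'
#' Leiden clustering on a k-nearest-neighbour graph of the embedding,
#' followed by a minimum spanning tree (Kruskal, lexicographic tie-break)
#' over the fully connected cluster-centroid graph weighted by Euclidean
#' distance. The MST over centroids summarises the branch topology.
#'
#' @param Z cells x d joint embedding (rownames used as cell ids).
#' @param resolution Leiden resolution (default 1).
#' @param knnK neighbourhood size of the cell graph (default 15).
#' @param seed clustering seed.
#' @return List with `clusters` (integer per cell), `centroids`
#'   (clusters x d) and `backbone` (data.frame `from`, `to`, `weight`;
#'   empty with a warning for a single cluster).
#' @export
inferBackbone <- function(Z, resolution = 1, knnK = 15, seed = 0L) {
    Z <- as.matrix(Z)
    n <- nrow(Z)
    .assert(n >= 2, "need at least 2 cells")
    knnK <- min(knnK, n - 1)
    nn <- FNN::get.knn(Z, k = knnK)$nn.index
    el <- cbind(rep(seq_len(n), knnK), as.vector(nn))
    g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    cl <- .with_seed(as.integer(seed),
        igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 3))
    clusters <- as.integer(igraph::membership(cl))
    k <- max(clusters)
    centroids <- rowsum(Z, clusters) / as.vector(table(clusters))
    rownames(centroids) <- seq_len(k)
    if (k == 1) {
        warning("single cluster: backbone is empty")
        backbone <- data.frame(from = integer(), to = integer(),
                               weight = numeric())
    } else {
        backbone <- .kruskal_mst(.pdist(centroids))
    }
    list(clusters = clusters, centroids = centroids, backbone = backbone)
}

# Kruskal MST on a dense symmetric weight matrix with deterministic
# (weight, from, to) edge ordering.
.kruskal_mst <- function(W) {
    k <- nrow(W)
    pairs <- which(upper.tri(W), arr.ind = TRUE)
    ord <- order(W[pairs], pairs[, 1], pairs[, 2])
    parent <- seq_len(k)
    find <- function(x) {
        while (parent[x] != x) x <- parent[x]
        x
    }
    edges <- matrix(0L, 0, 2)
    wts <- numeric()
    for (e in ord) {
        a <- pairs[e, 1]; b <- pairs[e, 2]
        ra <- find(a); rb <- find(b)
        if (ra != rb) {
            parent[ra] <- rb
            edges <- rbind(edges, c(a, b))
            wts <- c(wts, W[a, b])
            if (nrow(edges) == k - 1) break
        }
    }
    data.frame(from = edges[, 1], to = edges[, 2], weight = wts)
}

#' Diffusion pseudotime from a root cell
#'
#' Diffusion pseudotime on the embedding: the adaptive kernel defines a
#' random walk whose diffusion is accumulated over all scales — the
#' operator `sum_{t>=1} (P^t - stationary)`, evaluated spectrally with
#' weights `lambda / (1 - lambda)` on the walk's eigenvectors — and each
#' cell is assigned its accumulated diffusion distance from the root,
#' min-max scaled to `[0, 1]`. Accumulating over every scale (rather than a
#' fixed set of diffusion times) keeps the ordering stable as the number of
#' cells grows; distance along the latent manifold translates directly into
#' pseudotime.
#'
#' @param Z cells x d embedding.
#' @param root root cell: an index or a rowname of `Z`.
#' @param kNn,alpha kernel parameters (see [adaptiveKernel()]).
#' @param nComp number of spectral components of the walk to accumulate
#'   (default 50, capped at the number of cells minus one).
#' @return Numeric pseudotime per cell, 0 at the root.
#' @export
inferPseudotime <- function(Z, root, kNn = 5, alpha = 40, nComp = 50) {
    Z <- as.matrix(Z)
    n <- nrow(Z)
    if (is.character(root)) {
        root <- match(root, rownames(Z))
        .assert(!is.na(root), "root cell not found in rownames")
    }
    .assert(root >= 1 && root <= nrow(Z), "root index out of range")
    K <- adaptiveKernel(Z, kNn = kNn, alpha = alpha)
    adj <- K > .Machine$double.xmin
    comp <- igraph::components(
        igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    if (comp$no > 1)
        stop("kernel graph is disconnected (", comp$no,
             " components); increase kNn", call. = FALSE)
    deg <- rowSums(K)
    S <- K / sqrt(outer(deg, deg))          # symmetrised walk operator
    m <- min(nComp + 1, n)
    eg <- if (m < n / 2 && n > 200) {
        RSpectra::eigs_sym(S, k = m, which = "LA")
    } else {
        e <- eigen(S, symmetric = TRUE)
        list(values = e$values[seq_len(m)],
             vectors = e$vectors[, seq_len(m), drop = FALSE])
    }
    lam <- eg$values
    psi <- eg$vectors / sqrt(deg)           # right eigenvectors of P
    keep <- which(lam < 1 - 1e-10)          # drop the stationary mode
    w <- lam[keep] / (1 - lam[keep])
    coords <- psi[, keep, drop = FALSE] * rep(w, each = n)
    pt <- sqrt(rowSums((coords - rep(coords[root, ], each = n))^2))
    rng <- range(pt)
    if (rng[2] > rng[1]) pt <- (pt - rng[1]) / (rng[2] - rng[1])
    names(pt) <- rownames(Z)
    pt
}

#' Assign branch labels from a rooted backbone
#'
#' Roots the centroid MST at the root cluster and cuts it into maximal path
#' segments between nodes of degree != 2 (and the root); each cell inherits
#' the branch of its cluster.
#'
#' @param clusters integer cluster label per cell.
#' @param backbone MST edge data.frame from [inferBackbone()].
#' @param rootCluster cluster id the tree is rooted at.
#' @return Character branch label per cell.
#' @export
assignBranches <- function(clusters, backbone, rootCluster) {
    k <- max(clusters)
    if (k == 1 || nrow(backbone) == 0)
        return(rep("branch1", length(clusters)))
    adj <- vector("list", k)
    for (e in seq_len(nrow(backbone))) {
        a <- backbone$from[e]; b <- backbone$to[e]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    deg <- lengths(adj)
    node_branch <- integer(k)
    nb <- 0L
    node_branch[rootCluster] <- NA_integer_  # fixed after first child
    stack <- list(c(rootCluster, 0L))
    visited <- logical(k)
    visited[rootCluster] <- TRUE
    first_branch <- NA_integer_
    while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        node <- cur[1]
        for (child in adj[[node]]) {
            if (visited[child]) next
            visited[child] <- TRUE
            breakpoint <- node == rootCluster || deg[node] != 2
            if (breakpoint) {
                nb <- nb + 1L
                node_branch[child] <- nb
            } else {
                node_branch[child] <- node_branch[node]
            }
            if (is.na(first_branch)) first_branch <- node_branch[child]
            stack[[length(stack) + 1L]] <- c(child, node)
        }
    }
    node_branch[rootCluster] <- first_branch
    node_branch[is.na(node_branch) | node_branch == 0L] <- nb + 1L
    paste0("branch", node_branch[clusters])
}

#' Full trajectory inference on a joint embedding
#'
#' Convenience wrapper: backbone ([inferBackbone()]), pseudotime
#' ([inferPseudotime()]) and branch assignment ([assignBranches()]) in one
#' call.
#'
#' @param Z cells x d joint embedding with rownames.
#' @param root root cell index or name; when `NULL` and `anchors` is given,
#'   the cell nearest the anchor centroid; otherwise the cell farthest from
#'   the embedding medoid.
#' @param anchors optional indices of known root-region cells.
#' @param resolution,knnK,seed see [inferBackbone()].
#' @param kNn,alpha see [inferPseudotime()]. The sharply decaying
#'   kernel can disconnect a few outlying cells; when that happens the
#'   wrapper doubles `kNn` (up to 5 times, with a warning) until the kernel
#'   graph is connected.
#' @return A \linkS4class{TrajectoryResult}.
#' @export
inferTrajectory <- function(Z, root = NULL, anchors = NULL, resolution = 1,
                            knnK = 15, seed = 0L, kNn = 5, alpha = 40) {
    Z <- as.matrix(Z)
    if (is.null(rownames(Z))) rownames(Z) <- paste0("cell", seq_len(nrow(Z)))
    if (is.null(root)) {
        if (!is.null(anchors)) {
            ctr <- colMeans(Z[anchors, , drop = FALSE])
            root <- which.min(colSums((t(Z) - ctr)^2))
        } else {
            med <- which.min(rowSums(.pdist(Z)))
            root <- which.max(.pdist(Z)[med, ])
        }
    }
    if (is.character(root)) root <- match(root, rownames(Z))
    bb <- inferBackbone(Z, resolution = resolution, knnK = knnK, seed = seed)
    pt <- NULL
    for (try in 0:5) {
        pt <- tryCatch(
            inferPseudotime(Z, root, kNn = kNn * 2^try, alpha = alpha),
            error = function(e) {
                if (try == 5 || !grepl("disconnected", conditionMessage(e)))
                    stop(e)
                warning("kernel graph disconnected at kNn = ", kNn * 2^try,
                        "; retrying with ", kNn * 2^(try + 1), call. = FALSE)
                NULL
            })
        if (!is.null(pt)) break
    }
    br <- assignBranches(bb$clusters, bb$backbone, bb$clusters[root])
    new("TrajectoryResult", clusters = bb$clusters, backbone = bb$backbone,
        centroids = bb$centroids, pseudotime = pt, branches = br,
        root = rownames(Z)[root])
}
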