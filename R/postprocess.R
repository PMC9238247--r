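#' Mutual nearest neighbour graph between two embeddings
#'
#' Cross-batch edges `(i, j)` exist iff `j` is among the `k` nearest
#' neighbours of `i` within `Zb` and `i` is among the `k` nearest neighbours
#' of `j` within `Za`; edge weights are `exp(-||z_a(i) - z_b(j)||^2)`.
#'
#' @param Za,Zb cells x d embeddings of two batches (same d).
#' @param k neighbourhood size (default 10; clipped with a warning when it
#'   reaches a batch size).
#' @return List with `edges` (data.frame `from`, `to`, `weight`; `from`
#'   indexes `Za`, `to` indexes `Zb`) and `k`.
#' @export
buildMnnGraph <- function(Za, Zb, k = 10) {
    Za <- as.matrix(Za); Zb <- as.matrix(Zb)
    .assert(ncol(Za) == ncol(Zb), "latent dimensions differ")
    kmax <- min(nrow(Za), nrow(Zb))
    if (k >= kmax) {
        warning("k clipped from ", k, " to ", kmax - 1)
        k <- kmax - 1
    }
    nn_ab <- FNN::get.knnx(Zb, Za, k = k)$nn.index   # rows of Za -> Zb
    nn_ba <- FNN::get.knnx(Za, Zb, k = k)$nn.index   # rows of Zb -> Za
    from <- rep(seq_len(nrow(Za)), each = k)
    to <- as.vector(t(nn_ab))
    mutual <- vapply(seq_along(from), function(e)
        from[e] %in% nn_ba[to[e], ], TRUE)
    from <- from[mutual]; to <- to[mutual]
    w <- exp(-rowSums((Za[from, , drop = FALSE] -
                       Zb[to, , drop = FALSE])^2))
    list(edges = data.frame(from = from, to = to, weight = w), k = k)
}

#' Refine embeddings along the mutual nearest neighbour graph
#'
#' Replaces each cell that has at least one mutual cross-batch neighbour by
#' the weight-averaged embedding of those neighbours; isolated cells keep
#' their position. Both batches are updated symmetrically from the original
#' (pre-refinement) embeddings. The smoothing pulls matched regions of the
#' two batches onto each other, sharpening branch structure before
#' trajectory inference.
#'
#' @param Za,Zb embeddings the graph was built on.
#' @param graph result of [buildMnnGraph()] (built internally when `NULL`).
#' @param k neighbourhood size when building internally.
#' @return List with refined `Za` and `Zb`.
#' @export
refineEmbedding <- function(Za, Zb, graph = NULL, k = 10) {
    Za <- as.matrix(Za); Zb <- as.matrix(Zb)
    if (is.null(graph)) graph <- buildMnnGraph(Za, Zb, k = k)
    e <- graph$edges
    Za2 <- Za
    Zb2 <- Zb
    if (nrow(e)) {
        wsum_a <- rowsum(e$weight, e$from)
        acc_a <- rowsum(Zb[e$to, , drop = FALSE] * e$weight, e$from)
        ia <- as.integer(rownames(wsum_a))
        Za2[ia, ] <- acc_a / as.vector(wsum_a)
        wsum_b <- rowsum(e$weight, e$to)
        acc_b <- rowsum(Za[e$from, , drop = FALSE] * e$weight, e$to)
        ib <- as.integer(rownames(wsum_b))
        Zb2[ib, ] <- acc_b / as.vector(wsum_b)
    }
    list(Za = Za2, Zb = Zb2)
}

#' Refine a set of batch embeddings pairwise
#'
#' Applies [refineEmbedding()] to every pair of batches using the original
#' embeddings throughout, then averages each cell's proposed updates over the
#' pairs in which it found mutual neighbours.
#'
#' @param zList named list of embeddings.
#' @param k neighbourhood size.
#' @return List of refined embeddings, same names and shapes.
#' @export
refineEmbeddings <- function(zList, k = 10) {
    nb <- length(zList)
    if (nb < 2) return(zList)
    acc <- lapply(zList, function(z) z * 0)
    cnt <- lapply(zList, function(z) numeric(nrow(z)))
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
        g <- buildMnnGraph(zList[[i]], zList[[j]], k = k)
        r <- refineEmbedding(zList[[i]], zList[[j]], g)
        touched_i <- unique(g$edges$from)
        touched_j <- unique(g$edges$to)
        acc[[i]][touched_i, ] <- acc[[i]][touched_i, , drop = FALSE] +
            r$Za[touched_i, , drop = FALSE]
        cnt[[i]][touched_i] <- cnt[[i]][touched_i] + 1
        acc[[j]][touched_j, ] <- acc[[j]][touched_j, , drop = FALSE] +
            r$Zb[touched_j, , drop = FALSE]
        cnt[[j]][touched_j] <- cnt[[j]][touched_j] + 1
    }
    out <- zList
    for (i in seq_len(nb)) {
        got <- cnt[[i]] > 0
        out[[i]][got, ] <- acc[[i]][got, , drop = FALSE] / cnt[[i]][got]
    }
    out
}
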