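#' Reduce a batch to a low-dimensional representation
#'
#' RNA batches are reduced with PCA on the centred (preprocessed) matrix;
#' ATAC batches with latent semantic indexing: TF-IDF weighting of the binary
#' matrix followed by truncated SVD. The TF-IDF form is
#' `tf = x / rowSums(x)` and `idf = log(1 + N / df) - log(2)`, so a region
#' accessible in every cell carries zero weight. In both cases the returned
#' coordinates are the singular-vector scores `U %*% diag(d)`.
#'
#' @param batch a preprocessed \linkS4class{OmicsBatch}.
#' @param r target dimension (default 30).
#' @param dropFirst for LSI only: drop the first component, which often
#'   tracks library depth in real data (default `FALSE`).
#' @return A list with `coords` (cells x r matrix), `method` (`"PCA"` or
#'   `"LSI"`) and `r`.
#' @export
reduceDimension <- function(batch, r = 30, dropFirst = FALSE) {
    x <- .as_dense(counts(batch))
    .assert(r >= 2, "r must be >= 2")
    rank_cap <- min(dim(x))
    .assert(r <= rank_cap, "r = %d exceeds min(dim) = %d", r, rank_cap)
    if (modality(batch) == "RNA") {
        xc <- scale(x, center = TRUE, scale = FALSE)
        coords <- .trunc_svd_scores(xc, r)
        method <- "PCA"
    } else {
        tf <- x / pmax(rowSums(x), 1)
        df <- colSums(x > 0)
        idf <- ifelse(df > 0, log1p(nrow(x) / df) - log(2), 0)
        w <- sweep(tf, 2, idf, "*")
        k <- if (dropFirst) r + 1 else r
        .assert(k <= rank_cap, "r too large for dropFirst on this matrix")
        coords <- .trunc_svd_scores(w, k)
        if (dropFirst) coords <- coords[, -1, drop = FALSE]
        method <- "LSI"
    }
    rownames(coords) <- rownames(x)
    .assert(all(is.finite(coords)), "non-finite coordinates produced")
    list(coords = coords, method = method, r = ncol(coords))
}

# Scores of the top-r singular triplets; exact svd for small problems,
# seeded irlba otherwise.
.trunc_svd_scores <- function(x, r) {
    if (r >= min(dim(x)) - 2 || min(dim(x)) < 100) {
        s <- svd(x, nu = r, nv = 0)
        s$u %*% diag(s$d[seq_len(r)], r)
    } else {
        s <- .with_seed(1L, irlba::irlba(x, nv = r))
        s$u %*% diag(s$d, r)
    }
}

#' Adaptive-bandwidth similarity kernel
#'
#' Symmetric cell-cell similarity with a per-cell adaptive bandwidth:
#' `K(i, j) = 0.5 exp(-(d_ij / sigma_i)^alpha) + 0.5 exp(-(d_ij / sigma_j)^alpha)`
#' where `sigma_i` is the distance from cell `i` to its `kNn`-th nearest
#' neighbour (proportionality constant 1) and `alpha` controls how sharply
#' similarity decays outside the adaptive neighbourhood. A zero bandwidth
#' (at least `kNn` exact duplicates) falls back to the smallest positive
#' neighbour distance.
#'
#' @param rep a reduced representation as returned by [reduceDimension()],
#'   or a plain cells x r coordinate matrix.
#' @param kNn neighbour index defining the bandwidth (default 5).
#' @param alpha decay exponent (default 40).
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
adaptiveKernel <- function(rep, kNn = 5, alpha = 40) {
    x <- if (is.list(rep)) rep$coords else rep
    n <- nrow(x)
    .assert(n >= kNn + 1, "need at least kNn + 1 cells")
    d <- .pdist(x)
    sigma <- apply(d, 1, function(row) sort(row)[kNn + 1]) # row[1] is self
    if (any(sigma == 0)) {
        pos_min <- apply(d, 1, function(row) {
            p <- row[row > 0]
            if (length(p)) min(p) else 0
        })
        sigma[sigma == 0] <- pos_min[sigma == 0]
        if (any(sigma == 0))
            stop("all cells are identical; kernel is degenerate", call. = FALSE)
    }
    K <- 0.5 * exp(-(d / sigma)^alpha) + 0.5 * exp(-t(t(d) / sigma)^alpha)
    K <- (K + t(K)) / 2
    diag(K) <- 1
    dimnames(K) <- list(rownames(x), rownames(x))
    K
}

#' Diffusion distances from a similarity kernel
#'
#' Row-normalises `K` into a transition matrix `P`, diffuses it to several
#' scales `t`, averages the normalised powers
#' `Pbar = sum_t P^t / ||P^t||` (Frobenius norm by default), and takes the
#' pairwise Euclidean distances between the rows of `Pbar` as the diffusion
#' distance matrix `D`. Multiple `t` values blend local and global structure
#' instead of committing to one diffusion scale. The normalised distribution
#' `Q = D / sum(D)` is the target of the distance-preservation loss.
#'
#' @param K symmetric non-negative similarity matrix with positive row sums.
#' @param tList diffusion times (default `c(30, 50, 70)`).
#' @param norm `"frobenius"` (default) or `"spectral"` norm for scaling the
#'   powered operators.
#' @param params optional list recorded into the result (e.g. kernel
#'   settings).
#' @return A \linkS4class{DiffusionGeometry}.
#' @export
diffusionDistance <- function(K, tList = c(30, 50, 70),
                              norm = c("frobenius", "spectral"),
                              params = list()) {
    norm <- match.arg(norm)
    .assert(nrow(K) == ncol(K), "K must be square")
    .assert(min(K) >= 0, "K must be non-negative")
    rs <- rowSums(K)
    .assert(all(rs > 0), "K must have positive row sums")
    P <- K / rs
    powers <- .matrix_powers(P, as.integer(tList))
    Pbar <- 0
    for (Pt in powers) {
        nf <- if (norm == "frobenius") sqrt(sum(Pt^2)) else .spectral_norm(Pt)
        Pbar <- Pbar + Pt / nf
    }
    D <- .pdist(Pbar)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    dimnames(D) <- dimnames(K)
    new("DiffusionGeometry", K = K, P = P, Pbar = Pbar, D = D,
        Q = distanceDistribution(D),
        params = utils::modifyList(
            list(k_nn = 5L, alpha = 40, t_list = tList, norm = norm), params))
}

# All requested powers of P via shared repeated squaring.
.matrix_powers <- function(P, ts) {
    maxbit <- floor(log2(max(ts)))
    sq <- vector("list", maxbit + 1)
    sq[[1]] <- P
    for (b in seq_len(maxbit)) sq[[b + 1]] <- sq[[b]] %*% sq[[b]]
    lapply(ts, function(t) {
        bits <- which(intToBits(t)[seq_len(maxbit + 1)] == 1)
        acc <- sq[[bits[1]]]
        for (b in bits[-1]) acc <- acc %*% sq[[b]]
        acc
    })
}

.spectral_norm <- function(x) {
    if (min(dim(x)) < 100) return(max(svd(x, nu = 0, nv = 0)$d))
    .with_seed(1L, irlba::irlba(x, nv = 1)$d[1])
}

#' Normalised distance distribution
#'
#' `Q = D / sum(D)`: the distance matrix rescaled into a distribution over
#' cell pairs, invariant to any uniform rescaling of `D`.
#'
#' @param D non-negative distance matrix, not all zero.
#' @return Matrix `Q` with `sum(Q) == 1`.
#' @export
distanceDistribution <- function(D) {
    s <- sum(D)
    .assert(min(D) >= 0, "D must be non-negative")
    if (s == 0)
        stop("degenerate geometry: all distances are zero", call. = FALSE)
    D / s
}
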