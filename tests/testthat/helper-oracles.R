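# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity with naive loops / enumeration
# and stay independent of the package's code paths.

# Diffusion distances computed the slow way: explicit kernel, naive
# matrix-power loop, Frobenius-scaled averaging, elementwise distances.
oracle_diffusion <- function(coords, k_nn = 2, alpha = 40,
                             t_list = c(30, 50, 70)) {
    n <- nrow(coords)
    d <- as.matrix(stats::dist(coords))
    sigma <- numeric(n)
    for (i in seq_len(n)) sigma[i] <- sort(d[i, -i])[k_nn]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        K[i, j] <- 0.5 * exp(-(d[i, j] / sigma[i])^alpha) +
                   0.5 * exp(-(d[i, j] / sigma[j])^alpha)
    K <- (K + t(K)) / 2
    diag(K) <- 1
    P <- K / rowSums(K)
    Pbar <- matrix(0, n, n)
    for (t in t_list) {
        Pt <- diag(n)
        for (s in seq_len(t)) Pt <- Pt %*% P
        Pbar <- Pbar + Pt / sqrt(sum(Pt^2))
    }
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        D[i, j] <- sqrt(sum((Pbar[i, ] - Pbar[j, ])^2))
    list(K = K, D = D)
}

# Biased MMD by explicit double loops.
oracle_mmd <- function(Z1, Z2, gammas) {
    kern <- function(a, b, g) exp(-sum((a - b)^2) / (2 * g))
    total <- 0
    for (g in gammas) {
        s11 <- 0
        for (i in seq_len(nrow(Z1))) for (j in seq_len(nrow(Z1)))
            s11 <- s11 + kern(Z1[i, ], Z1[j, ], g)
        s22 <- 0
        for (i in seq_len(nrow(Z2))) for (j in seq_len(nrow(Z2)))
            s22 <- s22 + kern(Z2[i, ], Z2[j, ], g)
        s12 <- 0
        for (i in seq_len(nrow(Z1))) for (j in seq_len(nrow(Z2)))
            s12 <- s12 + kern(Z1[i, ], Z2[j, ], g)
        total <- total + s11 / nrow(Z1)^2 + s22 / nrow(Z2)^2 -
            2 * s12 / (nrow(Z1) * nrow(Z2))
    }
    total
}

# Branch F1 with explicit double-loop Jaccard computation.
oracle_f1 <- function(true_lab, inf_lab) {
    tu <- unique(true_lab); iu <- unique(inf_lab)
    jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
    Jt <- sapply(tu, function(tb) max(sapply(iu, function(ib)
        jac(which(true_lab == tb), which(inf_lab == ib)))))
    Ji <- sapply(iu, function(ib) max(sapply(tu, function(tb)
        jac(which(true_lab == tb), which(inf_lab == ib)))))
    rec <- mean(Jt); rel <- mean(Ji)
    2 / (1 / rec + 1 / rel)
}

# Minimum spanning tree weight by exhaustive enumeration of edge subsets.
oracle_mst_weight <- function(W) {
    k <- nrow(W)
    pairs <- which(upper.tri(W), arr.ind = TRUE)
    best <- Inf
    for (sub in utils::combn(nrow(pairs), k - 1, simplify = FALSE)) {
        # spanning check via repeated merging
        comp <- seq_len(k)
        for (e in sub) {
            a <- comp[pairs[e, 1]]; b <- comp[pairs[e, 2]]
            comp[comp == b] <- a
        }
        if (length(unique(comp)) == 1)
            best <- min(best, sum(W[pairs[sub, , drop = FALSE]]))
    }
    best
}

# Mutual nearest neighbour edges by O(n^2) scanning.
oracle_mnn <- function(Za, Zb, k) {
    knn_of <- function(query, data) {
        t(apply(query, 1, function(q)
            order(colSums((t(data) - q)^2))[seq_len(k)]))
    }
    ab <- knn_of(Za, Zb)
    ba <- knn_of(Zb, Za)
    edges <- NULL
    for (i in seq_len(nrow(Za))) for (j in ab[i, ])
        if (i %in% ba[j, ]) edges <- rbind(edges, c(i, j))
    edges
}

# Gaussian log-likelihood ratio for one feature, fitted with lm()/logLik().
oracle_lrt <- function(y, t, degree = 4) {
    alt <- stats::lm(y ~ splines::bs(t, degree = degree))
    null <- stats::lm(y ~ 1)
    2 * (as.numeric(stats::logLik(alt)) - as.numeric(stats::logLik(null)))
}

# Well-separated Gaussian blobs.
make_blobs <- function(centers, n_per, sd = 0.05, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
        matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
            matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
}
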