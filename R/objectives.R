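#' Multi-scale kernel bandwidth grid
#'
#' The Gaussian-kernel bandwidths the alignment loss is summed over:
#' `10^u` for integer `u` from -6 to 6 (13 values).
#'
#' @return Numeric vector of 13 strictly positive bandwidths.
#' @export
gammaGrid <- function() 10^(-6:6)

#' Loss term weights
#'
#' @param lambdaMmd weight of the distribution-alignment (MMD) term
#'   (default 1).
#' @param lambdaG weight of the gene-activity sparsity penalty (default 1).
#' @param anchorWeight weight of the anchor loss (fixed default 1).
#' @return A named list of validated non-negative weights.
#' @export
lossWeights <- function(lambdaMmd = 1, lambdaG = 1, anchorWeight = 1) {
    .assert(lambdaMmd >= 0 && lambdaG >= 0 && anchorWeight >= 0,
            "loss weights must be non-negative")
    list(lambdaMmd = lambdaMmd, lambdaG = lambdaG,
         anchorWeight = anchorWeight)
}

#' Distance-preservation loss
#'
#' Kullback-Leibler divergence `KL(Q_Z || Q_X)` between the normalised
#' pairwise-distance distribution of the embedding
#' (`Q_Z = D_Z / sum(D_Z)`, Euclidean) and the target diffusion-distance
#' distribution `Q_X`. Diagonal entries (structural zeros) are excluded and a
#' stabiliser `eps` is added inside the logarithms. The asymmetry of the KL
#' divergence penalises placing far-apart cells close together more than the
#' reverse, which preserves local manifold structure.
#'
#' @param Z cells x d embedding, rows aligned with `Q_X`.
#' @param Qx normalised target distribution matrix (non-negative; renormalised
#'   internally so its off-diagonal mass is 1, which makes minibatch
#'   submatrices of a full-data `Q` directly usable).
#' @param eps log stabiliser (default 1e-12).
#' @return Scalar loss (non-negative up to `eps` effects).
#' @export
distanceLoss <- function(Z, Qx, eps = 1e-12) {
    Z <- as.matrix(Z)
    n <- nrow(Z)
    .assert(n >= 3, "distance loss needs at least 3 cells")
    .assert(all(dim(Qx) == n), "Q_X must be %d x %d", n, n)
    .distance_loss_core(Z, Qx, eps, grad = FALSE)$value
}

.distance_loss_core <- function(Z, Qx, eps, grad) {
    n <- nrow(Z)
    Qx <- as.matrix(Qx)
    diag(Qx) <- 0
    sx <- sum(Qx)
    if (sx <= 0)
        stop("Q_X has zero off-diagonal mass", call. = FALSE)
    Qx <- Qx / sx
    D <- .pdist(Z)
    S <- sum(D)
    if (S == 0)
        stop("degenerate embedding: all cells coincide", call. = FALSE)
    Qz <- D / S
    G <- log(Qz + eps) - log(Qx + eps)
    diag(G) <- 0
    value <- sum(Qz * G)
    if (!grad) return(list(value = value))
    # dL/dQz = G + Qz/(Qz+eps); dL/dD = (g - sum(g*Qz))/S; chain to Z.
    g <- G + Qz / (Qz + eps)
    diag(g) <- 0
    dD <- (g - sum(g * Qz)) / S
    diag(dD) <- 0
    W <- dD + t(dD)
    pos <- D > 0
    W[pos] <- W[pos] / D[pos]
    W[!pos] <- 0
    dZ <- Z * rowSums(W) - W %*% Z
    list(value = value, dZ = dZ)
}

#' Maximum mean discrepancy between two embeddings
#'
#' Biased (V-statistic) MMD with a Gaussian kernel
#' `K(a, b) = exp(-||a - b||^2 / (2 gamma))`, summed over the bandwidth grid:
#' `sum_gamma E[K(Z1, Z1)] + E[K(Z2, Z2)] - 2 E[K(Z1, Z2)]`, where the
#' expectations are plain means over all pairs including self-pairs. Zero
#' when the two point sets are identical; summing over bandwidths makes the
#' term sensitive at every scale without tuning.
#'
#' @param Z1,Z2 point sets (rows) with the same dimension.
#' @param gammas bandwidth grid (default [gammaGrid()]).
#' @return Scalar loss, non-negative.
#' @export
mmdLoss <- function(Z1, Z2, gammas = gammaGrid()) {
    Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2)
    .assert(nrow(Z1) > 0 && nrow(Z2) > 0, "point sets must be non-empty")
    .assert(ncol(Z1) == ncol(Z2), "dimension mismatch")
    d11 <- .pdist2(Z1); d22 <- .pdist2(Z2); d12 <- .pdist2(Z1, Z2)
    total <- 0
    for (g in gammas) {
        total <- total + mean(exp(-d11 / (2 * g))) +
            mean(exp(-d22 / (2 * g))) - 2 * mean(exp(-d12 / (2 * g)))
    }
    total
}

# MMD value + gradients w.r.t. both point sets, over the decade bandwidth
# grid. Exploits the grid structure: K(gamma/10) = K(gamma)^10 elementwise,
# so most kernels are derived by four elementwise squarings/products from the
# previous decade instead of a fresh exp(); the exponential is recomputed
# every third decade to keep accumulated rounding below ~1e-13. Two provable
# shortcuts: bandwidths whose kernels are within `tol` of all-ones contribute
# |MMD| <= 2*tol and gradient of the same order (skipped); bandwidths where
# every off-diagonal kernel entry underflows to exactly 0 contribute exactly
# 1/n1 + 1/n2 with zero gradient (closed form, shared by all smaller
# bandwidths).
.mmd_loss_grad <- function(Z1, Z2, gammas = gammaGrid(), tol = 1e-9) {
    n1 <- nrow(Z1); n2 <- nrow(Z2)
    d11 <- .pdist2(Z1); d22 <- .pdist2(Z2); d12 <- .pdist2(Z1, Z2)
    maxd <- max(max(d11), max(d22), max(d12))
    offmin <- min(min(d11[upper.tri(d11)], Inf),
                  min(d22[upper.tri(d22)], Inf), min(d12))
    value <- 0
    dZ1 <- matrix(0, n1, ncol(Z1))
    dZ2 <- matrix(0, n2, ncol(Z2))
    gammas <- sort(gammas, decreasing = TRUE)
    pow10 <- function(K) {
        K2 <- K * K; K8 <- K2 * K2; K8 <- K8 * K8
        K8 * K2
    }
    prev_g <- NA_real_
    chain <- 0L
    K11 <- K22 <- K12 <- NULL
    for (gi in seq_along(gammas)) {
        g <- gammas[gi]
        if (maxd / (2 * g) < tol) { prev_g <- NA_real_; next }
        if (offmin / (2 * g) > 746) {
            value <- value + (length(gammas) - gi + 1) * (1 / n1 + 1 / n2)
            break
        }
        if (!is.na(prev_g) && isTRUE(all.equal(prev_g / 10, g)) &&
            chain < 3L) {
            K11 <- pow10(K11); K22 <- pow10(K22); K12 <- pow10(K12)
            chain <- chain + 1L
        } else {
            K11 <- exp(-d11 / (2 * g)); K22 <- exp(-d22 / (2 * g))
            K12 <- exp(-d12 / (2 * g))
            chain <- 0L
        }
        prev_g <- g
        value <- value + mean(K11) + mean(K22) - 2 * mean(K12)
        dZ1 <- dZ1 - (2 / (n1^2 * g)) * (Z1 * rowSums(K11) - K11 %*% Z1) +
            (2 / (n1 * n2 * g)) * (Z1 * rowSums(K12) - K12 %*% Z2)
        dZ2 <- dZ2 - (2 / (n2^2 * g)) * (Z2 * rowSums(K22) - K22 %*% Z2) +
            (2 / (n1 * n2 * g)) * (Z2 * colSums(K12) - crossprod(K12, Z1))
    }
    list(value = value, dZ1 = dZ1, dZ2 = dZ2)
}

#' Sparsity penalty tying the gene activity module to the prior
#'
#' L1 norm of the network's end-to-end linear map restricted to region-gene
#' pairs that the prior disallows: `|| M * (1 - A) ||_1` with
#' `M = effectiveLinearMap(model)`. Zeros in the prior are treated as
#' trustworthy (no regulation), ones as merely permitted, so only the
#' disallowed entries are penalised.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param gam a \linkS4class{GeneActivityMatrix} with `n_regions` rows and
#'   `n_genes` columns.
#' @return Scalar penalty, zero iff `M` vanishes on all disallowed pairs.
#' @export
gamPenalty <- function(model, gam) {
    M <- effectiveLinearMap(model)
    Ahat <- reversedGam(gam)
    .assert(all(dim(M) == dim(Ahat)),
            "prior is %d x %d but model implies %d x %d",
            nrow(Ahat), ncol(Ahat), nrow(M), ncol(M))
    sum(abs(M) * Ahat)
}

# Penalty value + gradients for every gact weight matrix.
# P = W_L ... W_1 (genes x regions); dP = t(sign(M) * Ahat);
# dW_i = t(W_L..W_{i+1}) dP t(W_{i-1}..W_1).
.gam_penalty_grad <- function(gact, Ahat) {
    L <- length(gact)
    Ws <- lapply(gact, `[[`, "W")
    prefix <- vector("list", L)   # prefix[[i]] = W_{i-1} ... W_1 (NULL if i=1)
    acc <- NULL
    for (i in seq_len(L)) {
        prefix[i] <- list(acc)
        acc <- if (is.null(acc)) Ws[[i]] else Ws[[i]] %*% acc
    }
    suffix <- vector("list", L)   # suffix[[i]] = W_L ... W_{i+1} (NULL if i=L)
    acc <- NULL
    for (i in rev(seq_len(L))) {
        suffix[i] <- list(acc)
        acc <- if (is.null(acc)) Ws[[i]] else acc %*% Ws[[i]]
    }
    P <- acc                       # genes x regions
    M <- t(P)
    value <- sum(abs(M) * Ahat)
    dP <- t(sign(M) * Ahat)
    grads <- vector("list", L)
    for (i in seq_len(L)) {
        d <- dP
        if (!is.null(suffix[[i]])) d <- crossprod(suffix[[i]], d)
        if (!is.null(prefix[[i]])) d <- d %*% t(prefix[[i]])
        grads[[i]] <- d
    }
    list(value = value, grads = grads)
}

#' Anchor alignment loss
#'
#' Squared Euclidean distance between the mean latent embeddings of the
#' anchor cells of the two batches. Anchors are cells with known
#' cross-modality identity (typically trajectory root cells); pulling their
#' group means together pins the otherwise rotation-free alignment.
#'
#' @param zRna,zAtac anchors x d embedding matrices (non-empty).
#' @return Scalar loss.
#' @export
anchorLoss <- function(zRna, zAtac) {
    zRna <- as.matrix(zRna); zAtac <- as.matrix(zAtac)
    .assert(nrow(zRna) > 0 && nrow(zAtac) > 0,
            "anchor sets must be non-empty")
    sum((colMeans(zRna) - colMeans(zAtac))^2)
}

.anchor_loss_grad <- function(zRna, zAtac) {
    delta <- colMeans(zRna) - colMeans(zAtac)
    list(value = sum(delta^2),
         dRna = matrix(2 * delta / nrow(zRna), nrow(zRna),
                       length(delta), byrow = TRUE),
         dAtac = matrix(-2 * delta / nrow(zAtac), nrow(zAtac),
                        length(delta), byrow = TRUE))
}

#' Per-modality composite objective
#'
#' Evaluation-mode value of the full training objective for one side:
#' the side's distance-preservation loss plus the weighted alignment,
#' gene-activity-penalty and (optional) anchor terms. Returned with the
#' per-term breakdown used for logging.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param side `"ATAC"` or `"RNA"`: which batch's distance loss enters.
#' @param xRna cells x genes log-normalised expression.
#' @param xAtac cells x regions binary accessibility.
#' @param qRna,qAtac normalised target distance distributions for the
#'   respective batches (the one matching `side` is required).
#' @param gam the gene activity prior.
#' @param weights a [lossWeights()] list.
#' @param anchorRna,anchorAtac optional row indices of anchor cells in the
#'   respective batches.
#' @return List with `total` and `components` (named numeric vector).
#' @export
compositeLoss <- function(model, side = c("ATAC", "RNA"), xRna, xAtac,
                          qRna = NULL, qAtac = NULL, gam,
                          weights = lossWeights(),
                          anchorRna = NULL, anchorAtac = NULL) {
    side <- match.arg(side)
    pseudo <- geneActivityForward(model, xAtac)
    zAtac <- projectCells(model, pseudo)
    zRna <- projectCells(model, xRna)
    q <- if (side == "ATAC") qAtac else qRna
    if (is.null(q))
        stop("missing Q target for the ", side, " side", call. = FALSE)
    ldist <- distanceLoss(if (side == "ATAC") zAtac else zRna, q)
    lmmd <- mmdLoss(zRna, zAtac)
    lgam <- gamPenalty(model, gam)
    comp <- c(dist = ldist, mmd = weights$lambdaMmd * lmmd,
              gam = weights$lambdaG * lgam)
    if (!is.null(anchorRna) && !is.null(anchorAtac)) {
        comp <- c(comp, anchor = weights$anchorWeight *
                      anchorLoss(zRna[anchorRna, , drop = FALSE],
                                 zAtac[anchorAtac, , drop = FALSE]))
    }
    list(total = sum(comp), components = comp)
}
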