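test_that("PCA preserves distances for data of matching rank and maps duplicates together", {
    set.seed(1)
    # non-negative rank-2 matrix (product of non-negative factors)
    base <- abs(matrix(rnorm(40 * 2), 40, 2)) %*%
        abs(matrix(rnorm(2 * 10), 2, 10))
    dimnames(base) <- list(paste0("c", 1:40), paste0("g", 1:10))
    base[2, ] <- base[1, ]            # duplicated cell
    ob <- OmicsBatch(base, "RNA", "b")
    red <- reduceDimension(ob, r = 2)
    expect_equal(red$method, "PCA")
    expect_equal(as.matrix(dist(red$coords)), as.matrix(dist(base)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(red$coords[1, ], red$coords[2, ])
})

test_that("LSI reproduces a hand-computed TF-IDF SVD and zeroes ubiquitous regions", {
    x <- matrix(c(1, 0, 1,
                  0, 1, 1,
                  1, 1, 1), 3, 3, byrow = TRUE,
                dimnames = list(paste0("c", 1:3), paste0("r", 1:3)))
    red <- reduceDimension(OmicsBatch(x, "ATAC", "b"), r = 2)
    expect_equal(red$method, "LSI")
    # independent TF-IDF: tf = x / rowSums, idf = log(1 + N/df) - log 2
    tf <- x / rowSums(x)
    idf <- log(1 + 3 / colSums(x > 0)) - log(2)
    w <- sweep(tf, 2, idf, "*")
    expect_equal(unname(idf[3]), 0)   # all-ones region contributes nothing
    s <- svd(w)
    oracle <- s$u[, 1:2] %*% diag(s$d[1:2])
    expect_equal(as.matrix(dist(red$coords)), as.matrix(dist(oracle)),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("adaptive kernel matches its analytic form", {
    set.seed(2)
    x <- matrix(rnorm(20 * 3), 20, 3)
    K <- adaptiveKernel(x, kNn = 5, alpha = 40)
    expect_equal(diag(K), rep(1, 20), ignore_attr = TRUE)
    expect_equal(K, t(K))
    # a pair at exactly its bandwidth distance gives exp(-1)
    y <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
    Ky <- adaptiveKernel(y, kNn = 1, alpha = 1)
    d <- as.matrix(dist(y))
    sig <- apply(d, 1, function(r) min(r[r > 0]))
    i <- 1; j <- 2
    expect_equal(Ky[i, j],
                 0.5 * exp(-(d[i, j] / sig[i])) +
                     0.5 * exp(-(d[i, j] / sig[j])),
                 ignore_attr = TRUE)
    expect_error(adaptiveKernel(matrix(1, 8, 2), kNn = 2), "identical")
})

test_that("diffusion distances equal the brute-force oracle on small inputs", {
    set.seed(3)
    x <- cbind(seq_len(8) + rnorm(8, sd = 0.1), rnorm(8, sd = 0.1))
    orc <- oracle_diffusion(x, k_nn = 2)
    geo <- diffusionDistance(orc$K)
    expect_lt(max(abs(diffusionDistances(geo) - orc$D)), 1e-10)
    # stochasticity preserved under powering
    P <- geo@P
    P70 <- P
    for (i in 1:69) P70 <- P70 %*% P
    expect_lt(max(abs(rowSums(P70) - 1)), 1e-8)
})

test_that("diffusion distance is a symmetric zero-diagonal permutation-equivariant metric", {
    set.seed(4)
    x <- matrix(rnorm(30 * 3), 30, 3)
    K <- adaptiveKernel(x, kNn = 5)
    D <- diffusionDistances(diffusionDistance(K))
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(0, 30), ignore_attr = TRUE)
    expect_true(min(D) >= 0)
    # identical kernel rows give identical diffusion profiles
    Kdup <- K
    Kdup[2, ] <- Kdup[1, ]; Kdup[, 2] <- Kdup[, 1]
    Ddup <- diffusionDistances(diffusionDistance(Kdup))
    expect_lt(Ddup[1, 2], 1e-12)
    # permutation equivariance
    p <- sample(30)
    Dp <- diffusionDistances(diffusionDistance(K[p, p]))
    expect_equal(Dp, D[p, p], tolerance = 1e-10)
})

test_that("well-separated blobs separate in diffusion distance", {
    x <- make_blobs(rbind(c(0, 0), c(10, 0)), 15, sd = 0.3, seed = 5)
    K <- adaptiveKernel(x, kNn = 5)
    D <- diffusionDistances(diffusionDistance(K))
    grp <- rep(1:2, each = 15)
    intra <- max(D[grp == 1, grp == 1], D[grp == 2, grp == 2])
    inter <- min(D[grp == 1, grp == 2])
    expect_gt(inter, intra)
})

test_that("distance distributions normalise and are scale-invariant", {
    D <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3)
    Q <- distanceDistribution(D)
    expect_equal(sum(Q), 1)
    expect_equal(Q[1, 2], 2 / sum(D))
    expect_equal(distanceDistribution(7.3 * D), Q)
    expect_error(distanceDistribution(matrix(0, 3, 3)), "degenerate")
})
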