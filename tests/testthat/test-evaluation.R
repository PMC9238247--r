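test_that("neighbourhood overlap finds coincident partners and grows with k", {
    set.seed(1)
    Z <- matrix(rnorm(60 * 3), 60, 3)
    expect_equal(neighborhoodOverlap(Z, Z, k = 1), 1)
    Zb <- matrix(rnorm(60 * 3), 60, 3)   # unrelated embedding
    vals <- sapply(c(1, 5, 20, 50), function(k)
        neighborhoodOverlap(Z, Zb, k = k))
    expect_true(all(diff(vals) >= 0))
    expect_lt(vals[1], 0.2)              # random matching, k=1: near zero
    expect_error(neighborhoodOverlap(Z, Zb, k = 200), "pooled")
})

test_that("cosine matching score matches direct arithmetic", {
    Za <- rbind(c(1, 0), c(0, 2), c(1, 1))
    Zb <- rbind(c(2, 0), c(0, -1), c(1, 0))
    oracle <- mean(c(1, -1, cos(pi / 4)))
    expect_equal(cosineMatchingScore(Za, Zb), oracle)
    expect_equal(cosineMatchingScore(Za, Za), 1)
    expect_equal(cosineMatchingScore(Za, -Za), -1)
    Zbad <- Zb; Zbad[2, ] <- 0
    expect_error(cosineMatchingScore(Za, Zbad), "zero-norm")
})

test_that("branch F1 equals the brute-force Jaccard oracle on random partitions", {
    expect_equal(branchF1(rep(c("a", "b"), 10), rep(c("a", "b"), 10)), 1)
    # one inferred branch vs two equal true branches
    expect_equal(branchF1(rep(c("a", "b"), each = 10), rep("x", 20)), 0.5)
    set.seed(2)
    for (i in 1:30) {
        n <- sample(10:50, 1)
        t_lab <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
        i_lab <- sample(LETTERS[1:sample(2:5, 1)], n, replace = TRUE)
        expect_equal(branchF1(t_lab, i_lab), oracle_f1(t_lab, i_lab))
        # symmetry under swapping the partitions
        expect_equal(branchF1(t_lab, i_lab), branchF1(i_lab, t_lab))
    }
})

test_that("Kendall tau reproduces hand-counted cases", {
    expect_equal(pseudotimeKendall(1:10, 1:10), 1)
    expect_equal(pseudotimeKendall(1:10, 10:1), -1)
    expect_equal(pseudotimeKendall(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
    expect_error(pseudotimeKendall(rep(1, 5), 1:5), "constant")
})

test_that("k-means matching ARI is 1 for mirrored embeddings and ~0 for noise", {
    Z <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), 40, sd = 0.3, seed = 3)
    expect_equal(kmeansMatchingAri(Z, Z, nClusters = 3, seed = 1), 1)
    set.seed(4)
    Zr <- matrix(rnorm(nrow(Z) * 2), nrow(Z), 2)
    ari_null <- kmeansMatchingAri(Z, Zr, nClusters = 3, seed = 1)
    expect_lt(abs(ari_null), 0.1)
    # symmetry in argument order
    expect_equal(kmeansMatchingAri(Z, Zr, nClusters = 3, seed = 1),
                 kmeansMatchingAri(Zr, Z,
                                   matching = cbind(1:nrow(Z), 1:nrow(Z)),
                                   nClusters = 3, seed = 1))
    expect_error(kmeansMatchingAri(Z, Z, nClusters = 500, seed = 1),
                 "nClusters")
})

test_that("the Leiden resolution scan returns the best achievable ARI", {
    Z <- make_blobs(rbind(c(0, 0), c(8, 0), c(0, 8)), 50, sd = 0.3, seed = 5)
    lab <- rep(1:3, each = 50)
    best <- clusterAriScan(Z, lab, seed = 1)
    expect_equal(best, 1)
    # max over the scan is >= any single-resolution ARI
    single <- mclust::adjustedRandIndex(
        inferBackbone(Z, resolution = 0.1, seed = 1)$clusters, lab)
    expect_gte(best, single)
    # default grid: 0.1 to 1 with step 0.5
    expect_equal(seq(0.1, 1, by = 0.5), c(0.1, 0.6))
})

test_that("graph connectivity reflects fragmentation of a cell type", {
    Z1 <- make_blobs(rbind(c(0, 0)), 40, sd = 0.3, seed = 6)
    expect_equal(graphConnectivity(Z1, rep("a", 40), k = 5), 1)
    # one type split across two far blobs, 70/30
    Z2 <- rbind(make_blobs(rbind(c(0, 0)), 70, sd = 0.3, seed = 7),
                make_blobs(rbind(c(50, 0)), 30, sd = 0.3, seed = 8))
    sc <- graphConnectivity(Z2, rep("a", 100), k = 5)
    expect_equal(sc, 0.7)
    # non-decreasing in k
    ks <- c(3, 10, 30, 99)
    vals <- sapply(ks, function(k) graphConnectivity(Z2, rep("a", 100), k))
    expect_true(all(diff(vals) >= 0))
})

test_that("normalised MSE has its analytic values and per-row oracle", {
    set.seed(9)
    X <- matrix(rnorm(10 * 5), 10, 5)
    expect_equal(normalizedMse(3.1 * X, X), 0)
    A <- rbind(c(1, 0, 0), c(0, 1, 0))   # orthonormal row pairs
    B <- rbind(c(0, 0, 1), c(1, 0, 0))
    expect_equal(normalizedMse(A, B), 2)
    Y <- matrix(rnorm(10 * 5), 10, 5)
    oracle <- mean(sapply(1:10, function(i)
        sum((X[i, ] / sqrt(sum(X[i, ]^2)) - Y[i, ] / sqrt(sum(Y[i, ]^2)))^2)))
    expect_equal(normalizedMse(X, Y), oracle)
    expect_true(normalizedMse(X, Y) <= 4)
    Xz <- X; Xz[3, ] <- 0
    expect_error(normalizedMse(Xz, Y), "zero-norm")
})

test_that("metrics are invariant under consistent cell reordering", {
    set.seed(10)
    Za <- matrix(rnorm(30 * 2), 30, 2)
    Zb <- Za + rnorm(60, sd = 0.1)
    p <- sample(30)
    expect_equal(cosineMatchingScore(Za[p, ], Zb[p, ]),
                 cosineMatchingScore(Za, Zb))
    t1 <- runif(30); t2 <- t1 + rnorm(30, sd = 0.1)
    expect_equal(pseudotimeKendall(t1[p], t2[p]), pseudotimeKendall(t1, t2))
    b1 <- sample(c("x", "y"), 30, TRUE); b2 <- sample(c("u", "v"), 30, TRUE)
    expect_equal(branchF1(b1[p], b2[p]), branchF1(b1, b2))
})
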