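test_that("trajectory trees are validated", {
    expect_s3_class(presetTree("trifurcating"), "trajectoryTree")
    expect_error(trajectoryTree(c("1", "3"), c("2", "4"), c(1, 1),
                                c(10, 10)), "root")
    expect_error(trajectoryTree("1", "2", -1, 10), "positive")
    expect_error(trajectoryTree(c("1", "1"), c("2", "2"), c(1, 1),
                                c(5, 5)), "one parent")
})

test_that("identity evolution is Brownian: squared displacement grows linearly", {
    tree <- trajectoryTree("1", "2", length = 2, nCells = 4)
    v <- 20; sd_step <- 0.5
    slopes <- replicate(120, {
        idl <- simulateIdentities(tree, v = v, stepSd = sd_step,
                                  cellJitter = 0, seed = sample.int(1e6, 1))
        # pairwise squared identity distance vs pseudotime gap along one path
        d2 <- as.matrix(dist(idl$identity))^2
        dt <- abs(outer(idl$pseudotime, idl$pseudotime, "-"))
        ut <- upper.tri(dt)
        sum(d2[ut] * dt[ut]) / sum(dt[ut]^2)   # regression through origin
    })
    expect_equal(mean(slopes), v * sd_step^2, tolerance = 0.2)
})

test_that("degenerate diffusion collapses to the root identity and branches diverge", {
    tree <- presetTree("bifurcating", 120)
    idl <- simulateIdentities(tree, stepSd = 1e-9, seed = 1)
    expect_lt(max(dist(idl$identity)), 1e-6)
    idl2 <- simulateIdentities(tree, stepSd = 0.6, seed = 2)
    d <- as.matrix(dist(idl2$identity))
    b <- idl2$branch
    late <- idl2$pseudotime > 1.2   # cells well past the branch point   # cells far from the branch point
    intra <- mean(d[b == "2_3" & late, b == "2_3" & late])
    inter <- mean(d[b == "2_3" & late, b == "2_4" & late])
    expect_gt(inter, intra)
    # branch cell counts match the tree allocation exactly
    tree3 <- presetTree("trifurcating", 400)
    idl3 <- simulateIdentities(tree3, seed = 3)
    expect_equal(unname(table(idl3$branch)[paste(tree3$parent, tree3$child,
                                                 sep = "_")]),
                 tree3$nCells, ignore_attr = TRUE)
})

test_that("accessibility is binary, rank-preserving and hits the target sparsity", {
    tree <- trajectoryTree("1", "2", 1, 2000)
    idl <- simulateIdentities(tree, seed = 4)
    at <- simulateAtac(idl$identity, nRegions = 150, seed = 4)
    expect_true(all(at$counts %in% c(0, 1)))
    expect_equal(mean(at$counts), 4 / 16, tolerance = 0.02 * 4)
    # within each region, accessible cells have higher raw propensity
    for (r in sample(150, 10)) {
        on <- at$counts[, r] == 1
        expect_gt(min(at$propensity[on, r]), max(at$propensity[!on, r]) - 1e-12)
    }
    # determinism
    at2 <- simulateAtac(idl$identity, nRegions = 150, seed = 4)
    expect_identical(at$counts, at2$counts)
})

test_that("expression counts respond monotonically to accessibility", {
    v <- 10
    set.seed(1)
    id <- matrix(rnorm(4000 * v, mean = 1, sd = 0.3), 4000, v)
    rownames(id) <- paste0("c", 1:4000)
    A <- matrix(0, 20, 10,
                dimnames = list(paste0("region%", 1:20), paste0("g", 1:10)))
    for (g in 1:10) A[sample(20, 4), g] <- 1
    gam <- GeneActivityMatrix(A)
    closed <- matrix(0, 4000, 20, dimnames = list(rownames(id), rownames(A)))
    open <- closed + 1
    r_closed <- simulateRna(id, closed, gam, seed = 9)
    r_open <- simulateRna(id, open, gam, seed = 9)
    expect_true(all(colMeans(r_open$counts) > colMeans(r_closed$counts)))
    expect_true(all(r_open$counts >= 0))
    expect_true(all(r_open$counts == round(r_open$counts)))
    # k_on coupling factor spans [0.5, 2] between closed and open
    expect_equal(r_open$kinetics$k_on / r_closed$kinetics$k_on,
                 matrix(4, 4000, 10), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("noise model thins counts at the capture efficiency and splits modalities", {
    sim0 <- simulateMultiome("linear", totalCells = 400, nGenes = 60,
                             nRegions = 100, captureEff = c(1, 1),
                             batchEffectSd = 0, seed = 6)
    # capture 1, no batch effect: exported counts equal the matched truth
    expect_equal(as.matrix(counts(sim0$rna)),
                 rnaCounts(sim0$truth)[sim0$rnaCells, ])
    truth <- sim0$truth
    sp <- addNoiseAndSplit(truth, captureEff = c(0.6, 0.6),
                           batchEffectSd = 0, seed = 7)
    kept <- as.matrix(counts(sp$batches$batch1_rna))
    orig <- rnaCounts(truth)[sp$batchAssign == 1, ]
    expect_equal(sum(kept) / sum(orig), 0.6, tolerance = 0.03)
    expect_error(addNoiseAndSplit(truth, captureEff = c(1.4, 1)), "captureEff")
    # modality sets disjoint per cell
    expect_length(intersect(sim0$rnaCells, sim0$atacCells), 0)
})

test_that("the full generator is reproducible and carries coupled signal", {
    s1 <- simulateMultiome("bifurcating", totalCells = 600, nGenes = 60,
                           nRegions = 120, seed = 8)
    s2 <- simulateMultiome("bifurcating", totalCells = 600, nGenes = 60,
                           nRegions = 120, seed = 8)
    expect_identical(rnaCounts(s1$truth), rnaCounts(s2$truth))
    expect_identical(as.matrix(counts(s1$atac)), as.matrix(counts(s2$atac)))
    # linked accessibility correlates positively with expression on average;
    # unlinked region-gene pairs are centred at zero
    truth <- s1$truth
    A <- as.matrix(gamMatrix(trueGam(truth)))
    frac <- truth@kinetics$fracOpen
    linked_cor <- sapply(seq_len(ncol(A)), function(g)
        suppressWarnings(cor(rnaCounts(truth)[, g], frac[, g],
                             method = "spearman")))
    expect_gt(mean(linked_cor, na.rm = TRUE), 0.1)
    set.seed(1)
    unlinked <- sapply(seq_len(ncol(A)), function(g) {
        r <- sample(which(A[, g] == 0), 1)
        suppressWarnings(cor(rnaCounts(truth)[, g],
                             atacCounts(truth)[, r], method = "spearman"))
    })
    expect_lt(abs(mean(unlinked, na.rm = TRUE)), 0.06)
})

test_that("discrete cluster mode yields k-means-recoverable clusters per modality", {
    sim <- simulateMultiome("clusters", totalCells = 900, nGenes = 60,
                            nRegions = 120, seed = 10)
    truth <- sim$truth
    lab <- branches(truth)
    pc_rna <- prcomp(log1p(rnaCounts(truth)), rank. = 10)$x
    km_rna <- kmeans(pc_rna, 3, nstart = 10)$cluster
    expect_gt(mclust::adjustedRandIndex(km_rna, lab), 0.9)
    pc_atac <- prcomp(atacCounts(truth), rank. = 10)$x
    km_atac <- kmeans(pc_atac, 3, nstart = 10)$cluster
    expect_gt(mclust::adjustedRandIndex(km_atac, lab), 0.9)
})

test_that("imbalanced and small-branch presets pin their characteristic sizes", {
    sim <- simulateMultiome("imbalanced", seed = 1, nGenes = 20, nRegions = 40)
    expect_equal(length(sim$rnaCells), 757)
    expect_equal(length(sim$atacCells), 1486)
    smb <- simulateMultiome("smallbranch", totalCells = 1100, seed = 1,
                            nGenes = 20, nRegions = 40)
    br <- branches(smb$truth)
    expect_equal(sum(br[smb$rnaCells] == "2_5"), 95)
    expect_equal(sum(br[smb$atacCells] == "2_5"), 107)
})
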