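# Shared small simulated dataset for trainer tests (kept tiny: the full-scale
# behaviour is exercised in test-acceptance.R).
local_sim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            sim <- simulateMultiome("linear", totalCells = 300, nGenes = 50,
                                    nRegions = 100, seed = 5)
            rna <- preprocessRna(sim$rna)
            pa <- preprocessAtac(sim$atac, trueGam(sim$truth))
            cache <<- list(sim = sim, rna = rna, atac = pa$batch,
                           gam = pa$gam)
        }
        cache
    }
})

small_net <- list(hiddenGact = c(64L, 32L), hiddenProj = c(32L, 16L))

test_that("training is seed-deterministic and the objective decreases", {
    d <- local_sim()
    run <- function() integrateModalities(
        d$rna, d$atac, d$gam, latentDim = 4, epochs = 40, seed = 7,
        hiddenGact = small_net$hiddenGact, hiddenProj = small_net$hiddenProj)
    r1 <- run()
    r2 <- run()
    expect_equal(trainingTrace(r1), trainingTrace(r2))
    expect_identical(embeddings(r1)[[1]], embeddings(r2)[[1]])
    tr <- trainingTrace(r1)
    expect_lt(tr$total[nrow(tr)], tr$total[1])
    expect_lt(tr$mmd[nrow(tr)], tr$mmd[1])
    expect_true(all(is.finite(as.matrix(tr))))
    # embeddings cover every cell and stay finite
    expect_equal(nrow(embeddings(r1)[[1]]), nrow(counts(d$rna)))
    expect_equal(nrow(embeddings(r1)[[2]]), nrow(counts(d$atac)))
    expect_true(all(is.finite(embeddings(r1)[[2]])))
    expect_equal(dim(pseudoRna(r1)[[1]]),
                 c(nrow(counts(d$atac)), ncol(counts(d$rna))))
})

test_that("RNA-side steps leave the gene activity weights bitwise unchanged", {
    ns <- asNamespace("scTrajAlign")
    set.seed(1)
    model <- initModel(10, 6, 2, seed = 1, hiddenGact = c(8L, 5L),
                       hiddenProj = c(6L, 4L))
    opt <- list(gact = ns$.adam_init(model@gact),
                proj = ns$.adam_init(model@proj), t = 0L, lr = 1e-3)
    x_rna <- matrix(abs(rnorm(8 * 6)), 8, 6)
    x_atac <- matrix(rbinom(9 * 10, 1, 0.4), 9, 10)
    qd <- as.matrix(dist(matrix(rnorm(16), 8)))
    Ahat <- matrix(rbinom(60, 1, 0.5), 10, 6)
    st <- ns$.train_step("RNA", model@gact, model@proj, opt, model@config,
                         lossWeights(), x_act = x_rna, act_is_atac = FALSE,
                         x_par = x_atac, par_is_atac = TRUE,
                         q_sub = qd, Ahat = Ahat)
    for (i in seq_along(model@gact))
        expect_identical(st$gact[[i]]$W, model@gact[[i]]$W)
    # and the ATAC side does update them
    st2 <- ns$.train_step("ATAC", model@gact, model@proj, opt, model@config,
                          lossWeights(), x_act = x_atac, act_is_atac = TRUE,
                          x_par = x_rna, par_is_atac = FALSE,
                          q_sub = as.matrix(dist(matrix(rnorm(18), 9))),
                          Ahat = Ahat)
    expect_false(identical(st2$gact[[1]]$W, model@gact[[1]]$W))
})

test_that("anchor loss at convergence is below its starting value", {
    d <- local_sim()
    pt <- pseudotime(d$sim$truth)
    roots_rna <- order(pt[d$sim$rnaCells])[1:10]
    roots_atac <- order(pt[d$sim$atacCells])[1:10]
    res <- integrateModalities(
        d$rna, d$atac, d$gam, latentDim = 4, epochs = 40, seed = 3,
        anchorsRna = roots_rna, anchorsAtac = roots_atac,
        hiddenGact = small_net$hiddenGact, hiddenProj = small_net$hiddenProj)
    tr <- trainingTrace(res)
    expect_gt(tr$anchor[1], 0)
    expect_lt(tr$anchor[nrow(tr)], tr$anchor[1])
})

test_that("quantile normalisation is rank-preserving and draws from the reference", {
    set.seed(2)
    dref <- matrix(runif(64, 0, 10), 8, 8)
    dtar <- matrix(runif(36), 6, 6)
    out <- quantileNormalizeDistances(dref, dtar, seed = 1)
    expect_equal(dim(out), dim(dtar))
    expect_true(all(out %in% dref))
    # rank-preserving: weakly monotone in the target (sampled values can tie)
    expect_true(all(diff(out[order(as.vector(dtar))]) >= 0))
    expect_gt(cor(as.vector(out), as.vector(dtar), method = "spearman"),
              0.99)
    # identity when the target's sorted values equal the samples
    samp <- scTrajAlign:::.with_seed(5L,
        sample(as.vector(dref), 36, replace = TRUE))
    dtar2 <- matrix(sample(samp), 6, 6)
    out2 <- quantileNormalizeDistances(dref, dtar2, seed = 5)
    expect_equal(out2, dtar2, ignore_attr = TRUE)
})

test_that("multi-batch MMD decomposes into pairwise terms", {
    set.seed(3)
    zs <- lapply(1:3, function(i) matrix(rnorm(12 * 2, mean = i / 2), 12, 2))
    expect_equal(multiBatchMmd(zs, refIndex = 1),
                 mmdLoss(zs[[2]], zs[[1]]) + mmdLoss(zs[[3]], zs[[1]]))
    expect_equal(multiBatchMmd(zs[1:2], refIndex = 1),
                 mmdLoss(zs[[2]], zs[[1]]))
    expect_equal(multiBatchMmd(list(zs[[1]], zs[[1]]), 1), 0)
    expect_warning(v <- multiBatchMmd(zs[1], 1), "single batch")
    expect_equal(v, 0)
})

test_that("training accepts multiple batches per modality", {
    d <- local_sim()
    # split the RNA batch in two to exercise the multi-batch path
    x <- counts(d$rna)
    b1 <- OmicsBatch(x[1:80, ], "RNA", "rna1")
    b2 <- OmicsBatch(x[81:nrow(x), ], "RNA", "rna2")
    res <- integrateModalities(list(b1, b2), d$atac, d$gam, latentDim = 4,
                               epochs = 8, seed = 2,
                               hiddenGact = small_net$hiddenGact,
                               hiddenProj = small_net$hiddenProj)
    expect_length(embeddings(res), 3)
    expect_true(all(vapply(embeddings(res),
                           function(z) all(is.finite(z)), TRUE)))
})
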