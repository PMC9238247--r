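test_that("distance loss vanishes on isometric embeddings and resists rigid motion", {
    set.seed(1)
    Z <- matrix(rnorm(12 * 2), 12, 2)
    Qx <- distanceDistribution(as.matrix(dist(Z)))
    expect_lt(abs(distanceLoss(Z, Qx)), 1e-9)
    # uniform scaling cancels in the normalised distribution
    expect_lt(abs(distanceLoss(3.7 * Z, Qx)), 1e-9)
    # rigid rotation + translation leaves the loss unchanged
    th <- 0.83
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Qother <- distanceDistribution(as.matrix(dist(matrix(rnorm(24), 12))))
    expect_equal(distanceLoss(Z %*% R + 5, Qother),
                 distanceLoss(Z, Qother), tolerance = 1e-9)
    expect_error(distanceLoss(Z[1:2, ], Qx[1:2, 1:2]), "at least 3")
    expect_error(distanceLoss(Z, matrix(0, 12, 12)), "zero off-diagonal")
})

test_that("distance loss on a 4-point toy matches direct summation", {
    Z <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 1))
    X <- rbind(c(0, 0), c(2, 1), c(1, 3), c(4, 0))
    Qx <- distanceDistribution(as.matrix(dist(X)))
    # independent elementwise summation
    Dz <- as.matrix(dist(Z))
    Qz <- Dz / sum(Dz)
    eps <- 1e-12
    oracle <- 0
    for (i in 1:4) for (j in 1:4) if (i != j)
        oracle <- oracle + Qz[i, j] * (log(Qz[i, j] + eps) - log(Qx[i, j] + eps))
    expect_equal(distanceLoss(Z, Qx), oracle, tolerance = 1e-12)
})

test_that("MMD matches closed forms and the double-loop oracle", {
    # identical point sets
    set.seed(2)
    Z <- matrix(rnorm(10 * 3), 10, 3)
    expect_equal(mmdLoss(Z, Z), 0)
    # two single points at distance delta, single bandwidth
    delta <- 1.7; g <- 0.5
    v <- mmdLoss(matrix(c(0, 0), 1), matrix(c(delta, 0), 1), gammas = g)
    expect_equal(v, 2 - 2 * exp(-delta^2 / (2 * g)))
    # 20-point clouds vs brute force on a small grid
    Z1 <- matrix(rnorm(20 * 2), 20, 2)
    Z2 <- matrix(rnorm(20 * 2, mean = 0.5), 20, 2)
    gs <- 10^(-2:2)
    expect_equal(mmdLoss(Z1, Z2, gs), oracle_mmd(Z1, Z2, gs),
                 tolerance = 1e-10)
    expect_error(mmdLoss(Z1[0, , drop = FALSE], Z2), "non-empty")
})

test_that("MMD gradient path agrees with the exact loss and grows with separation", {
    set.seed(3)
    Z1 <- matrix(rnorm(15 * 2), 15, 2)
    Z2 <- matrix(rnorm(15 * 2), 15, 2)
    gr <- scTrajAlign:::.mmd_loss_grad(Z1, Z2)
    expect_equal(gr$value, mmdLoss(Z1, Z2), tolerance = 1e-5)
    # monotone non-decreasing under translating Z2 away along a direction
    shifts <- c(0, 0.5, 1, 2, 4)
    vals <- sapply(shifts, function(s) mmdLoss(Z1, Z2 + s))
    expect_true(all(diff(vals) > -1e-10))
    expect_true(all(vals >= 0))
})

test_that("the gene-activity penalty is the masked L1 of the linear map", {
    m <- initModel(5, 3, 2, seed = 7, hiddenGact = c(4L, 3L),
                   hiddenProj = c(3L, 2L))
    A <- matrix(1, 5, 3, dimnames = list(paste0("r", 1:5), paste0("g", 1:3)))
    zeros <- rbind(c(1, 2), c(2, 3), c(4, 1), c(5, 2))
    A[zeros] <- 0
    gam <- GeneActivityMatrix(A)
    M <- t(m@gact[[3]]$W %*% m@gact[[2]]$W %*% m@gact[[1]]$W)
    expect_equal(gamPenalty(m, gam), sum(abs(M[zeros])))
    # all-ones prior: empty mask, zero penalty
    expect_equal(gamPenalty(m, GeneActivityMatrix(A * 0 + 1)), 0)
    # hand-masked weights: zero outside the support
    m2 <- m
    m2@gact[[2]]$W[] <- 0
    expect_equal(gamPenalty(m2, gam), 0)
})

test_that("anchor loss is the squared distance of anchor means", {
    Zr <- rbind(c(1, 0), c(3, 2))
    Za <- rbind(c(2, 1), c(2, 1), c(2, 1))
    expect_equal(anchorLoss(Zr, Za), 0)
    expect_equal(anchorLoss(sweep(Zr, 2, c(1, 0), "+"), Za), 1)
    expect_equal(anchorLoss(Zr[c(2, 1), ], Za), 0)  # permutation invariant
    expect_error(anchorLoss(Zr[0, , drop = FALSE], Za), "non-empty")
})

test_that("composite loss reduces to its parts and scales linearly in the weights", {
    set.seed(4)
    nR <- 8; nG <- 5
    m <- initModel(nR, nG, 2, seed = 8, hiddenGact = c(6L, 4L),
                   hiddenProj = c(5L, 3L))
    xr <- matrix(abs(rnorm(10 * nG)), 10, nG)
    xa <- matrix(rbinom(12 * nR, 1, 0.5), 12, nR)
    A <- matrix(rbinom(nR * nG, 1, 0.6), nR, nG,
                dimnames = list(paste0("r", 1:nR), paste0("g", 1:nG)))
    gam <- GeneActivityMatrix(A)
    qr_ <- distanceDistribution(as.matrix(dist(matrix(rnorm(20), 10))))
    qa_ <- distanceDistribution(as.matrix(dist(matrix(rnorm(24), 12))))

    zero_w <- compositeLoss(m, "RNA", xr, xa, qRna = qr_, qAtac = qa_,
                            gam = gam, weights = lossWeights(0, 0))
    zr <- projectCells(m, xr)
    expect_equal(zero_w$total, distanceLoss(zr, qr_))

    w1 <- compositeLoss(m, "ATAC", xr, xa, qRna = qr_, qAtac = qa_,
                        gam = gam, weights = lossWeights(1, 1))
    expect_equal(sum(w1$components), w1$total, tolerance = 1e-10)
    w2 <- compositeLoss(m, "ATAC", xr, xa, qRna = qr_, qAtac = qa_,
                        gam = gam, weights = lossWeights(2, 1))
    expect_equal(w2$components[["mmd"]], 2 * w1$components[["mmd"]],
                 tolerance = 1e-12)
    expect_error(compositeLoss(m, "ATAC", xr, xa, qRna = qr_, gam = gam),
                 "missing Q")
})

test_that("losses are invariant to permuting cells", {
    set.seed(5)
    Z <- matrix(rnorm(14 * 3), 14, 3)
    Qx <- distanceDistribution(as.matrix(dist(matrix(rnorm(28), 14))))
    p <- sample(14)
    expect_equal(distanceLoss(Z[p, ], Qx[p, p]), distanceLoss(Z, Qx),
                 tolerance = 1e-12)
    Z2 <- matrix(rnorm(9 * 3), 9, 3)
    expect_equal(mmdLoss(Z[p, ], Z2), mmdLoss(Z, Z2), tolerance = 1e-12)
})

test_that("training-step gradients match numerical differentiation", {
    ns <- asNamespace("scTrajAlign")
    set.seed(42)
    model <- initModel(6, 4, 2, seed = 3, hiddenGact = c(5L, 4L),
                       hiddenProj = c(4L, 3L))
    cfg <- model@config
    wts <- lossWeights(1.3, 0.7, 1.0)
    x_act <- matrix(rbinom(7 * 6, 1, 0.4), 7, 6)
    x_par <- matrix(abs(rnorm(5 * 4)), 5, 4)
    qd <- matrix(runif(49), 7, 7); qd <- qd + t(qd); diag(qd) <- 0
    anch_act <- matrix(rbinom(2 * 6, 1, 0.5), 2, 6)
    anch_par <- matrix(abs(rnorm(2 * 4)), 2, 4)
    Ahat <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4)
    value_fn <- function(gact, proj, side) {
        sg <- ns$.step_grads(side, gact, proj, cfg, wts, x_act, TRUE,
                             x_par, FALSE, qd, Ahat, anch_act, anch_par)
        sum(sg$comp)
    }
    h <- 1e-6
    for (side in c("ATAC", "RNA")) {
        sg <- ns$.step_grads(side, model@gact, model@proj, cfg, wts, x_act,
                             TRUE, x_par, FALSE, qd, Ahat, anch_act, anch_par)
        worst <- 0
        probe <- function(setter, grad) {
            for (e in sample(length(grad), min(6, length(grad)))) {
                gp <- setter(model@gact, model@proj, e, h)
                vplus <- value_fn(gp$gact, gp$proj, side)
                gm <- setter(model@gact, model@proj, e, -h)
                vminus <- value_fn(gm$gact, gm$proj, side)
                num <- (vplus - vminus) / (2 * h)
                worst <<- max(worst, abs(num - grad[e]) / max(1, abs(num)))
            }
        }
        if (side == "ATAC") {
            for (li in seq_along(sg$gact_grads)) {
                local({
                    li <- li
                    probe(function(g, p, e, d) {
                        g[[li]]$W[e] <- g[[li]]$W[e] + d
                        list(gact = g, proj = p)
                    }, sg$gact_grads[[li]]$dW)
                })
            }
        }
        for (li in seq_along(sg$proj_grads)) {
            local({
                li <- li
                probe(function(g, p, e, d) {
                    p[[li]]$W[e] <- p[[li]]$W[e] + d
                    list(gact = g, proj = p)
                }, sg$proj_grads[[li]]$dW)
                if (!is.null(sg$proj_grads[[li]]$dgamma)) {
                    probe(function(g, p, e, d) {
                        p[[li]]$bn$gamma[e] <- p[[li]]$bn$gamma[e] + d
                        list(gact = g, proj = p)
                    }, sg$proj_grads[[li]]$dgamma)
                    probe(function(g, p, e, d) {
                        p[[li]]$bn$beta[e] <- p[[li]]$bn$beta[e] + d
                        list(gact = g, proj = p)
                    }, sg$proj_grads[[li]]$dbeta)
                }
            })
        }
        expect_lt(worst, 1e-5)
    }
})
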