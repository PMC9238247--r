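#' Train the integration model on unmatched RNA and ATAC batches
#'
#' Alternating stochastic optimisation of the two per-modality objectives.
#' Each epoch interleaves minibatch steps: an ATAC-side step feeds
#' accessibility through the gene activity module and the projection module
#' and updates both (distance preservation on the ATAC batch, alignment
#' against the reference batch, gene-activity sparsity penalty, optional
#' anchor loss); an RNA-side step feeds expression through the projection
#' module alone and updates only the projection parameters. With more than
#' one batch per modality, each batch's diffusion-distance matrix is quantile
#' normalised against the reference batch (the first RNA batch) and the
#' alignment/anchor losses are computed between each batch and the reference.
#'
#' @param rnaBatches an RNA \linkS4class{OmicsBatch} (preprocessed:
#'   log-normalised) or list of them.
#' @param atacBatches an ATAC \linkS4class{OmicsBatch} (binary) or list.
#' @param gam \linkS4class{GeneActivityMatrix} aligned to the ATAC features
#'   (rows) and RNA features (columns).
#' @param latentDim latent dimension `d` (default 8; 4 is typical for real
#'   data).
#' @param lambdaMmd,lambdaG loss weights (defaults 1).
#' @param epochs training epochs (default 500).
#' @param learningRate Adam learning rate (default 5e-4).
#' @param minibatchSize minibatch size (default 512, clipped to batch size;
#'   must allow >= 3 cells per step).
#' @param seed integer seed controlling initialisation and sampling.
#' @param anchorsRna,anchorsAtac optional anchor cell indices: a vector (one
#'   batch) or list parallel to the batches. Anchor loss weight is 1.
#' @param kNn,alpha,tList diffusion geometry parameters (see
#'   [adaptiveKernel()] and [diffusionDistance()]).
#' @param reducedDim dimension for PCA/LSI before the kernel (default 30).
#' @param hiddenGact,hiddenProj network widths (see [initModel()]).
#' @param distanceTargets optional list of precomputed diffusion distance
#'   matrices, one per batch in (RNA, ATAC) order, as produced by
#'   [diffusionDistance()] on each batch's reduced representation. They are
#'   deterministic given the data, so repeated runs (e.g. over training
#'   seeds) can share them.
#' @param engine `"cpp"` (compiled core, default) or `"r"` (reference
#'   implementation in plain R; identical results, slower).
#' @param verbose print the loss breakdown every 50 epochs.
#' @return An \linkS4class{IntegrationResult}.
#' @export
integrateModalities <- function(rnaBatches, atacBatches, gam,
                                latentDim = 8, lambdaMmd = 1, lambdaG = 1,
                                epochs = 500, learningRate = 5e-4,
                                minibatchSize = 512, seed = 0L,
                                anchorsRna = NULL, anchorsAtac = NULL,
                                kNn = 5, alpha = 40, tList = c(30, 50, 70),
                                reducedDim = 30,
                                hiddenGact = c(1024L, 512L),
                                hiddenProj = c(512L, 128L),
                                distanceTargets = NULL,
                                engine = c("cpp", "r"),
                                verbose = FALSE) {
    engine <- match.arg(engine)
    if (is(rnaBatches, "OmicsBatch")) rnaBatches <- list(rnaBatches)
    if (is(atacBatches, "OmicsBatch")) atacBatches <- list(atacBatches)
    .assert(length(rnaBatches) >= 1 && length(atacBatches) >= 1,
            "need at least one batch per modality")
    .assert(epochs >= 1, "epochs must be >= 1")
    .assert(minibatchSize >= 3, "minibatchSize must be >= 3")
    A <- gamMatrix(gam)
    for (b in rnaBatches)
        .assert(identical(featureIds(b), colnames(A)),
                "RNA batch '%s' features must match gam genes", batchId(b))
    for (b in atacBatches)
        .assert(identical(featureIds(b), rownames(A)),
                "ATAC batch '%s' features must match gam regions", batchId(b))
    if (is.numeric(anchorsRna)) anchorsRna <- list(anchorsRna)
    if (is.numeric(anchorsAtac)) anchorsAtac <- list(anchorsAtac)

    batches <- c(lapply(rnaBatches, function(b)
                     list(x = .as_dense(counts(b)), modality = "RNA",
                          id = batchId(b))),
                 lapply(atacBatches, function(b)
                     list(x = .as_dense(counts(b)), modality = "ATAC",
                          id = batchId(b))))
    nb <- length(batches)
    refIdx <- 1L   # first RNA batch
    anchors <- vector("list", nb)
    for (i in seq_along(rnaBatches))
        if (!is.null(anchorsRna) && length(anchorsRna) >= i)
            anchors[[i]] <- anchorsRna[[i]]
    for (i in seq_along(atacBatches))
        if (!is.null(anchorsAtac) && length(anchorsAtac) >= i)
            anchors[[length(rnaBatches) + i]] <- anchorsAtac[[i]]

    # --- per-batch diffusion geometry targets -----------------------------
    geom_seed <- as.integer(seed)
    Ds <- if (!is.null(distanceTargets)) {
        .assert(length(distanceTargets) == nb,
                "distanceTargets must have one matrix per batch")
        distanceTargets
    } else .with_seed(geom_seed, lapply(batches, function(b) {
        ob <- OmicsBatch(b$x, b$modality, b$id)
        red <- reduceDimension(ob, r = min(reducedDim, min(dim(b$x)) - 1))
        K <- adaptiveKernel(red, kNn = kNn, alpha = alpha)
        diffusionDistances(diffusionDistance(K, tList = tList))
    }))
    if (nb > 2) {
        for (i in seq_len(nb)[-refIdx]) {
            Ds[[i]] <- quantileNormalizeDistances(Ds[[refIdx]], Ds[[i]],
                                                  seed = geom_seed + i)
            diag(Ds[[i]]) <- 0
        }
    }

    model <- initModel(nrow(A), ncol(A), latentDim, seed = seed,
                       hiddenGact = hiddenGact, hiddenProj = hiddenProj,
                       gamInit = A)
    cfg <- model@config
    wts <- lossWeights(lambdaMmd, lambdaG)
    gact <- model@gact
    proj <- model@proj
    Ahat <- reversedGam(gam)
    opt <- list(gact = .adam_init(gact), proj = .adam_init(proj),
                t = 0L, lr = learningRate)
    core <- if (engine == "cpp")
        .core_new(gact, proj, cfg, learningRate) else NULL
    gammas <- gammaGrid()

    trace <- NULL
    .with_seed(as.integer(seed) + 1L, {
        for (epoch in seq_len(epochs)) {
            chunks <- lapply(batches, function(b)
                .make_chunks(nrow(b$x), minibatchSize))
            nsteps <- max(vapply(chunks, length, 1L))
            comp_sum <- c(dist = 0, mmd = 0, gam = 0, anchor = 0)
            ncomp <- 0L
            for (s in seq_len(nsteps)) {
                for (bi in seq_len(nb)) {
                    b <- batches[[bi]]
                    side <- b$modality
                    pi <- if (bi == refIdx) {
                        others <- setdiff(seq_len(nb), refIdx)
                        others[1L + (s - 1L) %% length(others)]
                    } else refIdx
                    idx <- chunks[[bi]][[1L + (s - 1L) %% length(chunks[[bi]])]]
                    pidx <- chunks[[pi]][[1L + (s - 1L) %% length(chunks[[pi]])]]
                    x_act <- batches[[bi]]$x[idx, , drop = FALSE]
                    x_par <- batches[[pi]]$x[pidx, , drop = FALSE]
                    anch_act <- .anchor_x(batches[[bi]], anchors[[bi]])
                    anch_par <- .anchor_x(batches[[pi]], anchors[[pi]])
                    use_anchor <- !is.null(anch_act) && !is.null(anch_par)
                    if (engine == "cpp") {
                        comp <- .core_step(
                            core, side,
                            if (use_anchor) rbind(x_act, anch_act) else x_act,
                            side == "ATAC",
                            if (use_anchor) rbind(x_par, anch_par) else x_par,
                            batches[[pi]]$modality == "ATAC",
                            nrow(x_act), nrow(x_par),
                            Ds[[bi]][idx, idx], Ahat,
                            wts$lambdaMmd, wts$lambdaG, wts$anchorWeight,
                            use_anchor, gammas)
                    } else {
                        st <- .train_step(
                            side, gact, proj, opt, cfg, wts,
                            x_act = x_act, act_is_atac = side == "ATAC",
                            x_par = x_par,
                            par_is_atac = batches[[pi]]$modality == "ATAC",
                            q_sub = Ds[[bi]][idx, idx],
                            Ahat = Ahat,
                            anch_act = anch_act, anch_par = anch_par)
                        gact <- st$gact; proj <- st$proj; opt <- st$opt
                        comp <- st$comp
                    }
                    if (!all(is.finite(comp)))
                        stop("training diverged (",
                             paste(names(comp)[!is.finite(comp)],
                                   collapse = ", "),
                             " is not finite) at epoch ", epoch, call. = FALSE)
                    comp_sum <- comp_sum + comp[names(comp_sum)]
                    ncomp <- ncomp + 1L
                }
            }
            row <- c(epoch = epoch, comp_sum / ncomp,
                     total = sum(comp_sum) / ncomp)
            trace <- rbind(trace, row)
            if (verbose && (epoch == 1 || epoch %% 50 == 0))
                message(sprintf(
                    "epoch %d: dist %.4f mmd %.4f gam %.4f anchor %.4f",
                    epoch, row[["dist"]], row[["mmd"]], row[["gam"]],
                    row[["anchor"]]))
        }
    })
    if (engine == "cpp") {
        pars <- .core_params(core)
        gact <- pars$gact
        proj <- pars$proj
    }
    model@gact <- gact
    model@proj <- proj

    embeddings <- list()
    pseudo_out <- list()
    for (bi in seq_len(nb)) {
        b <- batches[[bi]]
        if (b$modality == "ATAC") {
            ps <- geneActivityForward(model, b$x)
            colnames(ps) <- colnames(A)
            pseudo_out[[b$id]] <- ps
            z <- projectCells(model, ps)
        } else {
            z <- projectCells(model, b$x)
        }
        embeddings[[b$id]] <- z
    }
    new("IntegrationResult",
        embeddings = embeddings, model = model, pseudoRna = pseudo_out,
        trace = as.data.frame(trace, row.names = seq_len(nrow(trace))),
        batchInfo = data.frame(
            batch = vapply(batches, `[[`, "", "id"),
            modality = vapply(batches, `[[`, "", "modality"),
            n_cells = vapply(batches, function(b) nrow(b$x), 1L)))
}

.anchor_x <- function(batch, anchor_idx) {
    if (is.null(anchor_idx) || length(anchor_idx) == 0) return(NULL)
    batch$x[anchor_idx, , drop = FALSE]
}

# Random minibatch chunks covering a batch; a trailing chunk with < 3 cells
# is merged into its predecessor (the distance loss needs >= 3).
.make_chunks <- function(n, size) {
    size <- min(size, n)
    ord <- sample.int(n)
    k <- ceiling(n / size)
    chunks <- split(ord, rep(seq_len(k), each = size, length.out = n))
    if (k > 1 && length(chunks[[k]]) < 3) {
        chunks[[k - 1]] <- c(chunks[[k - 1]], chunks[[k]])
        chunks[[k]] <- NULL
    }
    chunks
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(net) {
    lapply(net, function(ly) {
        st <- list(W = list(m = ly$W * 0, v = ly$W * 0))
        if (!is.null(ly$bn) && ly$bn$type == "affine") {
            z <- numeric(length(ly$bn$gamma))
            st$gamma <- list(m = z, v = z)
            st$beta <- list(m = z, v = z)
        }
        st
    })
}

.adam_step <- function(par, grad, st, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
    st$m <- b1 * st$m + (1 - b1) * grad
    st$v <- b2 * st$v + (1 - b2) * grad^2
    mh <- st$m / (1 - b1^t)
    vh <- st$v / (1 - b2^t)
    list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

# Apply accumulated gradients to one net.
.apply_grads <- function(net, grads, opt_net, lr, t) {
    for (i in seq_along(net)) {
        g <- grads[[i]]
        if (is.null(g)) next
        up <- .adam_step(net[[i]]$W, g$dW, opt_net[[i]]$W, lr, t)
        net[[i]]$W <- up$par; opt_net[[i]]$W <- up$st
        if (!is.null(g$dgamma) && !is.null(net[[i]]$bn$gamma)) {
            up <- .adam_step(net[[i]]$bn$gamma, g$dgamma,
                             opt_net[[i]]$gamma, lr, t)
            net[[i]]$bn$gamma <- up$par; opt_net[[i]]$gamma <- up$st
            up <- .adam_step(net[[i]]$bn$beta, g$dbeta,
                             opt_net[[i]]$beta, lr, t)
            net[[i]]$bn$beta <- up$par; opt_net[[i]]$beta <- up$st
        }
    }
    list(net = net, opt = opt_net)
}

.add_grads <- function(a, b, scale = 1) {
    if (is.null(a)) a <- vector("list", length(b))
    for (i in seq_along(b)) {
        if (is.null(b[[i]])) next
        if (is.null(a[[i]])) {
            a[[i]] <- lapply(b[[i]], function(g)
                if (is.null(g)) NULL else g * scale)
        } else {
            for (nm in names(b[[i]]))
                if (!is.null(b[[i]][[nm]]))
                    a[[i]][[nm]] <- (if (is.null(a[[i]][[nm]])) 0
                                     else a[[i]][[nm]]) + b[[i]][[nm]] * scale
        }
    }
    a
}

# One gradient step on the side-specific composite objective: compute
# gradients, then apply Adam to the parameter set the side updates.
.train_step <- function(side, gact, proj, opt, cfg, wts,
                        x_act, act_is_atac, x_par, par_is_atac,
                        q_sub, Ahat, anch_act = NULL, anch_par = NULL) {
    sg <- .step_grads(side, gact, proj, cfg, wts, x_act, act_is_atac,
                      x_par, par_is_atac, q_sub, Ahat, anch_act, anch_par,
                      gamCache = opt$last_gam)
    gact <- sg$gact; proj <- sg$proj
    opt$last_gam <- sg$gam_raw
    opt$t <- opt$t + 1L
    if (side == "ATAC") {
        upd <- .apply_grads(gact, sg$gact_grads, opt$gact, opt$lr, opt$t)
        gact <- upd$net; opt$gact <- upd$opt
    }
    upd <- .apply_grads(proj, sg$proj_grads, opt$proj, opt$lr, opt$t)
    proj <- upd$net; opt$proj <- upd$opt
    list(gact = gact, proj = proj, opt = opt, comp = sg$comp)
}

# Gradients of the side-specific composite objective w.r.t. all parameters
# (gene-activity gradients only assembled on ATAC-side steps, where they are
# updated). The active and partner minibatches (plus anchor cells, when
# given) pass through the projection network as ONE concatenated minibatch,
# so both modalities share the same batch-normalisation statistics each
# step; per-side statistics would silently whiten away the very
# distribution mismatch the alignment loss must see.
.step_grads <- function(side, gact, proj, cfg, wts,
                        x_act, act_is_atac, x_par, par_is_atac,
                        q_sub, Ahat, anch_act = NULL, anch_par = NULL,
                        gamCache = NULL) {
    use_anchor <- !is.null(anch_act) && !is.null(anch_par)
    m_act <- nrow(x_act); m_par <- nrow(x_par)
    xa <- if (use_anchor) rbind(x_act, anch_act) else x_act
    xp <- if (use_anchor) rbind(x_par, anch_par) else x_par
    na <- nrow(xa); np <- nrow(xp)

    # gene activity forward for whichever sides are ATAC
    fg_act <- fg_par <- NULL
    in_act <- xa
    if (act_is_atac) {
        fg_act <- .net_forward(gact, xa, TRUE, cfg)
        gact <- fg_act$net
        in_act <- fg_act$out
    }
    in_par <- xp
    if (par_is_atac) {
        fg_par <- .net_forward(gact, xp, TRUE, cfg)
        gact <- fg_par$net
        in_par <- fg_par$out
    }
    fp <- .net_forward(proj, rbind(in_act, in_par), TRUE, cfg)
    proj <- fp$net
    z_act <- fp$out[seq_len(m_act), , drop = FALSE]
    z_par <- fp$out[na + seq_len(m_par), , drop = FALSE]

    dl <- .distance_loss_core(z_act, q_sub, eps = 1e-12, grad = TRUE)
    mm <- .mmd_loss_grad(z_act, z_par)
    if (side != "ATAC" && !is.null(gamCache)) {
        # logging shortcut: the RNA step does not update the gene activity
        # module, so the most recently evaluated penalty is reused
        gp <- NULL
        gam_raw <- gamCache
    } else {
        gp <- .gam_penalty_grad(gact, Ahat)
        gam_raw <- gp$value
    }
    comp <- c(dist = dl$value, mmd = wts$lambdaMmd * mm$value,
              gam = wts$lambdaG * gam_raw, anchor = 0)

    dz <- matrix(0, na + np, ncol(z_act))
    dz[seq_len(m_act), ] <- dl$dZ + wts$lambdaMmd * mm$dZ1
    dz[na + seq_len(m_par), ] <- wts$lambdaMmd * mm$dZ2
    if (use_anchor) {
        ia <- (m_act + 1):na
        ip <- na + (m_par + 1):np
        z_anch_act <- fp$out[ia, , drop = FALSE]
        z_anch_par <- fp$out[ip, , drop = FALSE]
        # orient as (RNA, ATAC); loss is symmetric, gradients are signed
        if (act_is_atac) {
            al <- .anchor_loss_grad(z_anch_par, z_anch_act)
            dz[ia, ] <- wts$anchorWeight * al$dAtac
            dz[ip, ] <- wts$anchorWeight * al$dRna
        } else {
            al <- .anchor_loss_grad(z_anch_act, z_anch_par)
            dz[ia, ] <- wts$anchorWeight * al$dRna
            dz[ip, ] <- wts$anchorWeight * al$dAtac
        }
        comp[["anchor"]] <- wts$anchorWeight * al$value
    }

    bp <- .net_backward(proj, fp$caches, dz, TRUE, cfg)
    proj_grads <- bp$grads
    gact_grads <- NULL
    if (side == "ATAC") {
        if (act_is_atac) {
            bg <- .net_backward(gact, fg_act$caches,
                                bp$dinput[seq_len(na), , drop = FALSE],
                                TRUE, cfg)
            gact_grads <- .add_grads(gact_grads, bg$grads)
        }
        if (par_is_atac) {
            bg <- .net_backward(gact, fg_par$caches,
                                bp$dinput[na + seq_len(np), , drop = FALSE],
                                TRUE, cfg)
            gact_grads <- .add_grads(gact_grads, bg$grads)
        }
        gact_grads <- .add_grads(gact_grads,
                                 lapply(gp$grads, function(g) list(dW = g)),
                                 scale = wts$lambdaG)
    }
    list(gact = gact, proj = proj, comp = comp, gam_raw = gam_raw,
         gact_grads = gact_grads, proj_grads = proj_grads)
}

#' Quantile-normalise one distance matrix against a reference
#'
#' Samples values from the reference matrix with replacement to fill a matrix
#' of the target's size, sorts both, and replaces each target entry by the
#' sampled value of equal rank (ties in the target share one value). The
#' output preserves the target's rank order while adopting the reference's
#' value scale.
#'
#' @param dRef,dTarget square non-negative distance matrices.
#' @param seed integer seed for the sampling.
#' @return Matrix of `dTarget`'s shape with values drawn from `dRef`.
#' @export
quantileNormalizeDistances <- function(dRef, dTarget, seed = 0L) {
    .assert(length(dRef) > 0 && length(dTarget) > 0,
            "distance matrices must be non-empty")
    samp <- .with_seed(as.integer(seed),
                       sample(as.vector(dRef), length(dTarget),
                              replace = TRUE))
    samp <- sort(samp)
    out <- samp[rank(as.vector(dTarget), ties.method = "min")]
    matrix(out, nrow(dTarget), ncol(dTarget), dimnames = dimnames(dTarget))
}

#' Multi-batch alignment loss
#'
#' Sum of pairwise MMD losses between every batch embedding and the reference
#' batch embedding.
#'
#' @param zList list of embedding matrices (same latent dimension).
#' @param refIndex index of the reference batch.
#' @param gammas bandwidth grid.
#' @return Scalar loss; 0 (with a warning) for a single batch.
#' @export
multiBatchMmd <- function(zList, refIndex = 1L, gammas = gammaGrid()) {
    .assert(refIndex >= 1 && refIndex <= length(zList),
            "refIndex out of range")
    if (length(zList) == 1L) {
        warning("single batch: multi-batch MMD is 0")
        return(0)
    }
    sum(vapply(seq_along(zList)[-refIndex], function(i)
        mmdLoss(zList[[i]], zList[[refIndex]], gammas), 0))
}
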