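#' Define a trajectory tree
#'
#' A rooted tree given as an edge list with per-edge pseudotime lengths and
#' cell allocations. Node ids are arbitrary labels; the root is the unique
#' parent that never appears as a child.
#'
#' @param parent,child node labels per edge.
#' @param length pseudotime length per edge (positive).
#' @param nCells number of cells placed on each edge (>= 0).
#' @return A validated data.frame with class attribute `trajectoryTree`.
#' @examples
#' trajectoryTree(parent = c("1", "2", "2"), child = c("2", "3", "4"),
#'                length = c(1, 1, 1), nCells = c(100, 100, 100))
#' @export
trajectoryTree <- function(parent, child, length, nCells) {
    parent <- as.character(parent); child <- as.character(child)
    .assert(base::length(parent) >= 1, "tree must have at least one edge")
    .assert(all(length > 0), "edge lengths must be positive")
    .assert(all(nCells >= 0), "cell allocations must be >= 0")
    .assert(!anyDuplicated(child), "each node may have only one parent")
    roots <- setdiff(parent, child)
    .assert(base::length(roots) == 1,
            "tree must have exactly one root (found: %s)",
            paste(roots, collapse = ", "))
    # connectivity: every parent is the root or some edge's child
    .assert(all(parent %in% c(roots, child)), "tree is not connected")
    tr <- data.frame(parent = parent, child = child, length = length,
                     nCells = as.integer(nCells))
    class(tr) <- c("trajectoryTree", "data.frame")
    tr
}

#' Built-in trajectory presets
#'
#' Topologies mirroring the simulated regimes studied with this model:
#' `linear` (one path), `bifurcating` (one branch point, 3 branches),
#' `trifurcating` (one triple branch point, 4 branches), `smallbranch`
#' (trifurcating with one short, sparsely populated branch), `imbalanced`
#' (trifurcating sized for unequal batches) and `clusters` (3 discrete
#' groups).
#'
#' @param preset preset name.
#' @param totalCells total cells to allocate (default 3000, i.e. two batches
#'   of ~1500; the `smallbranch` and `imbalanced` presets carry their own
#'   characteristic sizes).
#' @return A [trajectoryTree()].
#' @export
presetTree <- function(preset = c("linear", "bifurcating", "trifurcating",
                                  "smallbranch", "imbalanced", "clusters"),
                       totalCells = 3000) {
    preset <- match.arg(preset)
    # Branch lengths and cell densities are deliberately unequal: real
    # differentiation snapshots over-represent early progenitors and have
    # branches of different depths, and a trajectory with identical arms and
    # uniform density is symmetric under arm exchange / path reversal, which
    # makes start and end unidentifiable for any method.
    alloc <- function(w) {
        n <- floor(totalCells * w)
        n[1] <- n[1] + totalCells - sum(n)
        n
    }
    switch(preset,
        linear = trajectoryTree(c("1", "2"), c("2", "3"), c(1, 0.8),
                                alloc(c(0.6, 0.4))),
        bifurcating = trajectoryTree(c("1", "2", "2"), c("2", "3", "4"),
                                     c(0.8, 1.2, 0.7),
                                     alloc(c(0.4, 0.35, 0.25))),
        trifurcating = trajectoryTree(c("1", "2", "2", "2"),
                                      c("2", "3", "4", "5"),
                                      c(0.8, 1.2, 0.9, 0.6),
                                      alloc(c(0.35, 0.25, 0.22, 0.18))),
        smallbranch = {
            rest <- totalCells - 202
            trajectoryTree(c("1", "2", "2", "2"), c("2", "3", "4", "5"),
                           c(0.8, 1.2, 0.9, 0.5),
                           c(round(rest * 0.4), round(rest * 0.32),
                             rest - round(rest * 0.4) - round(rest * 0.32),
                             202))
        },
        imbalanced = trajectoryTree(c("1", "2", "2", "2"),
                                    c("2", "3", "4", "5"),
                                    c(0.8, 1.2, 0.9, 0.6),
                                    c(785, 561, 494, 403)),
        clusters = trajectoryTree(c("1", "1", "1"), c("2", "3", "4"),
                                  c(1, 1, 1),
                                  alloc(c(0.34, 0.33, 0.33))))
}

#' Evolve cell identity vectors along a trajectory tree
#'
#' The root identity is drawn once; identities then evolve along the tree by
#' Brownian motion: cells are placed uniformly on each edge (sorted), and
#' consecutive positions differ by Gaussian increments with variance
#' proportional to the pseudotime gap, so the expected squared displacement
#' from the root grows linearly with pseudotime. Each cell additionally
#' receives a small independent increment for within-position individuality.
#' In `discrete` mode all cells sit at the child node of their edge, giving
#' point clusters.
#'
#' @param tree a [trajectoryTree()].
#' @param v identity vector length (default 30).
#' @param stepSd Brownian step standard deviation per coordinate per unit
#'   pseudotime (default 0.4).
#' @param cellJitter variance share of the per-cell individual increment
#'   (default 0.05).
#' @param discrete place cells at edge endpoints (point clusters).
#' @param seed integer seed.
#' @return List with `identity` (N x v), `pseudotime`, `branch` (edge label
#'   `parent_child` per cell) and `cellIds`.
#' @export
simulateIdentities <- function(tree, v = 30, stepSd = 0.4,
                               cellJitter = 0.05, discrete = FALSE,
                               seed = 0L) {
    .assert(v >= 1, "v must be >= 1")
    .assert(stepSd > 0, "stepSd must be positive")
    .assert(nrow(tree) >= 1, "empty tree")
    .with_seed(as.integer(seed), {
        root <- setdiff(tree$parent, tree$child)
        node_id <- list()
        node_depth <- list()
        node_id[[root]] <- stats::rnorm(v, mean = 1, sd = 0.5)
        node_depth[[root]] <- 0
        ids <- list(); pts <- list(); brs <- list()
        # edges in root-down order
        remaining <- seq_len(nrow(tree))
        done_nodes <- root
        order_e <- integer()
        while (length(remaining)) {
            nxt <- remaining[tree$parent[remaining] %in% done_nodes]
            order_e <- c(order_e, nxt)
            done_nodes <- c(done_nodes, tree$child[nxt])
            remaining <- setdiff(remaining, nxt)
        }
        for (e in order_e) {
            par <- tree$parent[e]; chd <- tree$child[e]
            L <- tree$length[e]; m <- tree$nCells[e]
            u <- if (m > 0) {
                if (discrete) rep(1, m) else sort(stats::runif(m))
            } else numeric()
            pos <- c(u, 1)  # walk visits each cell, then the child node
            cur <- node_id[[par]]
            prev <- 0
            cell_mat <- matrix(0, m, v)
            for (i in seq_along(pos)) {
                gap <- pos[i] - prev
                if (gap > 0)
                    cur <- cur + stats::rnorm(v, sd = stepSd * sqrt(gap * L))
                if (i <= m)
                    cell_mat[i, ] <- cur +
                        stats::rnorm(v, sd = stepSd * sqrt(cellJitter))
                prev <- pos[i]
            }
            node_id[[chd]] <- cur
            node_depth[[chd]] <- node_depth[[par]] + L
            if (m > 0) {
                ids[[e]] <- cell_mat
                pts[[e]] <- node_depth[[par]] + u * L
                brs[[e]] <- rep(paste0(par, "_", chd), m)
            }
        }
        keep <- order_e[tree$nCells[order_e] > 0]
        identity <- do.call(rbind, ids[keep])
        pseudotime <- unlist(pts[keep], use.names = FALSE)
        branch <- unlist(brs[keep], use.names = FALSE)
        cellIds <- sprintf("cell%04d", seq_len(nrow(identity)))
        rownames(identity) <- cellIds
        names(pseudotime) <- cellIds
        list(identity = identity, pseudotime = pseudotime, branch = branch,
             cellIds = cellIds)
    })
}

#' Simulate binary chromatin accessibility from cell identities
#'
#' Each region receives an identity vector of the same length as the cell
#' identities; the outer product of cell and region identities (plus
#' Gaussian noise) gives a raw accessibility propensity matrix, which is
#' then mapped rank-monotonically onto a realistic sparse binary
#' distribution. By default the target is parametric: each region draws an
#' accessible fraction from a Beta distribution and its top-ranked cells are
#' set accessible. An empirical reference matrix (binary cells x regions)
#' can be supplied instead; its per-region accessible fractions are then
#' resampled as the targets.
#'
#' @param cellIdentity N x v identity matrix from [simulateIdentities()].
#' @param nRegions number of regions R.
#' @param noiseSd standard deviation of propensity noise (default 0.3).
#' @param sparsityShape `c(alpha, beta)` of the Beta distribution of
#'   per-region accessible fractions (default `c(4, 12)`, mean 0.25).
#' @param referenceDistribution optional binary matrix whose per-column
#'   means replace the parametric sparsity model.
#' @param seed integer seed.
#' @return List with `counts` (binary N x R), `regionIdentity` (R x v) and
#'   `propensity` (the raw N x R matrix).
#' @export
simulateAtac <- function(cellIdentity, nRegions, noiseSd = 0.3,
                         sparsityShape = c(4, 12),
                         referenceDistribution = NULL, seed = 0L) {
    .assert(nRegions >= 1, "nRegions must be >= 1")
    v <- ncol(cellIdentity)
    n <- nrow(cellIdentity)
    .with_seed(as.integer(seed), {
        regionIdentity <- matrix(stats::rnorm(nRegions * v, sd = 1 / sqrt(v)),
                                 nRegions, v)
        S <- tcrossprod(cellIdentity, regionIdentity)
        if (noiseSd > 0)
            S <- S + matrix(stats::rnorm(n * nRegions, sd = noiseSd),
                            n, nRegions)
        q <- if (is.null(referenceDistribution)) {
            stats::rbeta(nRegions, sparsityShape[1], sparsityShape[2])
        } else {
            sample(colMeans(referenceDistribution > 0), nRegions,
                   replace = TRUE)
        }
        counts <- matrix(0, n, nRegions)
        for (r in seq_len(nRegions)) {
            m <- max(1L, min(n, round(q[r] * n)))
            counts[order(S[, r], decreasing = TRUE)[seq_len(m)], r] <- 1
        }
        dimnames(counts) <- list(rownames(cellIdentity),
                                 sprintf("region%04d", seq_len(nRegions)))
        rownames(regionIdentity) <- colnames(counts)
        list(counts = counts, regionIdentity = regionIdentity,
             propensity = S)
    })
}

#' Draw a random true region-to-gene coupling
#'
#' @param nRegions,nGenes dimensions.
#' @param linksPerGene range of regulating regions per gene (default 3 to 8).
#' @param seed integer seed.
#' @return A \linkS4class{GeneActivityMatrix}; every gene has at least one
#'   linked region.
#' @export
makeTrueGam <- function(nRegions, nGenes, linksPerGene = c(3L, 8L),
                        seed = 0L) {
    .with_seed(as.integer(seed), {
        A <- matrix(0, nRegions, nGenes,
                    dimnames = list(sprintf("region%04d", seq_len(nRegions)),
                                    sprintf("gene%04d", seq_len(nGenes))))
        for (g in seq_len(nGenes)) {
            nl <- sample(linksPerGene[1]:linksPerGene[2], 1)
            A[sample.int(nRegions, min(nl, nRegions)), g] <- 1
        }
        GeneActivityMatrix(A)
    })
}

#' Simulate expression counts coupled to chromatin accessibility
#'
#' Two-state (telegraph) kinetic model: each gene toggles between an on and
#' an off state at rates `k_on` / `k_off`; transcripts are synthesised at
#' rate `s` while on and degrade at rate `d` (fixed to 1, setting the time
#' unit). Counts are drawn from the stationary law
#' `p ~ Beta(k_on / d, k_off / d)`, `x ~ Poisson(p * s / d)`. The division
#' of labour between chromatin and trajectory follows the model's premise:
#' `k_off` and `s` derive from the cell identity vectors through per-gene
#' effect vectors (log-linear modulation of log-normal gene-level bases), so
#' they follow the trajectory; the burst frequency `k_on` depends on the
#' cell only through accessibility — a gene-wise log-normal base scaled by
#' `0.5 + 1.5 * fracOpen`, the fraction of the gene's coupled regions
#' accessible in that cell, monotone in accessibility.
#'
#' @param cellIdentity N x v identity matrix.
#' @param atacCounts binary N x R accessibility.
#' @param gam true \linkS4class{GeneActivityMatrix} (R x G).
#' @param nGenes number of genes G (must match `gam`).
#' @param seed integer seed.
#' @return List with `counts` (integer N x G) and `kinetics`
#'   (list of N x G matrices `k_on`, `k_off`, `s`, plus `fracOpen`).
#' @export
simulateRna <- function(cellIdentity, atacCounts, gam,
                        nGenes = ncol(gamMatrix(gam)), seed = 0L) {
    A <- .as_dense(gamMatrix(gam))
    .assert(ncol(A) == nGenes, "gam gene count mismatch")
    .assert(nrow(A) == ncol(atacCounts), "gam region count mismatch")
    v <- ncol(cellIdentity)
    n <- nrow(cellIdentity)
    .with_seed(as.integer(seed), {
        eff <- function() matrix(stats::rnorm(nGenes * v, sd = 1 / sqrt(v)),
                                 nGenes, v)
        E_off <- eff(); E_s <- eff()
        kon_base <- stats::rlnorm(nGenes, log(1), 0.3)
        koff_base <- stats::rlnorm(nGenes, log(1.5), 0.3)
        s_base <- stats::rlnorm(nGenes, log(50), 0.3)
        # unit log-linear modulation: expression-controlling rates vary
        # ~2-3 fold along the trajectory, conservative relative to real
        # differentiation markers but enough for the trajectory to be
        # visible in a per-modality PCA
        k_off <- sweep(exp(tcrossprod(cellIdentity, E_off)), 2,
                       koff_base, "*")
        s <- sweep(exp(tcrossprod(cellIdentity, E_s)), 2, s_base, "*")
        nlinked <- colSums(A)
        if (any(nlinked == 0))
            warning(sum(nlinked == 0),
                    " gene(s) have no coupled region; base k_on used")
        fracOpen <- atacCounts %*% A
        fracOpen <- sweep(fracOpen, 2, pmax(nlinked, 1), "/")
        fracOpen[, nlinked == 0] <- 1 / 3  # neutral: coupling factor 1
        k_on <- sweep(0.5 + 1.5 * fracOpen, 2, kon_base, "*")
        p <- matrix(stats::rbeta(n * nGenes, k_on, k_off), n, nGenes)
        counts <- matrix(stats::rpois(n * nGenes, p * s), n, nGenes)
        dimnames(counts) <- list(rownames(cellIdentity), colnames(A))
        list(counts = counts,
             kinetics = list(k_on = k_on, k_off = k_off, s = s,
                             fracOpen = fracOpen))
    })
}

#' Add technical noise and split matched cells into single-modality batches
#'
#' Cells are partitioned into batches; expression counts receive binomial
#' downsampling at each batch's capture efficiency and multiplicative
#' log-normal gene-wise batch factors; each exported batch keeps exactly one
#' modality (accessibility is exported as-is: it is already binarised).
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param captureEff capture efficiency per batch, each in (0, 1].
#' @param batchEffectSd standard deviation of log gene-wise batch factors
#'   (default 0.1).
#' @param keep list with integer vectors `rna` and `atac`: which batches
#'   export which modality (default batch 1 -> RNA, batch 2 -> ATAC).
#' @param batchAssign optional integer batch per cell (values in
#'   `seq_along(captureEff)`); random balanced split when `NULL`.
#' @param seed integer seed.
#' @return List with `batches` (named list of \linkS4class{OmicsBatch}),
#'   `batchAssign`, and `truth` (unchanged, for evaluation).
#' @export
addNoiseAndSplit <- function(truth, captureEff = c(0.5, 0.5),
                             batchEffectSd = 0.1,
                             keep = list(rna = 1L, atac = 2L),
                             batchAssign = NULL, seed = 0L) {
    .assert(all(captureEff > 0 & captureEff <= 1),
            "captureEff must be in (0, 1]")
    n <- nrow(rnaCounts(truth))
    nb <- length(captureEff)
    .with_seed(as.integer(seed), {
        if (is.null(batchAssign))
            batchAssign <- sample(rep(seq_len(nb), length.out = n))
        .assert(length(batchAssign) == n && all(batchAssign %in% seq_len(nb)),
                "batchAssign must give each cell a batch in 1..%d", nb)
        rna <- rnaCounts(truth)
        G <- ncol(rna)
        batches <- list()
        for (b in seq_len(nb)) {
            sel <- which(batchAssign == b)
            if (b %in% keep$rna) {
                f <- exp(stats::rnorm(G, sd = batchEffectSd))
                prob <- pmin(1, captureEff[b] * f)
                x <- rna[sel, , drop = FALSE]
                noisy <- matrix(stats::rbinom(length(x), as.vector(x),
                                              rep(prob, each = length(sel))),
                                length(sel), G, dimnames = dimnames(x))
                batches[[paste0("batch", b, "_rna")]] <-
                    OmicsBatch(noisy, "RNA", paste0("batch", b))
            }
            if (b %in% keep$atac) {
                x <- atacCounts(truth)[sel, , drop = FALSE]
                batches[[paste0("batch", b, "_atac")]] <-
                    OmicsBatch(x, "ATAC", paste0("batch", b))
            }
        }
        list(batches = batches, batchAssign = batchAssign, truth = truth)
    })
}

#' Simulate a matched multi-omic dataset and split it into unmatched batches
#'
#' End-to-end generator: identities along a trajectory preset (or custom
#' tree), binary accessibility, a true region-to-gene coupling, kinetic
#' expression counts driven by that coupling, technical noise, and a split
#' into one RNA-only and one ATAC-only batch. All ground truth (matching,
#' pseudotime, branches, coupling, kinetics) is retained for evaluation.
#'
#' @param preset preset name (see [presetTree()]) or a [trajectoryTree()].
#' @param totalCells total matched cells (split across two batches).
#' @param nGenes,nRegions feature counts (defaults 300 genes, 200 regions).
#' @param v identity dimension, `stepSd` Brownian step scale: see
#'   [simulateIdentities()].
#' @param stepSd Brownian step standard deviation.
#' @param captureEff,batchEffectSd expression noise: see
#'   [addNoiseAndSplit()].
#' @param seed integer seed; the full generator is reproducible from it.
#' @return List with `rna` and `atac` (\linkS4class{OmicsBatch}), `truth`
#'   (\linkS4class{SimulationTruth} over all matched cells), `batchAssign`,
#'   and per-batch truth indices `rnaCells`, `atacCells` (row indices into
#'   the matched matrices).
#' @export
simulateMultiome <- function(preset = "trifurcating", totalCells = 3000,
                             nGenes = 300, nRegions = 200, v = 30,
                             stepSd = 0.4, captureEff = c(0.5, 0.5),
                             batchEffectSd = 0.1, seed = 0L) {
    seed <- as.integer(seed)
    tree <- if (inherits(preset, "trajectoryTree")) preset
            else presetTree(preset, totalCells)
    discrete <- !inherits(preset, "trajectoryTree") &&
        identical(preset, "clusters")
    idl <- simulateIdentities(tree, v = v, stepSd = stepSd,
                              discrete = discrete, seed = seed)
    atac <- simulateAtac(idl$identity, nRegions, seed = seed + 1L)
    gam <- makeTrueGam(nRegions, nGenes, seed = seed + 2L)
    rna <- simulateRna(idl$identity, atac$counts, gam, seed = seed + 3L)
    truth <- new("SimulationTruth",
                 rnaCounts = rna$counts, atacCounts = atac$counts,
                 trueGam = gam, pseudotime = idl$pseudotime,
                 branch = idl$branch, cellIdentity = idl$identity,
                 regionIdentity = atac$regionIdentity,
                 kinetics = rna$kinetics,
                 params = list(preset = if (is.character(preset)) preset
                                        else "custom",
                               v = v, stepSd = stepSd, seed = seed))
    batchAssign <- NULL
    if (is.character(preset) && preset == "smallbranch") {
        # pin the small branch at ~95 RNA-batch and ~107 ATAC-batch cells
        small <- which(idl$branch == "2_5")
        other <- setdiff(seq_along(idl$branch), small)
        batchAssign <- integer(length(idl$branch))
        sm <- .with_seed(seed + 9L, sample(small))
        batchAssign[sm[seq_len(95)]] <- 1L
        batchAssign[sm[-seq_len(95)]] <- 2L
        ot <- .with_seed(seed + 10L, sample(other))
        batchAssign[ot] <- rep(1:2, length.out = length(ot))
    }
    if (is.character(preset) && preset == "imbalanced") {
        batchAssign <- .with_seed(seed + 9L,
            sample(rep(1:2, times = c(757, nrow(rna$counts) - 757))))
    }
    sp <- addNoiseAndSplit(truth, captureEff = captureEff,
                           batchEffectSd = batchEffectSd,
                           batchAssign = batchAssign, seed = seed + 4L)
    list(rna = sp$batches$batch1_rna, atac = sp$batches$batch2_atac,
         truth = truth, batchAssign = sp$batchAssign,
         rnaCells = which(sp$batchAssign == 1L),
         atacCells = which(sp$batchAssign == 2L))
}
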