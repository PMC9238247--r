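test_that("csv and mtx count matrices round-trip with ids intact", {
    m <- matrix(c(1, 0, 3, 2, 5, 0), 3, 2,
                dimnames = list(paste0("c", 1:3), c("geneA", "geneB")))
    csv <- tempfile(fileext = ".csv")
    write.csv(m, csv)
    ob <- loadCountMatrix(csv, "csv", modality = "RNA")
    expect_s4_class(ob, "OmicsBatch")
    expect_equal(dim(ob), c(3L, 2L))
    expect_equal(as.matrix(counts(ob)), m)

    dir <- tempfile()
    writeCountMatrix(ob, dir)
    back <- loadCountMatrix(dir, "mtx_dir", modality = "RNA")
    expect_equal(as.matrix(counts(back)), m)
    expect_equal(cellIds(back), rownames(m))
})

test_that("malformed mtx directories and h5ad requests are rejected", {
    dir <- tempfile()
    dir.create(dir)
    Matrix::writeMM(Matrix::Matrix(matrix(1:6, 3, 2), sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))    # too few
    writeLines(c("f1", "f2", "f3", "f4"), file.path(dir, "features.tsv"))
    expect_error(loadCountMatrix(dir, "mtx_dir"), "barcodes")
    expect_error(loadCountMatrix(tempfile(), "csv"), "does not exist")
    expect_error(loadCountMatrix(dir, "h5ad"), "HDF5")
})

test_that("gene activity windows follow the stated upstream rule", {
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(10000, 30000), c(12000, 33000)),
        strand = c("+", "-"))
    names(genes) <- c("gplus", "gminus")
    regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(8300, 6500, 11000, 33500, 36500, 50000),
        c(8500, 7000, 11100, 34000, 37000, 50100)))
    names(regions) <- paste0("r", 1:6)

    A <- gamMatrix(constructGam(regions, genes))
    expect_equal(A["r1", "gplus"], 1)  # ends 1500 bp upstream of TSS
    expect_equal(A["r2", "gplus"], 0)  # fully 3000 bp upstream
    expect_equal(A["r3", "gplus"], 1)  # inside gene body (flag on)
    expect_equal(A["r4", "gminus"], 1) # 1500 bp upstream on - strand
    expect_equal(A["r6", "gminus"], 0)

    A0 <- gamMatrix(constructGam(regions, genes, includeGeneBody = FALSE))
    expect_equal(A0["r3", "gplus"], 0) # gene body excluded
    expect_equal(A0["r1", "gplus"], 1)

    nostrand <- genes
    GenomicRanges::strand(nostrand) <- "*"
    expect_error(constructGam(regions, nostrand), "strand")
})

test_that("constructGam is permutation-equivariant in input order", {
    set.seed(7)
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sort(sample(1e5, 6)) * 10, width = 5000),
        strand = sample(c("+", "-"), 6, TRUE))
    names(genes) <- paste0("g", 1:6)
    regions <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1e6, 40), width = 300))
    names(regions) <- paste0("r", 1:40)
    A <- gamMatrix(constructGam(regions, genes))
    pr <- sample(40); pg <- sample(6)
    Ap <- gamMatrix(constructGam(regions[pr], genes[pg]))
    expect_equal(Ap, A[pr, pg])
})

test_that("RNA preprocessing normalises, log-transforms and ranks genes by dispersion", {
    m <- matrix(rpois(200 * 30, 5), 200, 30,
                dimnames = list(paste0("c", 1:200), sprintf("g%02d", 1:30)))
    m[, 1] <- 7                      # constant gene
    m[, 2] <- rpois(200, 60)         # dispersed gene
    ob <- OmicsBatch(m, "RNA", "b1")
    out <- preprocessRna(ob, nHvg = 10)
    expect_equal(ncol(counts(out)), 10L)
    expect_true(min(counts(out)) >= 0)
    expect_false("g01" %in% featureIds(out))  # constant gene never selected

    all_out <- preprocessRna(ob, nHvg = 30)
    expect_equal(ncol(counts(all_out)), 30L)  # no-op filter

    # equal counts in a cell stay equal after per-cell scaling
    full <- preprocessRna(ob)
    i <- which(m[, 5] == m[, 6])[1]
    expect_equal(counts(full)[i, "g05"], counts(full)[i, "g06"])

    m0 <- m; m0["c3", ] <- 0
    expect_error(preprocessRna(OmicsBatch(m0, "RNA", "b")), "c3")
})

test_that("ATAC preprocessing binarises and keeps only prior-linked regions", {
    m <- matrix(rpois(50 * 8, 1), 50, 8,
                dimnames = list(paste0("c", 1:50), paste0("r", 1:8)))
    m[1, 1] <- 7
    A <- matrix(1, 8, 3, dimnames = list(paste0("r", 1:8), paste0("g", 1:3)))
    A[4, ] <- 0                       # region with all-zero row is dropped
    out <- preprocessAtac(OmicsBatch(m, "ATAC", "b"), GeneActivityMatrix(A))
    x <- as.matrix(counts(out$batch))
    expect_true(all(x %in% c(0, 1)))
    expect_equal(x[1, 1], 1)          # count 7 -> 1
    expect_false("r4" %in% featureIds(out$batch))
    expect_equal(featureIds(out$batch), regionIds(out$gam))
    expect_equal(nrow(gamMatrix(out$gam)), ncol(counts(out$batch)))

    Aempty <- A * 0
    expect_error(preprocessAtac(OmicsBatch(m, "ATAC", "b"),
                                GeneActivityMatrix(Aempty)), "window")
})

test_that("OmicsBatch validity enforces ids and non-negativity", {
    m <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
    expect_error(OmicsBatch(m, "RNA", "b"), "duplicate")
    m2 <- matrix(c(-1, 1, 1, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
    expect_error(OmicsBatch(m2, "RNA", "b"), "non-negative")
})
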