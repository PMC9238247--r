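#' Load a count matrix into an OmicsBatch
#'
#' Reads a cells x features count matrix from one of the supported on-disk
#' layouts:
#' \describe{
#'   \item{`mtx_dir`}{a directory with `matrix.mtx` (cells as rows),
#'     `barcodes.tsv` (one cell id per line) and `features.tsv` (one feature
#'     id per line). A matrix stored features x cells (the common alignment
#'     of public data) is transposed automatically when the id files identify
#'     the orientation unambiguously.}
#'   \item{`csv`}{plain CSV, first column cell ids, header row feature ids.}
#' }
#'
#' @param path file (csv) or directory (mtx_dir).
#' @param format one of `"mtx_dir"`, `"csv"`, `"h5ad"`.
#' @param modality `"RNA"` or `"ATAC"`.
#' @param batchId batch identifier string (defaults to the file/dir name).
#' @return An \linkS4class{OmicsBatch}.
#' @export
loadCountMatrix <- function(path, format = c("mtx_dir", "csv", "h5ad"),
                            modality = "RNA", batchId = basename(path)) {
    format <- match.arg(format)
    .assert(file.exists(path), "path does not exist: %s", path)
    if (format == "h5ad") {
        stop("h5ad input requires an HDF5 reader, which this installation ",
             "does not provide; export the matrix as mtx_dir or csv instead",
             call. = FALSE)
    }
    if (format == "csv") {
        df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
        m <- as.matrix(df)
        storage.mode(m) <- "double"
    } else {
        mtx <- file.path(path, "matrix.mtx")
        bc <- file.path(path, "barcodes.tsv")
        ft <- file.path(path, "features.tsv")
        for (f in c(mtx, bc, ft))
            .assert(file.exists(f), "missing companion file: %s", f)
        m <- Matrix::readMM(mtx)
        cells <- readLines(bc)
        feats <- readLines(ft)
        if (nrow(m) == length(cells) && ncol(m) == length(feats)) {
            # stored cells x features
        } else if (nrow(m) == length(feats) && ncol(m) == length(cells)) {
            m <- Matrix::t(m)
        } else {
            stop(sprintf(
                "matrix is %d x %d but barcodes.tsv has %d and features.tsv has %d entries",
                nrow(m), ncol(m), length(cells), length(feats)), call. = FALSE)
        }
        dimnames(m) <- list(cells, feats)
    }
    .assert(!anyDuplicated(colnames(m)), "duplicate feature ids in %s", path)
    .assert(!anyDuplicated(rownames(m)), "duplicate cell ids in %s", path)
    OmicsBatch(m, modality = modality, batchId = batchId)
}

#' Write an OmicsBatch as an mtx directory
#'
#' Inverse of [loadCountMatrix()] for the `mtx_dir` format (cells as rows).
#'
#' @param batch an \linkS4class{OmicsBatch}.
#' @param path output directory, created if needed.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(batch, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- counts(batch)
    if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(cellIds(batch), file.path(path, "barcodes.tsv"))
    writeLines(featureIds(batch), file.path(path, "features.tsv"))
    invisible(path)
}

#' Build the proximity-based gene activity matrix
#'
#' Marks `A[r, g] = 1` when region `r` overlaps the putative regulatory window
#' of gene `g`: the `upstreamWindow` base pairs immediately upstream of the
#' gene body (strand-aware), plus the gene body itself when
#' `includeGeneBody = TRUE` (the default; set `FALSE` for the upstream-only
#' definition).
#'
#' @param regions `GRanges` of accessible regions, named (or names are
#'   generated as `chr:start-end`).
#' @param genes `GRanges` of gene bodies with strand (`+`/`-`) and names.
#' @param upstreamWindow integer width of the upstream window in bp
#'   (default 2000).
#' @param includeGeneBody logical; also count overlap with the gene body.
#' @return A \linkS4class{GeneActivityMatrix} ordered as the inputs.
#' @examples
#' library(GenomicRanges)
#' genes <- GRanges("chr1", IRanges(10000, 12000), strand = "+")
#' names(genes) <- "geneA"
#' regions <- GRanges("chr1", IRanges(c(8600, 6500, 11000), width = 200))
#' names(regions) <- paste0("r", 1:3)
#' gamMatrix(constructGam(regions, genes))          # r1 and r3 linked
#' gamMatrix(constructGam(regions, genes, includeGeneBody = FALSE))
#' @importFrom GenomicRanges promoters resize findOverlaps strand
#' @importFrom S4Vectors queryHits subjectHits
#' @export
constructGam <- function(regions, genes, upstreamWindow = 2000,
                         includeGeneBody = TRUE) {
    .assert(length(genes) > 0 && length(regions) > 0,
            "regions and genes must be non-empty")
    .assert(all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-")),
            "every gene must carry a '+' or '-' strand")
    if (is.null(names(genes)))
        stop("genes must be named", call. = FALSE)
    if (is.null(names(regions)))
        names(regions) <- paste0(GenomicRanges::seqnames(regions), ":",
                                 GenomicRanges::start(regions), "-",
                                 GenomicRanges::end(regions))
    windows <- if (includeGeneBody) {
        # gene body extended upstream: anchor the downstream (3') end
        suppressWarnings(GenomicRanges::resize(
            genes, GenomicRanges::width(genes) + upstreamWindow, fix = "end"))
    } else {
        suppressWarnings(GenomicRanges::promoters(
            genes, upstream = upstreamWindow, downstream = 0))
    }
    windows <- GenomicRanges::trim(windows)
    hits <- GenomicRanges::findOverlaps(regions, windows, ignore.strand = TRUE)
    A <- matrix(0, length(regions), length(genes),
                dimnames = list(names(regions), names(genes)))
    A[cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))] <- 1
    GeneActivityMatrix(A)
}

#' Preprocess an scRNA-seq batch
#'
#' Library-size normalisation to the median library size of the batch,
#' `log(1 + x)` transform, and optional restriction to the most highly
#' variable genes ranked by dispersion (variance / mean of the log-normalised
#' values; ties broken by gene id). Simulated data are conventionally used
#' without feature filtering (`nHvg = NULL`).
#'
#' @param batch an RNA \linkS4class{OmicsBatch} of raw counts.
#' @param nHvg number of highly variable genes to keep (typically 500 or
#'   1000), or `NULL` to keep all genes.
#' @return A preprocessed \linkS4class{OmicsBatch}.
#' @export
preprocessRna <- function(batch, nHvg = NULL) {
    .assert(modality(batch) == "RNA", "preprocessRna expects an RNA batch")
    x <- .as_dense(counts(batch))
    lib <- rowSums(x)
    if (any(lib == 0))
        stop("cells with zero library size: ",
             paste(rownames(x)[lib == 0], collapse = ", "), call. = FALSE)
    scale_c <- stats::median(lib)
    xn <- log1p(x / lib * scale_c)
    if (!is.null(nHvg)) {
        .assert(nHvg >= 1 && nHvg <= ncol(xn),
                "nHvg must be in [1, %d]", ncol(xn))
        mu <- colMeans(xn)
        v <- apply(xn, 2, stats::var)
        disp <- ifelse(mu > 0, v / mu, 0)
        ord <- order(-disp, colnames(xn))
        keep <- sort(ord[seq_len(nHvg)])
        xn <- xn[, keep, drop = FALSE]
    }
    fr <- featureRanges(batch)
    if (!is.null(fr)) fr <- fr[match(colnames(xn), featureIds(batch))]
    OmicsBatch(xn, "RNA", batchId(batch), fr)
}

#' Preprocess an scATAC-seq batch against a gene activity matrix
#'
#' Binarises accessibility (`x > 0`) and restricts regions to those linked to
#' at least one retained gene in the prior, subsetting the prior consistently.
#'
#' @param batch an ATAC \linkS4class{OmicsBatch} of raw counts.
#' @param gam a \linkS4class{GeneActivityMatrix} whose region ids are a subset
#'   of the batch's features and whose gene ids are the retained genes.
#' @return A list with elements `batch` (binary, filtered) and `gam`
#'   (row-subset to the retained regions).
#' @export
preprocessAtac <- function(batch, gam) {
    .assert(modality(batch) == "ATAC", "preprocessAtac expects an ATAC batch")
    A <- .as_dense(gamMatrix(gam))
    .assert(all(rownames(A) %in% featureIds(batch)),
            "gam region ids must be a subset of the batch's features")
    x <- .as_dense(counts(batch))[, rownames(A), drop = FALSE]
    x <- (x > 0) * 1
    keep <- rowSums(A) > 0
    if (!any(keep))
        stop("no region is linked to any retained gene; ",
             "rebuild the prior with a larger upstream window", call. = FALSE)
    A <- A[keep, , drop = FALSE]
    x <- x[, keep, drop = FALSE]
    fr <- featureRanges(batch)
    if (!is.null(fr)) fr <- fr[match(colnames(x), featureIds(batch))]
    list(batch = OmicsBatch(x, "ATAC", batchId(batch), fr),
         gam = GeneActivityMatrix(A))
}

#' Read gene annotation into gene-body ranges
#'
#' Convenience wrapper around `rtracklayer::import` that extracts named,
#' stranded gene bodies from a GTF/GFF file, or named regions from BED.
#'
#' @param path GTF/GFF/BED file.
#' @param feature for GTF/GFF, the feature type to keep (default `"gene"`).
#' @param nameField metadata column holding names (default `"gene_id"` for
#'   GTF/GFF; BED names are used as-is).
#' @return A named `GRanges`.
#' @export
readAnnotation <- function(path, feature = "gene", nameField = "gene_id") {
    gr <- rtracklayer::import(path)
    if (grepl("\\.(gtf|gff|gff3)$", path, ignore.case = TRUE)) {
        if ("type" %in% names(S4Vectors::mcols(gr)) &&
            any(gr$type == feature))
            gr <- gr[gr$type == feature]
        if (nameField %in% names(S4Vectors::mcols(gr)))
            names(gr) <- S4Vectors::mcols(gr)[[nameField]]
    } else if (!is.null(gr$name)) {
        names(gr) <- gr$name
    }
    gr
}
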