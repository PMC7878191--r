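#' @importFrom Matrix readMM colSums rowSums t sparseMatrix
#' @importFrom SingleCellExperiment SingleCellExperiment counts
#' @importFrom SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Barcode quality-control thresholds
#'
#' Defaults are the stated filters: barcodes with fewer than 250 detected
#' genes, more than 4,000 detected genes, more than 15,000 UMIs, or more
#' than 10\% of counts from mitochondrial genes are excluded. All
#' violations are strict, so the boundary values themselves are kept.
#'
#' @param minGenes,maxGenes,maxUmis,maxMitoFraction threshold values.
#' @return list with class \code{"qcThresholds"}.
#' @export
qcThresholds <- function(minGenes = 250L, maxGenes = 4000L,
                         maxUmis = 15000L, maxMitoFraction = 0.10) {
    if (minGenes >= maxGenes)
        stop("minGenes must be below maxGenes")
    if (minGenes <= 0 || maxUmis <= 0 || maxMitoFraction <= 0)
        stop("thresholds must be positive")
    structure(list(minGenes = as.integer(minGenes),
                   maxGenes = as.integer(maxGenes),
                   maxUmis = as.integer(maxUmis),
                   maxMitoFraction = maxMitoFraction),
              class = "qcThresholds")
}

#' Highly-variable-gene selection criteria
#'
#' A gene is highly variable when the mean of its non-zero normalized
#' values lies strictly inside (\code{nonzeroMeanLow}, \code{nonzeroMeanHigh})
#' and the standard deviation of its normalized values over all cells
#' (n-1 denominator, zeros included) exceeds \code{sdMin}.
#'
#' @param nonzeroMeanLow,nonzeroMeanHigh,sdMin criterion bounds
#'   (defaults 0.0125, 4, 0.5).
#' @return list with class \code{"hvgCriteria"}.
#' @export
hvgCriteria <- function(nonzeroMeanLow = 0.0125, nonzeroMeanHigh = 4,
                        sdMin = 0.5) {
    if (nonzeroMeanLow >= nonzeroMeanHigh)
        stop("nonzeroMeanLow must be below nonzeroMeanHigh")
    structure(list(nonzeroMeanLow = nonzeroMeanLow,
                   nonzeroMeanHigh = nonzeroMeanHigh, sdMin = sdMin),
              class = "hvgCriteria")
}

#' Read a 10x-style Matrix-Market triplet count matrix
#'
#' Reads matrix.mtx (coordinate format, 1-based indices), barcodes.tsv (one
#' barcode per line) and features.tsv (three columns: id, symbol, type)
#' into a \linkS4class{SingleCellExperiment} with a sparse \code{counts}
#' assay. Mitochondrial genes are flagged by matching the feature symbol
#' against \code{mitoPattern}.
#'
#' @param matrixPath,barcodesPath,featuresPath file paths.
#' @param mitoPattern regular expression on feature symbols (default
#'   \code{"^mt-"}, case-insensitive).
#' @return SingleCellExperiment; \code{rowData} carries id, symbol, type
#'   and the logical \code{mito} flag.
#' @export
readMtxCounts <- function(matrixPath, barcodesPath, featuresPath,
                          mitoPattern = "^mt-") {
    for (p in c(matrixPath, barcodesPath, featuresPath))
        if (!file.exists(p)) stop("file not found: ", p)
    header <- readLines(matrixPath, n = 1L)
    if (!grepl("^%%MatrixMarket matrix coordinate", header))
        stop("missing Matrix-Market coordinate header in ", matrixPath)
    m <- as(readMM(matrixPath), "TsparseMatrix")
    if (anyDuplicated(cbind(m@i, m@j)))
        stop("duplicate (gene, barcode) triplets in ", matrixPath)
    barcodes <- readLines(barcodesPath)
    features <- read.delim(featuresPath, header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(features) < 3L)
        stop("features file needs 3 columns: id, symbol, type")
    colnames(features)[1:3] <- c("id", "symbol", "type")
    if (nrow(m) != nrow(features) || ncol(m) != length(barcodes))
        stop("matrix dimensions disagree with barcode/feature files")
    counts <- as(m, "CsparseMatrix")
    dimnames(counts) <- list(features$id, barcodes)
    rd <- DataFrame(features[, 1:3],
                    mito = grepl(mitoPattern, features$symbol,
                                 ignore.case = TRUE))
    rownames(rd) <- features$id
    SingleCellExperiment(assays = list(counts = counts), rowData = rd)
}

#' Write a count matrix in 10x-style Matrix-Market triplet format
#'
#' Writes matrix.mtx with the header
#' \code{\%\%MatrixMarket matrix coordinate integer general} and 1-based
#' indices, plus barcodes.tsv and a three-column features.tsv.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay; rowData must
#'   carry \code{id}, \code{symbol} and \code{type} columns (filled from
#'   rownames if absent).
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeMtxCounts <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- as(counts(sce), "TsparseMatrix")
    mtx <- file.path(dir, "matrix.mtx")
    con <- file(mtx, "w")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
    if (length(m@x) > 0L)
        writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L,
                           as.integer(m@x)), con)
    close(con)
    bc <- file.path(dir, "barcodes.tsv")
    writeLines(colnames(sce), bc)
    rd <- rowData(sce)
    feat <- data.frame(
        id = if ("id" %in% colnames(rd)) rd$id else rownames(sce),
        symbol = if ("symbol" %in% colnames(rd)) rd$symbol
                 else rownames(sce),
        type = if ("type" %in% colnames(rd)) rd$type
               else "Gene Expression")
    ft <- file.path(dir, "features.tsv")
    write.table(feat, ft, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(c(matrix = mtx, barcodes = bc, features = ft))
}

.barcodeMetrics <- function(sce) {
    m <- counts(sce)
    mito <- rowData(sce)$mito
    if (is.null(mito)) stop("rowData(sce)$mito flag is required")
    umis <- Matrix::colSums(m)
    data.frame(barcode = colnames(sce),
               genes_detected = Matrix::colSums(m > 0),
               total_umis = umis,
               mito_fraction = ifelse(umis > 0,
                   Matrix::colSums(m[mito, , drop = FALSE]) / umis, 0),
               stringsAsFactors = FALSE)
}

#' Filter barcodes by quality control and drop undetected genes
#'
#' A barcode is kept iff its detected-gene count lies in
#' [minGenes, maxGenes], its UMI total is at most maxUmis and its
#' mitochondrial count fraction is at most maxMitoFraction (the stated
#' "less than" / "more than" rules read as strict violations, so boundary
#' values are kept). Genes with zero total count across the kept barcodes
#' are then removed. The mitochondrial fraction denominator is the
#' barcode's total UMI count.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay and a
#'   \code{mito} rowData flag.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return list with the filtered \code{sce}, the per-barcode
#'   \code{report} data.frame (metrics, kept flag, semicolon-separated
#'   exclusion reasons), and a \code{summary} list (barcodes in/kept,
#'   counts per reason, genes removed).
#' @export
qcFilter <- function(sce, thresholds = qcThresholds()) {
    if (ncol(sce) == 0L || nrow(sce) == 0L)
        stop("empty count matrix")
    t <- thresholds
    met <- .barcodeMetrics(sce)
    viol <- cbind(
        min_genes = met$genes_detected < t$minGenes,
        max_genes = met$genes_detected > t$maxGenes,
        max_umis = met$total_umis > t$maxUmis,
        max_mito_fraction = met$mito_fraction > t$maxMitoFraction)
    kept <- rowSums(viol) == 0L
    reasons <- apply(viol, 1L, function(v)
        paste(colnames(viol)[v], collapse = ";"))
    report <- cbind(met, kept = kept, reasons = reasons)
    out <- sce[, kept]
    geneTotals <- Matrix::rowSums(counts(out))
    genesRemoved <- rownames(out)[geneTotals == 0]
    out <- out[geneTotals > 0, ]
    summary <- list(
        n_barcodes = ncol(sce), n_kept = sum(kept),
        n_excluded = sum(!kept),
        reason_counts = colSums(viol),
        n_genes_removed = length(genesRemoved),
        genes_removed = genesRemoved)
    list(sce = out, report = report, summary = summary)
}

#' Log-normalize single-cell counts
#'
#' Each count becomes \code{ln(1 + count * scale / barcode_total)}. Zeros
#' map to zeros, so sparsity is preserved.
#'
#' @param sce filtered SingleCellExperiment; every barcode must have a
#'   positive total count.
#' @param scale library-size scale factor (default 10,000).
#' @return the SingleCellExperiment with an added \code{lognorm} assay.
#' @export
logNormalizeCounts <- function(sce, scale = 1e4) {
    m <- as(counts(sce), "CsparseMatrix")
    totals <- Matrix::colSums(m)
    if (any(totals == 0))
        stop("barcode(s) with zero total count; run qcFilter first")
    norm <- m
    norm@x <- log1p(m@x * scale / rep.int(totals, diff(m@p)))
    SummarizedExperiment::assays(sce)$lognorm <- norm
    sce
}

#' Select highly variable genes
#'
#' @param sce SingleCellExperiment with a \code{lognorm} assay (see
#'   \code{\link{logNormalizeCounts}}).
#' @param criteria a \code{\link{hvgCriteria}} object.
#' @return character vector of highly-variable gene ids. Genes with no
#'   non-zero values are excluded (their non-zero mean is undefined).
#' @export
selectHvg <- function(sce, criteria = hvgCriteria()) {
    m <- as(SummarizedExperiment::assay(sce, "lognorm"), "CsparseMatrix")
    n <- ncol(m)
    nnz <- Matrix::rowSums(m != 0)
    rowTot <- Matrix::rowSums(m)
    nzMean <- ifelse(nnz > 0, rowTot / nnz, NA_real_)
    mu <- rowTot / n
    sdAll <- sqrt(pmax(Matrix::rowSums(m^2) - n * mu^2, 0) / (n - 1))
    sel <- !is.na(nzMean) &
        nzMean > criteria$nonzeroMeanLow &
        nzMean < criteria$nonzeroMeanHigh &
        sdAll > criteria$sdMin
    rownames(m)[sel]
}

#' Average-linkage dendrogram of cluster centroids
#'
#' Computes the mean normalized expression of each cluster over a gene
#' subset, the Euclidean distances between these centroids, and an
#' average-linkage agglomerative tree relating the clusters.
#'
#' @param sce SingleCellExperiment with a \code{lognorm} assay.
#' @param clusterLabels named character/factor vector, barcode -> cluster;
#'   every barcode of \code{sce} must be labelled.
#' @param geneSubset genes to compute centroids over (default: all genes).
#' @return an \code{ape} \code{phylo} tree whose leaves are the cluster
#'   labels; serialize with \code{ape::write.tree}.
#' @export
clusterCentroidTree <- function(sce, clusterLabels, geneSubset = NULL) {
    if (is.null(names(clusterLabels)))
        stop("clusterLabels must be named by barcode")
    miss <- setdiff(colnames(sce), names(clusterLabels))
    if (length(miss) > 0L)
        stop("unlabelled barcodes: ", paste(head(miss, 5), collapse = ", "))
    lab <- as.character(clusterLabels[colnames(sce)])
    lev <- sort(unique(lab))
    if (length(lev) < 2L)
        stop("need at least 2 clusters")
    sizes <- table(factor(lab, levels = lev))
    if (any(sizes == 0L))
        stop("cluster with 0 cells")
    m <- SummarizedExperiment::assay(sce, "lognorm")
    if (!is.null(geneSubset)) {
        bad <- setdiff(geneSubset, rownames(m))
        if (length(bad) > 0L)
            stop("genes absent from the matrix: ",
                 paste(head(bad, 5), collapse = ", "))
        m <- m[geneSubset, , drop = FALSE]
    }
    ind <- sparseMatrix(i = seq_along(lab),
                        j = match(lab, lev),
                        x = 1 / as.numeric(sizes)[match(lab, lev)],
                        dims = c(length(lab), length(lev)))
    centroids <- t(as.matrix(m %*% ind))
    rownames(centroids) <- lev
    hc <- hclust(dist(centroids, method = "euclidean"),
                 method = "average")
    ape::as.phylo(hc)
}

#' Tissue-by-cluster composition table
#'
#' Cross-tabulates the tissue of origin against the cluster assignment over
#' the shared barcodes, and reports per-tissue proportions (each tissue row
#' sums to 1).
#'
#' @param tissueLabels,clusterLabels named vectors, barcode -> label.
#' @return list with the counts \code{table} (tissue x cluster), the
#'   \code{proportions} matrix, and \code{nShared}.
#' @export
compositionTable <- function(tissueLabels, clusterLabels) {
    if (is.null(names(tissueLabels)) || is.null(names(clusterLabels)))
        stop("label vectors must be named by barcode")
    shared <- intersect(names(tissueLabels), names(clusterLabels))
    if (length(shared) == 0L)
        stop("no shared barcodes")
    tab <- table(tissue = as.character(tissueLabels[shared]),
                 cluster = as.character(clusterLabels[shared]))
    prop <- sweep(tab, 1L, rowSums(tab), "/")
    list(table = tab, proportions = prop, nShared = length(shared))
}
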