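# build a tiny SCE by hand for boundary tests
makeSce <- function(counts, mito = rep(FALSE, nrow(counts))) {
    rd <- S4Vectors::DataFrame(
        id = rownames(counts), symbol = rownames(counts),
        type = "Gene Expression", mito = mito,
        row.names = rownames(counts))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(Matrix::Matrix(counts, sparse = TRUE),
                                  "CsparseMatrix")),
        rowData = rd)
}

test_that("mtx reader validates files and flags mitochondrial genes", {
    d <- withr::local_tempdir()
    counts <- matrix(0, 6, 3, dimnames = list(
        paste0("ENSG", 1:6), paste0("BC", 1:3)))
    counts[1, 1] <- 5; counts[2, 2] <- 1; counts[6, 3] <- 2
    sce <- makeSce(counts)
    SummarizedExperiment::rowData(sce)$symbol <-
        c("mt-Co1", paste0("Gene", 2:6))
    writeMtxCounts(sce, d)
    back <- readMtxCounts(file.path(d, "matrix.mtx"),
                          file.path(d, "barcodes.tsv"),
                          file.path(d, "features.tsv"))
    expect_equal(SummarizedExperiment::rowData(back)$mito,
                 c(TRUE, rep(FALSE, 5)))
    expect_equal(as.matrix(SingleCellExperiment::counts(back)), counts)

    # duplicate triplet is rejected
    lines <- readLines(file.path(d, "matrix.mtx"))
    lines[2] <- "6 3 4"
    writeLines(c(lines, lines[3]), file.path(d, "matrix.mtx"))
    expect_error(readMtxCounts(file.path(d, "matrix.mtx"),
                               file.path(d, "barcodes.tsv"),
                               file.path(d, "features.tsv")),
                 "duplicate")
    # out-of-range index is rejected
    writeLines(c(lines[1], "6 3 1", "7 1 4"), file.path(d, "matrix.mtx"))
    expect_error(readMtxCounts(file.path(d, "matrix.mtx"),
                               file.path(d, "barcodes.tsv"),
                               file.path(d, "features.tsv")))
    expect_error(readMtxCounts(file.path(d, "nope.mtx"),
                               file.path(d, "barcodes.tsv"),
                               file.path(d, "features.tsv")),
                 "not found")
})

test_that("QC boundaries are kept, strict violations excluded", {
    nGenes <- 4200
    counts <- matrix(0, nGenes, 5, dimnames = list(
        paste0("g", seq_len(nGenes)), paste0("bc", 1:5)))
    mito <- c(TRUE, rep(FALSE, nGenes - 1))
    counts[2:250, 1] <- 1                       # 249 genes -> excluded
    counts[2:251, 2] <- 1                       # 250 genes -> kept
    counts[2:4001, 3] <- 1                      # exactly 4000 genes -> kept
    counts[2:251, 4] <- 60                      # exactly 15000 UMIs -> kept
    counts[1, 5] <- 30; counts[2:271, 5] <- 1   # mito 30/300 = 0.10 -> kept
    sce <- makeSce(counts, mito)
    qc <- qcFilter(sce)
    expect_equal(qc$report$kept, c(FALSE, TRUE, TRUE, TRUE, TRUE))
    expect_equal(qc$report$reasons[1], "min_genes")
    expect_equal(qc$report$total_umis[4], 15000)
    expect_equal(qc$report$mito_fraction[5], 0.10)
    # one more UMI / gene / mito count tips each over
    counts[2, 4] <- 61                          # 15001 UMIs
    counts[4002, 3] <- 1                        # 4001 genes
    counts[1, 5] <- 31                          # mito > 10%
    qc2 <- qcFilter(makeSce(counts, mito))
    expect_equal(qc2$report$kept, c(FALSE, TRUE, FALSE, FALSE, FALSE))
    expect_equal(qc2$report$reasons[3], "max_genes")
    expect_equal(qc2$report$reasons[4], "max_umis")
    expect_equal(qc2$report$reasons[5], "max_mito_fraction")
})

test_that("genes seen only in excluded barcodes are removed", {
    counts <- matrix(0, 300, 2, dimnames = list(
        paste0("g", 1:300), c("good", "bad")))
    counts[1:260, "good"] <- 1
    counts[291:300, "bad"] <- 1   # only 10 genes detected -> excluded
    qc <- qcFilter(makeSce(counts))
    expect_equal(colnames(qc$sce), "good")
    expect_false(any(paste0("g", 291:300) %in% rownames(qc$sce)))
    expect_equal(qc$summary$n_genes_removed, 40)
    expect_error(qcFilter(makeSce(counts[, 0])), "empty")
})

test_that("QC filter equals the brute-force recount and is idempotent", {
    sce <- simulateScCounts(nCellsGood = 120, nBarcodesJunk = 40,
                            seed = 17)
    qc <- qcFilter(sce)
    expect_setequal(colnames(qc$sce), qcRecountOracle(sce))
    expect_equal(ncol(qc$sce), 120)
    again <- qcFilter(qc$sce)
    expect_equal(as.matrix(SingleCellExperiment::counts(again$sce)),
                 as.matrix(SingleCellExperiment::counts(qc$sce)))
    expect_equal(again$summary$n_excluded, 0)
})

test_that("log-normalization follows ln(1 + count * scale / total)", {
    counts <- matrix(0, 4, 2, dimnames = list(paste0("g", 1:4),
                                              c("b1", "b2")))
    counts[1, 1] <- 1; counts[2, 1] <- 9999
    counts[3, 2] <- 4; counts[4, 2] <- 16
    sce <- logNormalizeCounts(makeSce(counts))
    ln <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
    expect_equal(ln[1, 1], log(2))             # total 10000, count 1
    expect_equal(ln[4, 1], 0)                  # zero stays zero
    expect_equal(ln[3, 2], log1p(4 * 1e4 / 20))
    # per-barcode scale invariance
    sce2 <- logNormalizeCounts(makeSce(counts * 2))
    expect_equal(as.matrix(SummarizedExperiment::assay(sce2, "lognorm")),
                 ln)
    zero <- makeSce(matrix(c(1, 0), 1, 2,
                           dimnames = list("g", c("a", "b"))))
    expect_error(logNormalizeCounts(zero), "zero total")
})

test_that("HVG selection applies the stated bounds", {
    # gene rows engineered around each bound of the criteria
    n <- 20
    vals <- rbind(
        lowMean = c(rep(0.012, 10), rep(0, 10)),  # nz mean 0.012 <= 0.0125
        sdLow = c(rep(0.9, 10), rep(0, 10)),      # nz mean 0.9, sd ~ 0.46
        good = c(rep(2, 10), rep(0, 10)),         # nz mean 2, sd ~ 1
        highMean = c(rep(4.5, 12), rep(0, 8)))    # nz mean 4.5 >= 4
    colnames(vals) <- paste0("b", 1:n)
    sce <- makeSce(matrix(1, 4, n, dimnames = dimnames(vals)))
    SummarizedExperiment::assays(sce)$lognorm <-
        as(Matrix::Matrix(vals, sparse = TRUE), "CsparseMatrix")
    expect_equal(selectHvg(sce), "good")
    expect_equal(selectHvg(sce), hvgOracle(sce))
    # brute-force equality on simulated data
    sim <- simulateScCounts(nCellsGood = 80, nBarcodesJunk = 0,
                            nGenes = 1000, seed = 23)
    norm <- logNormalizeCounts(qcFilter(sim)$sce)
    expect_setequal(selectHvg(norm), hvgOracle(norm))
})

test_that("centroid tree equals brute-force average linkage", {
    sim <- simulateScCounts(nCellsGood = 120, nBarcodesJunk = 0,
                            nClusters = 4, seed = 29)
    norm <- logNormalizeCounts(qcFilter(sim)$sce)
    cl <- plantedTruth(sim)$cellClusters
    tree <- clusterCentroidTree(norm, cl)
    expect_setequal(tree$tip.label, unique(cl))
    # merge heights match a hand-rolled average-linkage agglomeration
    m <- as.matrix(SummarizedExperiment::assay(norm, "lognorm"))
    cent <- t(sapply(sort(unique(cl)), function(k)
        rowMeans(m[, names(cl)[cl == k], drop = FALSE])))
    hc <- hclust(dist(cent), method = "average")
    expect_equal(sort(hc$height),
                 sort(averageLinkageHeightsOracle(dist(cent))),
                 tolerance = 1e-10)
    # permuting the cells leaves the tree unchanged
    perm <- sample(colnames(norm))
    tree2 <- clusterCentroidTree(norm[, perm], cl[perm])
    expect_true(ape::all.equal.phylo(tree, tree2))
})

test_that("two planted tight pairs of clusters join first", {
    # centroids at 0, 0.1, 10, 10.1 on one axis: average linkage must
    # join (A,B) and (C,D) before the final merge
    z <- matrix(0, 2, 8, dimnames = list(c("g1", "g2"),
                                         paste0("c", 1:8)))
    z[1, ] <- rep(c(0, 0.1, 10, 10.1), each = 2)
    sce <- makeSce(matrix(1, 2, 8, dimnames = dimnames(z)))
    SummarizedExperiment::assays(sce)$lognorm <-
        as(Matrix::Matrix(z, sparse = TRUE), "CsparseMatrix")
    cl <- setNames(rep(c("A", "B", "C", "D"), each = 2), colnames(z))
    tree <- clusterCentroidTree(sce, cl)
    ab <- ape::getMRCA(tree, c("A", "B"))
    cd <- ape::getMRCA(tree, c("C", "D"))
    expect_equal(length(ape::extract.clade(tree, ab)$tip.label), 2)
    expect_equal(length(ape::extract.clade(tree, cd)$tip.label), 2)
    # two-cluster tree: single join at half the centroid distance
    cl2 <- setNames(rep(c("A", "B"), each = 4), colnames(z))
    t2 <- clusterCentroidTree(sce, cl2)
    d <- dist(rbind(A = rowMeans(z[, cl2 == "A"]),
                    B = rowMeans(z[, cl2 == "B"])))[1]
    expect_equal(sort(t2$edge.length), rep(d / 2, 2))
})

test_that("composition table counts tissues by cluster", {
    tissue <- setNames(rep(c("ecto", "endo"), each = 4),
                       paste0("b", 1:8))
    clust <- setNames(c("C1", "C1", "C2", "C2", "C1", "C2", "C2", "C2"),
                      paste0("b", 1:8))
    comp <- compositionTable(tissue, clust)
    expect_equal(unname(comp$table["ecto", ]), c(2, 2))
    expect_equal(unname(comp$table["endo", ]), c(1, 3))
    expect_true(all(abs(rowSums(comp$proportions) - 1) < 1e-9))
    one <- compositionTable(tissue[1:2], clust[1:2])
    expect_equal(sum(one$table), 2)
    expect_error(compositionTable(tissue, setNames("C1", "zz")),
                 "shared")
})
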