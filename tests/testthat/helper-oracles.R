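# Independent brute-force oracles used to cross-check the implementation.

# O(m^2) literal step-up evaluation of the Benjamini-Hochberg adjustment
bhStepUpOracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
        vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
        q[ord[i]] <- min(c(vals, 1))
    }
    q
}

# rank-then-Pearson with average ranks
spearmanOracle <- function(x, y) {
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ordinary pooled-variance two-sample t per row
pooledTOracle <- function(m, a, b) {
    t(apply(m, 1L, function(r) {
        tt <- t.test(r[a], r[b], var.equal = TRUE)
        c(t = unname(tt$statistic), p = tt$p.value)
    }))
}

# full enumeration of the Mann-Whitney U null: all ways to assign the
# pooled values to group sizes (n1, n2); two-sided p by doubling the
# smaller tail, capped at 1
mannWhitneyEnumOracle <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    uAll <- apply(combos, 2L, function(idx)
        sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
    p <- 2 * min(mean(uAll <= uObs), mean(uAll >= uObs))
    list(U = uObs, p = min(p, 1))
}

# average-linkage agglomeration by hand; returns the merge heights
averageLinkageHeightsOracle <- function(d) {
    d <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            dd <- mean(d[clusters[[i]], clusters[[j]]])
            if (dd < bestD) { bestD <- dd; best <- c(i, j) }
        }
        heights <- c(heights, bestD)
        clusters[[best[1]]] <- c(clusters[[best[1]]],
                                 clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# per-barcode QC recount on a dense copy of the counts
qcRecountOracle <- function(sce, t = qcThresholds()) {
    m <- as.matrix(SingleCellExperiment::counts(sce))
    mito <- SummarizedExperiment::rowData(sce)$mito
    kept <- character(0)
    for (j in seq_len(ncol(m))) {
        v <- m[, j]
        genes <- sum(v > 0)
        umis <- sum(v)
        mf <- if (umis > 0) sum(v[mito]) / umis else 0
        if (genes >= t$minGenes && genes <= t$maxGenes &&
            umis <= t$maxUmis && mf <= t$maxMitoFraction)
            kept <- c(kept, colnames(m)[j])
    }
    kept
}

# dense per-gene evaluation of the HVG criteria
hvgOracle <- function(sce, c = hvgCriteria()) {
    m <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
    sel <- character(0)
    for (i in seq_len(nrow(m))) {
        v <- m[i, ]
        nz <- v[v != 0]
        if (length(nz) == 0L) next
        if (mean(nz) > c$nonzeroMeanLow && mean(nz) < c$nonzeroMeanHigh &&
            sd(v) > c$sdMin)
            sel <- c(sel, rownames(m)[i])
    }
    sel
}

# small helper: gene-level DE table for threshold tests
makeGeneDe <- function(genes, log2fc, fdr) {
    data.frame(log2fc = log2fc, t = 0, p = fdr, fdr = fdr, df = 10,
               row.names = genes)
}
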