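#' Planted ground truth of a simulated dataset
#'
#' @param x a SummarizedExperiment / SingleCellExperiment produced by one of
#'   the \code{simulate*} generators.
#' @return the truth list stored in \code{metadata(x)$truth}.
#' @export
plantedTruth <- function(x) S4Vectors::metadata(x)$truth

#' Largest-remainder apportionment
#'
#' Deterministically rounds \code{n * proportions} to integers summing to
#' \code{n}: floors first, then distributes the remaining units by largest
#' fractional remainder (ties resolved in input order).
#'
#' @param n total count.
#' @param proportions non-negative weights summing to 1.
#' @return integer vector summing to \code{n}.
#' @export
largestRemainder <- function(n, proportions) {
    if (abs(sum(proportions) - 1) > 1e-9)
        stop("proportions must sum to 1")
    raw <- n * proportions
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' Simulate two-lineage organoid microarrays with replicate probes
#'
#' Emulates a single-colour microarray experiment contrasting squamous
#' (ectocervical) and columnar (endocervical) organoids: each gene is
#' measured by several probes sharing the gene's mean plus a fixed
#' probe-specific offset; a subset of genes carries a planted group
#' difference of \code{deLog2fc} log2 units (squamous minus columnar, with
#' random sign); intensities are log-normal (additive Gaussian noise on the
#' log2 scale).
#'
#' @param nGenes,nProbesPerGene,nSamplesPerGroup design dimensions.
#' @param nDeGenes number of differentially expressed genes (<= nGenes).
#' @param deLog2fc planted absolute effect in log2 units.
#' @param noiseSd residual standard deviation on the log2 scale (> 0).
#' @param seed RNG seed.
#' @return SummarizedExperiment with a raw-scale \code{exprs} assay
#'   (probes x samples), \code{rowData(probe, gene)},
#'   \code{colData(group)} with groups "squamous"/"columnar", and
#'   \code{metadata(x)$truth} listing the planted signed effects
#'   (\code{deGenes}, gene -> log2fc squamous minus columnar).
#' @export
simulateOrganoidArrays <- function(nGenes = 1000L, nProbesPerGene = 2L,
        nSamplesPerGroup = 5L, nDeGenes = 100L, deLog2fc = 2.0,
        noiseSd = 0.3, seed = 1L) {
    if (nGenes < 1L || nProbesPerGene < 1L || nSamplesPerGroup < 2L)
        stop("invalid design dimensions")
    if (nDeGenes > nGenes)
        stop("nDeGenes cannot exceed nGenes")
    if (noiseSd <= 0 || deLog2fc <= 0)
        stop("deLog2fc and noiseSd must be positive")
    withr::with_seed(as.integer(seed), {
        genes <- sprintf("G%05d", seq_len(nGenes))
        probeGene <- rep(genes, each = nProbesPerGene)
        probes <- paste0(probeGene, "_p",
                         rep(seq_len(nProbesPerGene), nGenes))
        baseline <- setNames(runif(nGenes, 6, 12), genes)
        probeOffset <- rnorm(length(probes), 0, 0.5)
        deIdx <- sort(sample.int(nGenes, nDeGenes))
        effect <- setNames(rep(0, nGenes), genes)
        effect[deIdx] <- sample(c(-1, 1), nDeGenes, replace = TRUE) *
            deLog2fc
        samples <- c(paste0("sq_", seq_len(nSamplesPerGroup)),
                     paste0("co_", seq_len(nSamplesPerGroup)))
        group <- rep(c("squamous", "columnar"), each = nSamplesPerGroup)
        shift <- ifelse(group == "squamous", +0.5, -0.5)
        mu <- baseline[probeGene] + probeOffset
        log2mat <- outer(mu, rep(1, length(samples))) +
            outer(effect[probeGene], shift) +
            matrix(rnorm(length(probes) * length(samples), 0, noiseSd),
                   nrow = length(probes))
        dimnames(log2mat) <- list(probes, samples)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(exprs = 2^log2mat),
            rowData = DataFrame(probe = probes, gene = probeGene,
                                row.names = probes),
            colData = DataFrame(group = group, row.names = samples))
        S4Vectors::metadata(se) <- list(
            truth = list(deGenes = effect[deIdx], seed = as.integer(seed)),
            scale = "raw")
        se
    })
}

#' Simulate a synthetic lineage signature
#'
#' Draws a signed log2 fold-change vector over a gene set: signs are
#' balanced at random and magnitudes uniform in \code{fcRange}. Used both
#' by the tumour-cohort generator and to build fold-change vectors for
#' null-calibration experiments.
#'
#' @param genes character vector of gene ids.
#' @param fcRange range of absolute log2 fold changes (default 1 to 3).
#' @param seed RNG seed.
#' @return A \linkS4class{LineageSignature} with \code{NA} thresholds.
#' @export
simulateSignature <- function(genes, fcRange = c(1, 3), seed = 1L) {
    withr::with_seed(as.integer(seed), {
        fc <- sample(c(-1, 1), length(genes), replace = TRUE) *
            runif(length(genes), fcRange[1], fcRange[2])
        LineageSignature(setNames(fc, genes))
    })
}

#' Simulate a tumour cohort with planted lineage classes
#'
#' Emulates a gene-level tumour expression cohort containing squamous-like,
#' columnar-like and mixed samples. Signature genes shift by half the
#' signature fold change up (squamous-like) or down (columnar-like); mixed
#' samples sit at a \code{mixFraction} blend of the two class means before
#' noise. Bimodal marker genes (squamous- or columnar-high) are planted on
#' top, values are log-normal around the class means, and per-sample
#' library-size factors vary within \code{librarySizeRange} so that
#' size-factor normalization is non-trivial. Histology labels mimic a
#' clinical annotation: squamous-like and mixed samples are "squamous cell
#' carcinoma", columnar-like samples are "adenocarcinoma" or
#' "adenosquamous carcinoma".
#'
#' @param nSamples cohort size.
#' @param classProportions proportions of (squamous-like, columnar-like,
#'   mixed) samples, summing to 1; per-class counts use
#'   \code{\link{largestRemainder}}.
#' @param nGenes total genes; \code{signatureSize} of them carry the
#'   planted signature.
#' @param signatureSize number of signature genes (<= nGenes); ignored when
#'   \code{signature} is supplied.
#' @param signature optional \linkS4class{LineageSignature} to plant
#'   (e.g. the truth of a simulated organoid experiment, so that cohort and
#'   organoid share a gene universe); by default a synthetic signature over
#'   \code{signatureSize} new genes is drawn.
#' @param markerGenes named character vector, marker gene ->
#'   \code{"squamous"} or \code{"columnar"} (the class in which it is
#'   high).
#' @param librarySizeRange range of per-sample library-size factors.
#' @param mixFraction blend of mixed samples between the columnar (0) and
#'   squamous (1) class means (default 0.5, exactly halfway).
#' @param effectLog2 multiplier on the signature fold changes (default 1).
#' @param noiseSd log2-scale noise standard deviation (default 0.5).
#' @param seed RNG seed.
#' @return SummarizedExperiment with a raw-scale \code{exprs} assay
#'   (genes x samples) and colData(class, histology, librarySize);
#'   \code{metadata(x)$truth} carries \code{sampleClasses},
#'   the planted \code{signature} (a \linkS4class{LineageSignature}),
#'   \code{markerDirections} and the seed.
#' @export
simulateTumorCohort <- function(nSamples = 178L,
        classProportions = c(0.4, 0.4, 0.2), nGenes = 2000L,
        signatureSize = 200L,
        markerGenes = c(KRT5 = "squamous", TP63 = "squamous",
                        KRT7 = "columnar"),
        librarySizeRange = c(0.5, 2), mixFraction = 0.5,
        effectLog2 = 1.0, noiseSd = 0.5, seed = 1L, signature = NULL) {
    if (abs(sum(classProportions) - 1) > 1e-9)
        stop("classProportions must sum to 1")
    if (any(classProportions < 0))
        stop("classProportions must be non-negative")
    if (!is.null(signature)) signatureSize <- length(signature)
    if (signatureSize > nGenes)
        stop("signatureSize cannot exceed nGenes")
    if (mixFraction < 0 || mixFraction > 1)
        stop("mixFraction must lie in [0, 1]")
    counts <- largestRemainder(nSamples, classProportions)
    withr::with_seed(as.integer(seed), {
        sig <- if (is.null(signature)) {
            simulateSignature(sprintf("SIG%04d", seq_len(signatureSize)),
                              seed = sample.int(1e6, 1))
        } else signature
        sigGenes <- sigGenes(sig)
        nBg <- nGenes - signatureSize - length(markerGenes)
        if (nBg < 0) stop("nGenes too small for signature plus markers")
        bgGenes <- sprintf("BG%04d", seq_len(nBg))
        genes <- c(sigGenes, names(markerGenes), bgGenes)
        if (anyDuplicated(genes))
            stop("signature genes collide with marker/background ids")
        fc <- sigFoldChanges(sig)

        classes <- rep(c("squamous-like", "columnar-like", "mixed"),
                       counts)
        classes <- sample(classes)
        samples <- sprintf("S%03d", seq_len(nSamples))
        dir <- c("squamous-like" = 1, "columnar-like" = -1,
                 "mixed" = 2 * mixFraction - 1)[classes]

        baseline <- setNames(runif(nGenes, 5, 10), genes)
        log2mu <- matrix(baseline, nrow = nGenes, ncol = nSamples,
                         dimnames = list(genes, samples))
        log2mu[sigGenes, ] <- log2mu[sigGenes, ] +
            outer(0.5 * effectLog2 * fc, dir)
        # bimodal markers: high (log2 ~ 10) in their lineage, low (~ 4)
        # otherwise; mixed samples follow the squamous pattern, mimicking
        # contaminated squamous tumours
        markerHighIn <- lapply(markerGenes, function(d)
            if (d == "squamous") c("squamous-like", "mixed")
            else "columnar-like")
        for (g in names(markerGenes)) {
            high <- classes %in% markerHighIn[[g]]
            log2mu[g, ] <- ifelse(high, 10, 4)
        }
        libSize <- runif(nSamples, librarySizeRange[1],
                         librarySizeRange[2])
        exprs <- sweep(2^(log2mu + matrix(rnorm(nGenes * nSamples, 0,
                                                noiseSd), nGenes)),
                       2L, libSize, "*")
        histology <- ifelse(classes == "columnar-like",
            sample(c("adenocarcinoma", "adenosquamous carcinoma"),
                   nSamples, replace = TRUE),
            "squamous cell carcinoma")
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(exprs = exprs),
            colData = DataFrame(class = classes, histology = histology,
                                librarySize = libSize,
                                row.names = samples))
        S4Vectors::metadata(se) <- list(
            truth = list(sampleClasses = setNames(classes, samples),
                         signature = sig,
                         markerDirections = markerGenes,
                         seed = as.integer(seed)),
            scale = "raw")
        se
    })
}

#' Simulate sparse single-cell counts with planted QC violations
#'
#' Generates a 10x-style sparse count matrix containing \code{nCellsGood}
#' well-behaved cells with planted cluster structure plus
#' \code{nBarcodesJunk} low-quality barcodes, each constructed to violate
#' exactly one stated QC rule (too few genes, too many genes, too many
#' UMIs, or excessive mitochondrial fraction) while satisfying the others.
#' Good cells draw 2,000-8,000 UMIs from a gamma-shaped gene abundance
#' profile with about 5\% mitochondrial mass, cluster-specific gene modules
#' up-weighted 4-fold, and a tissue label correlated with the cluster. The
#' "too many genes" junk type needs \code{nGenes > 4200}; with fewer genes
#' it is skipped and the remaining rules are cycled.
#'
#' @param nCellsGood,nBarcodesJunk,nGenes,nMitoGenes,nClusters design
#'   dimensions (\code{nMitoGenes <= nGenes}).
#' @param tissueLabels labels sampled for good cells.
#' @param seed RNG seed.
#' @return SingleCellExperiment with a sparse \code{counts} assay,
#'   rowData(id, symbol, type, mito), colData(tissue, cluster, junk,
#'   junkReason); \code{metadata(x)$truth} lists \code{cellClusters},
#'   \code{junkBarcodes}, \code{junkReasons} and \code{tissues}.
#' @export
simulateScCounts <- function(nCellsGood = 500L, nBarcodesJunk = 100L,
        nGenes = 5000L, nMitoGenes = 13L, nClusters = 3L,
        tissueLabels = c("ectocervix", "endocervix", "transition_zone"),
        seed = 1L) {
    if (nMitoGenes > nGenes)
        stop("nMitoGenes cannot exceed nGenes")
    if (nCellsGood < 1L || nGenes < 300L || nClusters < 1L)
        stop("invalid design dimensions")
    withr::with_seed(as.integer(seed), {
        ids <- sprintf("ENSG%08d", seq_len(nGenes))
        mito <- seq_len(nGenes) %in% seq_len(nMitoGenes)
        symbols <- ifelse(mito, paste0("mt-G", seq_len(nGenes)),
                          paste0("Gene", seq_len(nGenes)))
        # gamma-shaped abundances; mitochondrial genes get 5% of the mass
        w <- rgamma(nGenes, shape = 0.5)
        w[mito] <- w[mito] / sum(w[mito]) * 0.05 * sum(w[!mito]) / 0.95
        prob <- w / sum(w)

        modules <- lapply(seq_len(nClusters), function(k)
            sample(which(!mito), min(100L, sum(!mito))))
        clusterProb <- lapply(seq_len(nClusters), function(k) {
            p <- prob
            p[modules[[k]]] <- p[modules[[k]]] * 4
            p / sum(p)
        })

        junkTypes <- c("min_genes", "max_umis",
                       if (nMitoGenes > 0L) "max_mito_fraction",
                       if (sum(!mito) >= 4150L) "max_genes")
        nCells <- nCellsGood + nBarcodesJunk
        dense <- matrix(0L, nrow = nGenes, ncol = nCells)
        cluster <- integer(nCells)
        tissue <- character(nCells)
        junkReason <- character(nCells)
        nonMito <- which(!mito)
        for (j in seq_len(nCells)) {
            if (j <= nCellsGood) {
                k <- sample.int(nClusters, 1L)
                cluster[j] <- k
                # tissue depends on cluster: 70% its "home" tissue
                home <- ((k - 1L) %% length(tissueLabels)) + 1L
                tp <- rep(0.3 / max(length(tissueLabels) - 1L, 1L),
                          length(tissueLabels))
                tp[home] <- if (length(tissueLabels) > 1L) 0.7 else 1
                tissue[j] <- sample(tissueLabels, 1L, prob = tp)
                total <- round(runif(1L, 2000, 8000))
                dense[, j] <- rmultinom(1L, total, clusterProb[[k]])
            } else {
                type <- junkTypes[((j - nCellsGood - 1L) %%
                                   length(junkTypes)) + 1L]
                junkReason[j] <- type
                if (type == "min_genes") {
                    total <- round(runif(1L, 50, 150))
                    pick <- sample(nonMito, min(100L, length(nonMito)))
                    p <- prob[pick] / sum(prob[pick])
                    dense[pick, j] <- rmultinom(1L, total, p)
                } else if (type == "max_genes") {
                    pick <- sample(nonMito, 4150L)
                    dense[pick, j] <- 1L
                    extra <- sample(pick, 300L)
                    dense[extra, j] <- dense[extra, j] + 1L
                } else if (type == "max_umis") {
                    total <- round(runif(1L, 16000, 20000))
                    pick <- sample(nonMito, min(3000L, length(nonMito)))
                    p <- prob[pick] / sum(prob[pick])
                    dense[pick, j] <- rmultinom(1L, total, p)
                } else { # max_mito_fraction
                    total <- round(runif(1L, 2000, 8000))
                    mitoShare <- runif(1L, 0.15, 0.30)
                    nm <- round(total * mitoShare)
                    if (nMitoGenes > 0L)
                        dense[seq_len(nMitoGenes), j] <-
                            rmultinom(1L, nm, rep(1, nMitoGenes))
                    p <- prob[nonMito] / sum(prob[nonMito])
                    dense[nonMito, j] <- dense[nonMito, j] +
                        rmultinom(1L, total - nm, p)
                }
            }
        }
        ord <- sample.int(nCells)
        dense <- dense[, ord, drop = FALSE]
        cluster <- cluster[ord]; tissue <- tissue[ord]
        junkReason <- junkReason[ord]
        barcodes <- sprintf("BC%05d", seq_len(nCells))
        isJunk <- junkReason != ""
        countsM <- as(Matrix::Matrix(dense, sparse = TRUE),
                      "CsparseMatrix")
        dimnames(countsM) <- list(ids, barcodes)
        rd <- DataFrame(id = ids, symbol = symbols,
                        type = "Gene Expression", mito = mito,
                        row.names = ids)
        cd <- DataFrame(
            tissue = ifelse(isJunk, NA_character_, tissue),
            cluster = ifelse(isJunk, NA_character_,
                             paste0("C", cluster)),
            junk = isJunk,
            junkReason = ifelse(isJunk, junkReason, NA_character_),
            row.names = barcodes)
        sce <- SingleCellExperiment(assays = list(counts = countsM),
                                    rowData = rd, colData = cd)
        good <- barcodes[!isJunk]
        S4Vectors::metadata(sce) <- list(truth = list(
            cellClusters = setNames(paste0("C", cluster[!isJunk]), good),
            tissues = setNames(tissue[!isJunk], good),
            junkBarcodes = barcodes[isJunk],
            junkReasons = setNames(junkReason[isJunk],
                                   barcodes[isJunk]),
            seed = as.integer(seed)))
        # generator contract: good cells pass all QC rules, junk violates
        met <- .barcodeMetrics(sce)
        t <- qcThresholds()
        pass <- met$genes_detected >= t$minGenes &
            met$genes_detected <= t$maxGenes &
            met$total_umis <= t$maxUmis &
            met$mito_fraction <= t$maxMitoFraction
        stopifnot(all(pass[!isJunk]), all(!pass[isJunk]))
        sce
    })
}

#' Simulate stem-versus-differentiated comparison tables
#'
#' Builds \code{nComparisons} differential-expression tables over a common
#' gene universe with a planted consensus: every consensus gene is
#' significant (|logFC| > 1, adjusted P < 0.05) with consistent sign in
#' exactly \code{support} comparisons, while decoy genes reach significance
#' in fewer than \code{support} comparisons with random signs.
#'
#' @param nComparisons number of comparisons (default 18).
#' @param consensusUp,consensusDown gene ids planted as consistently up- /
#'   down-regulated.
#' @param support number of supporting comparisons per consensus gene
#'   (<= nComparisons).
#' @param nGenes size of the gene universe (consensus genes included).
#' @param seed RNG seed.
#' @return list with \code{tables} (list of data.frames with columns gene,
#'   logFC, adjP) and \code{truth} (consensusUp, consensusDown, support,
#'   seed).
#' @export
simulateStemComparisons <- function(nComparisons = 18L,
        consensusUp = sprintf("STEMUP%02d", 1:15),
        consensusDown = sprintf("STEMDN%02d", 1:15),
        support = 5L, nGenes = 500L, seed = 1L) {
    if (support > nComparisons)
        stop("support cannot exceed nComparisons")
    if (support < 1L) stop("support must be >= 1")
    nCons <- length(consensusUp) + length(consensusDown)
    if (nGenes < nCons)
        stop("nGenes smaller than the consensus set")
    withr::with_seed(as.integer(seed), {
        decoys <- sprintf("DECOY%04d", seq_len(nGenes - nCons))
        genes <- c(consensusUp, consensusDown, decoys)
        sign <- setNames(rep(0, nGenes), genes)
        sign[consensusUp] <- 1
        sign[consensusDown] <- -1
        inComp <- matrix(FALSE, nrow = nGenes, ncol = nComparisons,
                         dimnames = list(genes, NULL))
        for (g in c(consensusUp, consensusDown))
            inComp[g, sample.int(nComparisons, support)] <- TRUE
        for (g in decoys) {
            k <- sample.int(support, 1L) - 1L   # 0 .. support-1 hits
            if (k > 0L) inComp[g, sample.int(nComparisons, k)] <- TRUE
        }
        tables <- lapply(seq_len(nComparisons), function(cc) {
            sig <- inComp[, cc]
            sgn <- ifelse(sign[genes] != 0, sign[genes],
                          sample(c(-1, 1), nGenes, replace = TRUE))
            logFC <- ifelse(sig, sgn * runif(nGenes, 1.2, 3),
                            runif(nGenes, -0.8, 0.8))
            adjP <- ifelse(sig, runif(nGenes, 1e-6, 0.04),
                           runif(nGenes, 0.06, 1))
            data.frame(gene = genes, logFC = logFC, adjP = adjP,
                       stringsAsFactors = FALSE)
        })
        list(tables = tables,
             truth = list(consensusUp = consensusUp,
                          consensusDown = consensusDown,
                          support = as.integer(support),
                          seed = as.integer(seed)))
    })
}
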