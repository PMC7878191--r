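#' Quantile-normalize a positive expression matrix
#'
#' Forces every column (array) to share the same distribution of values: the
#' value at rank r in each column is replaced by the mean over columns of the
#' rank-r values. Standard pre-processing for single-colour microarrays
#' before differential expression.
#'
#' @param m numeric matrix, probes x samples, strictly positive raw
#'   intensities with row and column names.
#' @return matrix of the same dimensions and dimnames, quantile-normalized.
#'   The operation is idempotent.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), c("a", "b")))
#' quantileNormalize(m)
#' @export
quantileNormalize <- function(m) {
    m <- .checkMatrix(m)
    if (ncol(m) < 2L)
        stop("quantile normalization needs at least 2 columns")
    if (any(m <= 0))
        stop("raw intensities must be strictly positive")
    out <- limma::normalizeQuantiles(m)
    dimnames(out) <- dimnames(m)
    out
}

.checkMatrix <- function(m) {
    if (!is.matrix(m) || !is.numeric(m))
        stop("input must be a numeric matrix")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("matrix must carry row and column names")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        stop("row and column names must be unique")
    if (any(!is.finite(m)))
        stop("matrix contains non-finite values")
    m
}

#' Invert the trigamma function
#'
#' Newton iteration solving trigamma(y) = x, used to estimate the prior
#' degrees of freedom of the empirical-Bayes variance model by moment
#' matching on log sample variances.
#'
#' @param x positive numeric vector.
#' @return numeric vector y with trigamma(y) = x.
#' @keywords internal
trigammaInverse <- function(x) {
    y <- 0.5 + 1 / x
    for (i in 1:75) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
        y <- y + dif
        if (max(abs(dif) / y, na.rm = TRUE) < 1e-10) break
    }
    y
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per-row differential expression between two sample groups on the log2
#' scale. Row variances are shrunk towards a common prior by the standard
#' empirical-Bayes construction: the moderated variance is
#' \deqn{\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' and the moderated t is referred to a t distribution with d0 + dg degrees
#' of freedom. The hyper-parameters (d0, s0^2) are estimated by moment
#' matching on log s^2_g via the digamma/trigamma relations; when the
#' observed spread of log variances does not exceed its sampling
#' expectation, d0 is infinite and all variances shrink to s0^2.
#'
#' @param m numeric matrix on the log2 scale (probes or genes x samples).
#' @param groupA,groupB disjoint character or integer vectors selecting the
#'   columns of the two groups, each of size >= 2. The reported fold change
#'   is mean(A) - mean(B).
#' @param priorDf optional override of the estimated prior degrees of
#'   freedom d0. \code{priorDf = 0} gives the ordinary pooled-variance
#'   two-sample t-test; \code{priorDf = Inf} forces every variance to the
#'   prior value.
#' @return data.frame keyed by rownames with columns \code{log2fc},
#'   \code{t}, \code{p}, \code{fdr} (Benjamini-Hochberg) and \code{df}
#'   (total degrees of freedom d0 + dg); attributes \code{priorDf} and
#'   \code{priorVar} carry the fitted hyper-parameters.
#' @export
moderatedTTest <- function(m, groupA, groupB, priorDf = NULL) {
    m <- .checkMatrix(m)
    a <- .resolveColumns(m, groupA)
    b <- .resolveColumns(m, groupB)
    if (length(intersect(a, b)) > 0L)
        stop("groups must be disjoint")
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 samples")
    nA <- length(a); nB <- length(b)
    mA <- rowMeans(m[, a, drop = FALSE])
    mB <- rowMeans(m[, b, drop = FALSE])
    ssA <- rowSums((m[, a, drop = FALSE] - mA)^2)
    ssB <- rowSums((m[, b, drop = FALSE] - mB)^2)
    df <- nA + nB - 2L
    s2 <- (ssA + ssB) / df
    log2fc <- mA - mB

    if (is.null(priorDf)) {
        ok <- s2 > 0
        if (!any(ok))
            stop("all rows have zero variance; prior unestimable")
        fit <- .fitVariancePrior(s2[ok], df)
        d0 <- fit$df0
        s20 <- fit$s20
    } else {
        d0 <- priorDf
        # prior variance only matters when it receives weight
        s20 <- if (d0 > 0) {
            ok <- s2 > 0
            if (!any(ok)) stop("all rows have zero variance; prior unestimable")
            exp(mean(log(s2[ok])))
        } else NA_real_
    }

    if (is.infinite(d0)) {
        s2tilde <- rep(s20, length(s2))
        dfTotal <- rep(Inf, length(s2))
    } else if (d0 == 0) {
        s2tilde <- s2
        dfTotal <- rep(as.numeric(df), length(s2))
    } else {
        s2tilde <- (d0 * s20 + df * s2) / (d0 + df)
        dfTotal <- rep(d0 + df, length(s2))
    }

    se <- sqrt(s2tilde * (1 / nA + 1 / nB))
    t <- ifelse(log2fc == 0, 0, log2fc / se)
    p <- ifelse(is.infinite(dfTotal), 2 * pnorm(-abs(t)),
                2 * pt(-abs(t), df = dfTotal))
    res <- data.frame(log2fc = log2fc, t = t, p = p,
                      fdr = bhAdjust(p), df = dfTotal,
                      row.names = rownames(m))
    attr(res, "priorDf") <- d0
    attr(res, "priorVar") <- s20
    res
}

.resolveColumns <- function(m, idx) {
    if (is.character(idx)) {
        miss <- setdiff(idx, colnames(m))
        if (length(miss) > 0L)
            stop("unknown columns: ", paste(miss, collapse = ", "))
        match(idx, colnames(m))
    } else as.integer(idx)
}

# Moment matching of a scaled-F model for sample variances: with
# s2 ~ s0^2 F(df, df0), e = log s2 - digamma(df/2) + log(df/2) has mean
# log s0^2 - digamma(df0/2) + log(df0/2) and variance
# trigamma(df/2) + trigamma(df0/2).
.fitVariancePrior <- function(s2, df) {
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    ebar <- mean(e)
    n <- length(e)
    evar <- mean((e - ebar)^2) * n / (n - 1) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
        df0 <- 2 * trigammaInverse(evar)
        s20 <- exp(ebar + digamma(df0 / 2) - log(df0 / 2))
    } else {
        df0 <- Inf
        s20 <- exp(ebar)
    }
    list(df0 = df0, s20 = s20)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of adjusted p-values (q-values) in input order:
#'   q_(i) = min over j >= i of m p_(j) / j, clipped at 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must be numeric in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Collapse probe-level results to gene level
#'
#' @param de data.frame from \code{\link{moderatedTTest}} (rownames are
#'   probe ids; columns log2fc, t, p, fdr, df).
#' @param annotation data.frame with columns \code{probe} and \code{gene}
#'   mapping every probe in \code{de} to one gene.
#' @param rule \code{"lowest_p"} keeps, per gene, the probe with the
#'   smallest p-value (ties broken by larger |log2fc|, then lexicographic
#'   probe id); \code{"largest_abs_fc"} keeps the probe whose signed fold
#'   change has the largest absolute value.
#' @return data.frame with one row per gene (rownames are gene ids) plus a
#'   \code{probe} column naming the retained probe.
#' @export
collapseProbes <- function(de, annotation, rule = c("lowest_p",
                                                    "largest_abs_fc")) {
    rule <- match.arg(rule)
    if (is.null(rownames(de)))
        stop("'de' must have probe ids as rownames")
    if (!all(c("probe", "gene") %in% colnames(annotation)))
        stop("'annotation' needs columns 'probe' and 'gene'")
    gene <- annotation$gene[match(rownames(de), annotation$probe)]
    if (anyNA(gene))
        stop("unannotated probes: ",
             paste(rownames(de)[is.na(gene)], collapse = ", "))
    ord <- switch(rule,
        lowest_p = order(gene, de$p, -abs(de$log2fc), rownames(de)),
        largest_abs_fc = order(gene, -abs(de$log2fc), rownames(de)))
    de2 <- de[ord, , drop = FALSE]
    gene2 <- gene[ord]
    keep <- !duplicated(gene2)
    out <- de2[keep, , drop = FALSE]
    out$probe <- rownames(out)
    rownames(out) <- gene2[keep]
    out[order(rownames(out)), , drop = FALSE]
}

#' Build the squamous-versus-columnar lineage signature
#'
#' Selects genes with \code{fdr < fdrMax} and \code{|log2fc| > absFcMin}
#' (both strict) from a gene-level differential-expression table and stores
#' their signed fold changes (squamous-positive convention when group A of
#' the test was the squamous/ectocervical group).
#'
#' @param geneDe gene-level data.frame (after \code{\link{collapseProbes}}).
#' @param fdrMax,absFcMin strict selection thresholds.
#' @return A \linkS4class{LineageSignature}. An empty selection yields an
#'   empty signature with a warning, not an error.
#' @export
buildLineageSignature <- function(geneDe, fdrMax = 0.05, absFcMin = 1.0) {
    sel <- geneDe$fdr < fdrMax & abs(geneDe$log2fc) > absFcMin
    if (!any(sel))
        warning("no genes pass the signature thresholds; empty signature")
    fc <- setNames(geneDe$log2fc[sel], rownames(geneDe)[sel])
    LineageSignature(fc, fdrMax = fdrMax, absFcMin = absFcMin)
}

#' Build the culture-state signature from two comparisons
#'
#' Union of genes passing \code{fdr < fdrMax} and \code{log2fc < -fcMin or
#' > fcMin} in either of two gene-level comparisons (e.g. 2D versus
#' differentiated organoids and early versus differentiated organoids). Per
#' gene, the stored fold change is the one with the largest absolute value
#' across both comparisons.
#'
#' @param de1,de2 gene-level data.frames with columns log2fc and fdr.
#' @param fdrMax strict FDR threshold.
#' @param fcMin strict absolute fold-change threshold (default 1.5).
#' @return A \linkS4class{LineageSignature} carrying the selected genes.
#' @export
buildCultureSignature <- function(de1, de2, fdrMax = 0.05, fcMin = 1.5) {
    passes <- function(de) rownames(de)[de$fdr < fdrMax &
                                        abs(de$log2fc) > fcMin]
    genes <- union(passes(de1), passes(de2))
    fc <- vapply(genes, function(g) {
        cand <- c(if (g %in% rownames(de1)) de1[g, "log2fc"],
                  if (g %in% rownames(de2)) de2[g, "log2fc"])
        cand[which.max(abs(cand))]
    }, numeric(1))
    if (length(genes) == 0L)
        warning("no genes pass the culture-signature thresholds")
    LineageSignature(fc, fdrMax = fdrMax, absFcMin = fcMin)
}

#' Voting parameters for the stem-cell meta-signature
#'
#' @param absLogfcMin strict absolute log fold-change threshold per
#'   comparison (default 1).
#' @param adjPMax strict adjusted-P threshold per comparison (default 0.05).
#' @param minSupport minimum number of supporting comparisons (default 5).
#' @return list with class \code{"votingParams"}.
#' @export
votingParams <- function(absLogfcMin = 1.0, adjPMax = 0.05,
                         minSupport = 5L) {
    if (absLogfcMin <= 0 || adjPMax <= 0 || minSupport < 1L)
        stop("voting parameters must be positive and minSupport >= 1")
    structure(list(absLogfcMin = absLogfcMin, adjPMax = adjPMax,
                   minSupport = as.integer(minSupport)),
              class = "votingParams")
}

#' Stem-cell meta-signature by voting across comparisons
#'
#' A gene enters the up (down) set when it is significantly up- (down-)
#' regulated -- \code{logFC > absLogfcMin} (\code{< -absLogfcMin}) with
#' \code{adjP < adjPMax} -- in at least \code{minSupport} of the supplied
#' stem-versus-differentiated comparisons. A gene qualifying in both
#' directions is assigned to the direction with more supporting comparisons
#' and dropped on a tie.
#'
#' @param tables list of data.frames, each with columns \code{gene},
#'   \code{logFC} and \code{adjP}.
#' @param params a \code{\link{votingParams}} object.
#' @return A \linkS4class{StemSignature}.
#' @export
stemCellVoting <- function(tables, params = votingParams()) {
    if (length(tables) < 1L)
        stop("at least one comparison table is required")
    if (params$minSupport > length(tables))
        stop("minSupport exceeds the number of comparisons")
    count <- function(dir) {
        hits <- lapply(tables, function(tb) {
            sig <- tb$adjP < params$adjPMax &
                (if (dir > 0) tb$logFC > params$absLogfcMin
                 else tb$logFC < -params$absLogfcMin)
            tb$gene[sig]
        })
        table(unlist(hits))
    }
    upVotes <- count(+1)
    downVotes <- count(-1)
    up <- as.character(names(upVotes)[upVotes >= params$minSupport])
    down <- as.character(names(downVotes)[downVotes >= params$minSupport])
    both <- intersect(up, down)
    for (g in both) {
        u <- upVotes[g]; d <- downVotes[g]
        if (u > d) down <- setdiff(down, g)
        else if (d > u) up <- setdiff(up, g)
        else { up <- setdiff(up, g); down <- setdiff(down, g) }
    }
    new("StemSignature", upGenes = sort(up), downGenes = sort(down),
        supportThreshold = params$minSupport,
        nComparisons = length(tables))
}
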