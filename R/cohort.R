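#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed by the median-of-ratios
#' construction: the factor of sample j is the median, over genes with
#' strictly positive values in every sample, of the ratio of the gene's
#' value in j to the gene's geometric mean across samples.
#'
#' @param m non-negative numeric matrix, genes x samples, with dimnames.
#' @return named positive numeric vector of size factors (one per sample).
#' @examples
#' m <- matrix(c(2, 2, 8, 4, 4, 16), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cohortSizeFactors(m)  # (1/sqrt(2), sqrt(2))
#' @export
cohortSizeFactors <- function(m) {
    m <- .checkMatrix(m)
    if (ncol(m) < 2L)
        stop("size factors need at least 2 samples")
    if (any(m < 0))
        stop("expression values must be non-negative")
    keep <- rowSums(m > 0) == ncol(m)
    if (!any(keep))
        stop("no gene has strictly positive values in all samples")
    logm <- log(m[keep, , drop = FALSE])
    loggeo <- rowMeans(logm)
    sf <- apply(logm, 2L, function(col) exp(median(col - loggeo)))
    if (any(sf <= 0) || any(!is.finite(sf)))
        stop("degenerate size factors")
    sf
}

#' Normalize, log2-transform and z-score a tumour cohort
#'
#' Each value is divided by its sample's size factor, log2-transformed with
#' a pseudocount, and each gene is centred and scaled to mean 0 and
#' (sample, n-1 denominator) standard deviation 1 across samples. Genes
#' with zero variance after transformation are dropped and reported.
#'
#' @param m non-negative numeric matrix, genes x samples.
#' @param sf named size factors from \code{\link{cohortSizeFactors}}; when
#'   \code{NULL} they are computed from \code{m}.
#' @param pseudocount added before the log2 (default 1, so zeros map to 0).
#' @return z-scored matrix (genes x samples); dropped zero-variance genes
#'   are reported via \code{message()} and listed in the \code{"dropped"}
#'   attribute.
#' @export
preprocessCohort <- function(m, sf = NULL, pseudocount = 1) {
    m <- .checkMatrix(m)
    if (is.null(sf)) sf <- cohortSizeFactors(m)
    if (length(sf) != ncol(m) || any(sf <= 0))
        stop("size factors must be positive, one per sample")
    if (!is.null(names(sf)) && !identical(names(sf), colnames(m)))
        sf <- sf[colnames(m)]
    lm <- log2(sweep(m, 2L, sf, "/") + pseudocount)
    mu <- rowMeans(lm)
    sdv <- apply(lm, 1L, sd)
    drop <- sdv == 0
    if (all(drop))
        stop("all genes have zero variance")
    if (any(drop))
        message(sum(drop), " zero-variance gene(s) dropped: ",
                paste(head(rownames(lm)[drop], 5L), collapse = ", "),
                if (sum(drop) > 5L) ", ..." else "")
    z <- (lm[!drop, , drop = FALSE] - mu[!drop]) / sdv[!drop]
    attr(z, "dropped") <- rownames(lm)[drop]
    z
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#'
#' @param x,y numeric vectors of equal length >= 3, each non-constant.
#' @return correlation in [-1, 1].
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y))
        stop("vectors must have equal length")
    if (length(x) < 3L)
        stop("need at least 3 observations")
    if (sd(x) == 0 || sd(y) == 0)
        stop("Spearman correlation undefined for constant vectors")
    cor(x, y, method = "spearman")
}

#' Score and classify tumour samples by the Co-Sq procedure
#'
#' For every sample, the Co-Sq score is the Spearman correlation between
#' the sample's z-scored expression over the signature genes present in the
#' matrix and the signature's signed fold changes over the same genes.
#' Samples with score > \code{upper} are squamous-like, < \code{lower}
#' columnar-like, all others undetermined (strict comparisons).
#'
#' @param z z-scored matrix from \code{\link{preprocessCohort}}
#'   (genes x samples).
#' @param sig a \linkS4class{LineageSignature}.
#' @param upper,lower classification thresholds (default +0.2 / -0.2).
#' @return A \linkS4class{CoSqResult}. Signature genes absent from the
#'   matrix are excluded and reported via \code{message()}.
#' @export
cosqClassify <- function(z, sig, upper = 0.2, lower = -0.2) {
    z <- .checkMatrix(z)
    if (!is(sig, "LineageSignature"))
        stop("'sig' must be a LineageSignature")
    if (upper <= lower)
        stop("'upper' must exceed 'lower'")
    fc <- sigFoldChanges(sig)
    common <- intersect(names(fc), rownames(z))
    missing <- setdiff(names(fc), common)
    if (length(missing) > 0L)
        message(length(missing),
                " signature gene(s) not measured; excluded: ",
                paste(head(missing, 5L), collapse = ", "),
                if (length(missing) > 5L) ", ..." else "")
    if (length(common) < 3L)
        stop("fewer than 3 signature genes overlap the expression matrix")
    score <- drop(cor(fc[common], z[common, , drop = FALSE],
                      method = "spearman"))
    names(score) <- colnames(z)
    label <- ifelse(score > upper, "squamous-like",
             ifelse(score < lower, "columnar-like", "undetermined"))
    new("CoSqResult", score = score, label = label, upper = upper,
        lower = lower, nOverlap = length(common))
}

#' Null distribution of Co-Sq scores from random gene sets
#'
#' Repeats the scoring procedure on random gene sets: each set is drawn
#' without replacement from all measured genes (signature genes included),
#' paired position-wise with the signature's fixed fold-change vector, and
#' every sample is scored. The resulting score matrix calibrates how large
#' a Co-Sq score can get by chance.
#'
#' @param z z-scored matrix (genes x samples).
#' @param sig a \linkS4class{LineageSignature}; its size and fold-change
#'   vector are reused for every random set.
#' @param nSets number of random sets (default 1000).
#' @param seed RNG seed (stored in the result).
#' @return A \linkS4class{NullDistribution}; quantiles of |score| at the
#'   50th, 95th and 99th percentile and the maximum are precomputed.
#' @export
randomSetNull <- function(z, sig, nSets = 1000L, seed = 1L) {
    z <- .checkMatrix(z)
    fc <- sigFoldChanges(sig)
    k <- length(fc)
    if (nrow(z) < k)
        stop("measured-gene universe smaller than the signature")
    genes <- rownames(z)
    scores <- withr::with_seed(as.integer(seed), {
        t(vapply(seq_len(nSets), function(i) {
            idx <- sample.int(length(genes), k)
            drop(cor(fc, z[idx, , drop = FALSE], method = "spearman"))
        }, numeric(ncol(z))))
    })
    dimnames(scores) <- list(NULL, colnames(z))
    q <- quantile(abs(scores), c(0.5, 0.95, 0.99))
    quant <- c(q50 = unname(q[1]), q95 = unname(q[2]),
               q99 = unname(q[3]), max = max(abs(scores)))
    new("NullDistribution", scores = scores, setSize = as.integer(k),
        seed = as.integer(seed), quantiles = quant)
}
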