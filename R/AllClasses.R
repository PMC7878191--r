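#' @import methods
#' @importFrom stats cor median quantile sd var rnorm runif rmultinom
#'   rgamma p.adjust pt pnorm pwilcox dnorm setNames hclust dist
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Signed lineage signature
#'
#' A set of genes with signed log2 fold changes following the
#' squamous-positive convention: positive values mark genes higher in
#' squamous/ectocervical organoids, negative values genes higher in
#' columnar/endocervical organoids. The thresholds used to derive the
#' signature are carried along for provenance; synthetic signatures that were
#' not derived from a differential-expression table store \code{NA}
#' thresholds.
#'
#' @slot foldChanges named numeric vector, gene -> signed log2 fold change.
#' @slot fdrMax numeric(1), FDR threshold used to build the signature
#'   (strict, \code{fdr < fdrMax}); \code{NA} if not applicable.
#' @slot absFcMin numeric(1), absolute log2 fold-change threshold (strict,
#'   \code{|log2fc| > absFcMin}); \code{NA} if not applicable.
#'
#' @aliases LineageSignature-class
#' @exportClass LineageSignature
setClass("LineageSignature",
    representation(foldChanges = "numeric", fdrMax = "numeric",
                   absFcMin = "numeric"))

setValidity("LineageSignature", function(object) {
    fc <- object@foldChanges
    if (length(fc) > 0L && (is.null(names(fc)) || any(!nzchar(names(fc)))))
        return("all fold changes must be named by gene")
    if (anyDuplicated(names(fc)))
        return("duplicate gene ids in signature")
    if (any(!is.finite(fc)))
        return("fold changes must be finite")
    if (length(fc) > 0L && is.finite(object@absFcMin) &&
        any(abs(fc) <= object@absFcMin))
        return("all |log2fc| must exceed absFcMin")
    TRUE
})

#' Construct a LineageSignature
#'
#' @param foldChanges named numeric vector of signed log2 fold changes
#'   (squamous-positive convention).
#' @param fdrMax,absFcMin thresholds recorded for provenance (\code{NA} for
#'   synthetic signatures).
#' @return A \linkS4class{LineageSignature}.
#' @examples
#' LineageSignature(c(KRT5 = 3.1, KRT7 = -2.4))
#' @export
LineageSignature <- function(foldChanges, fdrMax = NA_real_,
                             absFcMin = NA_real_) {
    new("LineageSignature", foldChanges = foldChanges,
        fdrMax = as.numeric(fdrMax), absFcMin = as.numeric(absFcMin))
}

#' Stem-cell voting meta-signature
#'
#' Genes significantly up- or down-regulated in stem versus differentiated
#' cells in at least \code{supportThreshold} of \code{nComparisons}
#' differential-expression comparisons.
#'
#' @slot upGenes,downGenes character vectors of gene ids (disjoint).
#' @slot supportThreshold integer(1), minimum number of supporting
#'   comparisons.
#' @slot nComparisons integer(1), number of comparisons voted over.
#'
#' @aliases StemSignature-class
#' @exportClass StemSignature
setClass("StemSignature",
    representation(upGenes = "character", downGenes = "character",
                   supportThreshold = "integer", nComparisons = "integer"))

setValidity("StemSignature", function(object) {
    if (length(intersect(object@upGenes, object@downGenes)) > 0L)
        return("upGenes and downGenes must be disjoint")
    if (object@supportThreshold < 1L)
        return("supportThreshold must be >= 1")
    if (object@supportThreshold > object@nComparisons)
        return("supportThreshold cannot exceed nComparisons")
    TRUE
})

#' Per-sample Co-Sq scores and class labels
#'
#' The Co-Sq score of a sample is the Spearman correlation between its
#' z-scored expression over the signature genes and the signature's signed
#' fold changes. Samples with score > \code{upper} are squamous-like, score
#' < \code{lower} columnar-like, all others undetermined (strict
#' inequalities; a score exactly at a threshold is undetermined).
#'
#' @slot score named numeric vector of per-sample scores in [-1, 1].
#' @slot label named character vector of class labels, parallel to score.
#' @slot upper,lower numeric(1) classification thresholds.
#' @slot nOverlap integer(1), number of signature genes found in the
#'   expression matrix and used for scoring.
#'
#' @aliases CoSqResult-class
#' @exportClass CoSqResult
setClass("CoSqResult",
    representation(score = "numeric", label = "character",
                   upper = "numeric", lower = "numeric",
                   nOverlap = "integer"))

.cosqLabels <- c("squamous-like", "columnar-like", "undetermined")

setValidity("CoSqResult", function(object) {
    s <- object@score; l <- object@label
    if (length(s) != length(l) || !identical(names(s), names(l)))
        return("score and label must be parallel named vectors")
    if (any(abs(s) > 1 + 1e-12))
        return("scores must lie in [-1, 1]")
    if (!all(l %in% .cosqLabels))
        return("unknown class label")
    expect <- ifelse(s > object@upper, "squamous-like",
              ifelse(s < object@lower, "columnar-like", "undetermined"))
    if (!all(l == expect))
        return("labels inconsistent with scores and thresholds")
    TRUE
})

#' Null distribution of Co-Sq scores from random gene sets
#'
#' Scores obtained by re-running the classification procedure on random gene
#' sets of the same size as the signature, paired position-wise with the
#' signature's fold-change vector.
#'
#' @slot scores numeric matrix, n_sets x n_samples.
#' @slot setSize integer(1), size of each random set (= signature size used).
#' @slot seed integer(1), RNG seed used for the draws.
#' @slot quantiles named numeric vector of summary quantiles of |score|.
#'
#' @aliases NullDistribution-class
#' @exportClass NullDistribution
setClass("NullDistribution",
    representation(scores = "matrix", setSize = "integer", seed = "integer",
                   quantiles = "numeric"))

setValidity("NullDistribution", function(object) {
    if (any(abs(object@scores) > 1 + 1e-12))
        return("null scores must lie in [-1, 1]")
    TRUE
})

#' Bimodal expression threshold for a marker gene
#'
#' Result of a deterministic two-component Gaussian-mixture fit used to
#' separate marker-high from marker-low samples, replacing a manual cut
#' point. The threshold is the point of equal posterior probability between
#' the two components and always lies strictly between the component means.
#'
#' @slot marker character(1) marker gene id (may be \code{NA}).
#' @slot threshold numeric(1) cut point (same units as the input values).
#' @slot componentMeans numeric(2), sorted component means.
#' @slot componentSds numeric(2), component standard deviations.
#' @slot weights numeric(2), mixing weights.
#' @slot separation numeric(1), |mu2 - mu1| / pooled sd.
#' @slot bimodal logical(1), FALSE when separation < the requested minimum.
#'
#' @aliases MarkerThreshold-class
#' @exportClass MarkerThreshold
setClass("MarkerThreshold",
    representation(marker = "character", threshold = "numeric",
                   componentMeans = "numeric", componentSds = "numeric",
                   weights = "numeric", separation = "numeric",
                   bimodal = "logical"))

setValidity("MarkerThreshold", function(object) {
    m <- sort(object@componentMeans)
    if (!(object@threshold > m[1] && object@threshold < m[2]))
        return("threshold must lie strictly between the component means")
    TRUE
})
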