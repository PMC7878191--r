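#' Accessors for cosq result objects
#'
#' Small generics giving read access to the slots of the S4 result classes
#' without touching \code{@}.
#'
#' @param x a \linkS4class{LineageSignature}, \linkS4class{StemSignature},
#'   \linkS4class{CoSqResult} or \linkS4class{NullDistribution}.
#' @return \code{sigGenes}: character vector of signature genes.
#'   \code{sigFoldChanges}: named numeric vector of signed log2 fold changes.
#'   \code{sampleScores} / \code{sampleLabels}: named per-sample vectors.
#'   \code{upGenes} / \code{downGenes}: character vectors.
#'   \code{nullScores}: the n_sets x n_samples score matrix.
#'   \code{nullQuantiles}: named quantiles of |null score|.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))
#' @rdname accessors
#' @export
setGeneric("sigFoldChanges", function(x) standardGeneric("sigFoldChanges"))
#' @rdname accessors
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))
#' @rdname accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))
#' @rdname accessors
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))
#' @rdname accessors
#' @export
setGeneric("nullQuantiles", function(x) standardGeneric("nullQuantiles"))

#' @rdname accessors
setMethod("sigGenes", "LineageSignature",
          function(x) names(x@foldChanges))
#' @rdname accessors
setMethod("sigFoldChanges", "LineageSignature", function(x) x@foldChanges)

#' @describeIn accessors number of genes in a signature.
#' @export
setMethod("length", "LineageSignature", function(x) length(x@foldChanges))

#' @rdname accessors
setMethod("sampleScores", "CoSqResult", function(x) x@score)
#' @rdname accessors
setMethod("sampleLabels", "CoSqResult", function(x) x@label)

#' @rdname accessors
setMethod("upGenes", "StemSignature", function(x) x@upGenes)
#' @rdname accessors
setMethod("downGenes", "StemSignature", function(x) x@downGenes)

#' @rdname accessors
setMethod("nullScores", "NullDistribution", function(x) x@scores)
#' @rdname accessors
setMethod("nullQuantiles", "NullDistribution", function(x) x@quantiles)

#' Coerce a CoSqResult to a data.frame
#'
#' @param x a \linkS4class{CoSqResult}.
#' @param ... ignored.
#' @return data.frame with columns \code{sample}, \code{score},
#'   \code{label}, \code{n_overlap}.
#' @export
setMethod("as.data.frame", "CoSqResult", function(x, ...) {
    data.frame(sample = names(x@score), score = unname(x@score),
               label = unname(x@label), n_overlap = x@nOverlap,
               stringsAsFactors = FALSE)
})

setMethod("show", "LineageSignature", function(object) {
    fc <- object@foldChanges
    cat("LineageSignature with", length(fc), "genes",
        sprintf("(%d squamous-positive, %d columnar-positive)\n",
                sum(fc > 0), sum(fc < 0)))
    cat("  thresholds: fdr <", object@fdrMax, "; |log2fc| >",
        object@absFcMin, "\n")
    if (length(fc) > 0L) {
        show <- head(fc, 4L)
        cat("  ", paste(sprintf("%s=%.2f", names(show), show),
                        collapse = " "),
            if (length(fc) > 4L) "..." else "", "\n")
    }
})

setMethod("show", "StemSignature", function(object) {
    cat(sprintf(
        "StemSignature: %d up / %d down genes (>= %d of %d comparisons)\n",
        length(object@upGenes), length(object@downGenes),
        object@supportThreshold, object@nComparisons))
})

setMethod("show", "CoSqResult", function(object) {
    tab <- table(factor(object@label, levels = .cosqLabels))
    cat("CoSqResult for", length(object@score), "samples",
        sprintf("(thresholds %g / %g, %d signature genes scored)\n",
                object@lower, object@upper, object@nOverlap))
    print(tab)
})

setMethod("show", "NullDistribution", function(object) {
    cat(sprintf(
        "NullDistribution: %d random sets of size %d x %d samples (seed %d)\n",
        nrow(object@scores), object@setSize, ncol(object@scores),
        object@seed))
    cat("  |score| quantiles:",
        paste(sprintf("%s=%.4f", names(object@quantiles), object@quantiles),
              collapse = " "), "\n")
})

setMethod("show", "MarkerThreshold", function(object) {
    cat(sprintf(
        "MarkerThreshold%s: cut %.3f between means (%.3f, %.3f); separation %.2f%s\n",
        if (is.na(object@marker)) "" else paste0(" [", object@marker, "]"),
        object@threshold, object@componentMeans[1], object@componentMeans[2],
        object@separation, if (object@bimodal) "" else " (non-bimodal)"))
})
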