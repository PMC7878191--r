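#' Write an expression matrix as TSV
#'
#' Tab-separated, header row of sample ids, first column \code{id} holding
#' the feature (probe or gene) identifiers.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTsv <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path file written by \code{\link{writeExpressionTsv}} (or any TSV
#'   with feature ids in the first column and samples in the header).
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readExpressionTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
}

#' Write a lineage signature as two-column TSV with JSON provenance
#'
#' The TSV has columns \code{gene} and \code{log2fc}; a sidecar
#' \code{<path>.json} records the thresholds, signature size and optional
#' input-file hashes.
#'
#' @param sig a \linkS4class{LineageSignature}.
#' @param path output TSV path.
#' @param inputHashes optional named character vector of md5 hashes of the
#'   inputs the signature was derived from.
#' @return invisibly, \code{path}.
#' @export
writeSignatureTsv <- function(sig, path, inputHashes = NULL) {
    fc <- sigFoldChanges(sig)
    write.table(data.frame(gene = names(fc), log2fc = unname(fc)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- list(size = length(fc),
                 input_hashes = as.list(inputHashes))
    if (!is.na(sig@fdrMax)) prov$fdr_max <- sig@fdrMax
    if (!is.na(sig@absFcMin)) prov$abs_fc_min <- sig@absFcMin
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a lineage signature from TSV
#'
#' @param path TSV written by \code{\link{writeSignatureTsv}}; thresholds
#'   are restored from the JSON sidecar when present.
#' @return A \linkS4class{LineageSignature}.
#' @export
readSignatureTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    fdrMax <- NA_real_; absFcMin <- NA_real_
    side <- paste0(path, ".json")
    if (file.exists(side)) {
        prov <- jsonlite::read_json(side)
        if (!is.null(prov$fdr_max)) fdrMax <- as.numeric(prov$fdr_max)
        if (!is.null(prov$abs_fc_min))
            absFcMin <- as.numeric(prov$abs_fc_min)
    }
    LineageSignature(setNames(df$log2fc, df$gene), fdrMax = fdrMax,
                     absFcMin = absFcMin)
}
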