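#' Default pipeline configuration
#'
#' Returns the full configuration with every threshold at its documented
#' default: Co-Sq classification at +0.2 / -0.2; QC at 250 / 4,000 genes,
#' 15,000 UMIs, 10\% mitochondrial fraction; HVG bounds 0.0125 / 4 with an
#' s.d. floor of 0.5; voting at 5 of 18 comparisons with |logFC| > 1 and
#' adjusted P < 0.05; 1,000 random gene sets; signature thresholds
#' FDR < 0.05 and |log2fc| > 1.
#'
#' @return nested named list.
#' @export
cosqDefaults <- function() {
    list(
        outdir = "cosq_out",
        seed = 1L,
        simulate = list(
            organoid = list(n_genes = 1000L, n_probes_per_gene = 2L,
                            n_samples_per_group = 5L, n_de_genes = 100L,
                            de_log2fc = 2.0, noise_sd = 0.3),
            cohort = list(n_samples = 178L,
                          class_proportions = c(0.4, 0.4, 0.2),
                          n_genes = 2000L, signature_size = 200L,
                          library_size_range = c(0.5, 2),
                          mix_fraction = 0.5, effect_log2 = 1.0,
                          noise_sd = 0.5),
            sc = list(n_cells_good = 500L, n_barcodes_junk = 100L,
                      n_genes = 5000L, n_mito_genes = 13L,
                      n_clusters = 3L),
            stem = list(n_comparisons = 18L, support = 5L,
                        n_genes = 500L)),
        signature = list(fdr_max = 0.05, abs_fc_min = 1.0),
        voting = list(abs_logfc_min = 1.0, adj_p_max = 0.05,
                      min_support = 5L),
        classify = list(upper = 0.2, lower = -0.2, n_sets = 1000L,
                        pseudocount = 1,
                        marker_genes = c("KRT5", "TP63", "KRT7"),
                        marker_min_separation = 1.0,
                        adenoma_terms = c("adenocarcinoma",
                                          "adenosquamous carcinoma"),
                        other_terms = c("squamous cell carcinoma")),
        scqc = list(min_genes = 250L, max_genes = 4000L,
                    max_umis = 15000L, max_mito_fraction = 0.10,
                    mito_pattern = "^mt-",
                    hvg = list(nonzero_mean_low = 0.0125,
                               nonzero_mean_high = 4, sd_min = 0.5)))
}

.mergeConfig <- function(defaults, user, path = character(0),
                         warnings = NULL) {
    for (key in names(user)) {
        here <- paste(c(path, key), collapse = ".")
        if (!key %in% names(defaults)) {
            warning("unknown configuration key: ", here, call. = FALSE)
            next
        }
        if (is.list(defaults[[key]]) && is.list(user[[key]])) {
            defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                            c(path, key))
        } else {
            defaults[[key]] <- user[[key]]
        }
    }
    defaults
}

#' Validate (and default-fill) a pipeline configuration
#'
#' Reads a YAML file (or takes a list), overlays it on
#' \code{\link{cosqDefaults}}, warns on unknown keys and collects every
#' constraint violation with its field path before failing.
#'
#' @param config path to a YAML file, or a named list (possibly empty for
#'   an all-defaults run).
#' @return validated configuration list with class \code{"cosqConfig"}.
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
        if (is.null(config)) config <- list()
    }
    if (!is.list(config))
        stop("config must be a YAML file path or a list")
    cfg <- .mergeConfig(cosqDefaults(), config)
    errs <- character(0)
    chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)

    chk(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed),
        "seed: must be an integer")
    chk(cfg$classify$upper > cfg$classify$lower,
        "classify.upper: must exceed classify.lower")
    chk(cfg$classify$n_sets > 0, "classify.n_sets: must be positive")
    chk(cfg$scqc$min_genes < cfg$scqc$max_genes,
        "scqc.min_genes: must be below scqc.max_genes")
    chk(all(c(cfg$scqc$min_genes, cfg$scqc$max_umis,
              cfg$scqc$max_mito_fraction) > 0),
        "scqc: thresholds must be positive")
    chk(cfg$scqc$hvg$nonzero_mean_low < cfg$scqc$hvg$nonzero_mean_high,
        "scqc.hvg.nonzero_mean_low: must be below nonzero_mean_high")
    chk(abs(sum(cfg$simulate$cohort$class_proportions) - 1) < 1e-9,
        "simulate.cohort.class_proportions: must sum to 1")
    chk(cfg$simulate$organoid$n_de_genes <=
            cfg$simulate$organoid$n_genes,
        "simulate.organoid.n_de_genes: cannot exceed n_genes")
    chk(cfg$voting$min_support >= 1 &&
            cfg$voting$min_support <= cfg$simulate$stem$n_comparisons,
        "voting.min_support: must be in 1..n_comparisons")
    chk(cfg$signature$fdr_max > 0 && cfg$signature$abs_fc_min > 0,
        "signature: thresholds must be positive")
    if (length(errs) > 0L)
        stop("invalid configuration:\n  ",
             paste(errs, collapse = "\n  "), call. = FALSE)
    class(cfg) <- "cosqConfig"
    cfg
}

.log <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

.stageDir <- function(cfg, stage) {
    d <- file.path(cfg$outdir, stage)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    d
}

.requireOutput <- function(path, stage) {
    if (!file.exists(path))
        stop("missing output of stage '", stage, "': ", path,
             " (run that stage first)", call. = FALSE)
    path
}

#' Run the analysis pipeline
#'
#' Executes the requested stage (or all stages in dependency order:
#' simulate, then signature and classify; scqc independent) against a
#' validated configuration, writing results and a run manifest under the
#' configured output directory.
#'
#' Stage outputs: \code{simulate/} (expression TSVs, Matrix-Market counts,
#' truth JSONs), \code{signature/} (lineage signature TSV + provenance,
#' stem-voting gene sets), \code{classify/} (per-sample scores/labels TSV,
#' null-distribution summary JSON, marker thresholds JSON, contingency
#' TSV), \code{scqc/} (QC report TSV + summary JSON, HVG list, centroid
#' tree Newick, composition TSV), and \code{manifest.json}.
#'
#' @param config a YAML path, list, or validated \code{cosqConfig}.
#' @param stage one of "simulate", "signature", "classify", "scqc", "all".
#' @param outdir,seed optional overrides of the configured values.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(),
                        stage = c("all", "simulate", "signature",
                                  "classify", "scqc"),
                        outdir = NULL, seed = NULL) {
    stage <- match.arg(stage)
    cfg <- if (inherits(config, "cosqConfig")) config
           else validateConfig(config)
    if (!is.null(outdir)) cfg$outdir <- outdir
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    stages <- if (stage == "all")
        c("simulate", "signature", "classify", "scqc") else stage
    timings <- list()
    for (s in stages) {
        .log(s, sprintf("starting (seed %d)", cfg$seed))
        t0 <- proc.time()[["elapsed"]]
        switch(s,
               simulate = .stageSimulate(cfg),
               signature = .stageSignature(cfg),
               classify = .stageClassify(cfg),
               scqc = .stageScqc(cfg))
        timings[[s]] <- round(proc.time()[["elapsed"]] - t0, 3)
        .log(s, sprintf("done in %.1fs", timings[[s]]))
    }
    manifest <- .writeManifest(cfg, timings)
    invisible(manifest)
}

.stageSimulate <- function(cfg) {
    d <- .stageDir(cfg, "simulate")
    sc <- cfg$simulate
    org <- simulateOrganoidArrays(
        nGenes = sc$organoid$n_genes,
        nProbesPerGene = sc$organoid$n_probes_per_gene,
        nSamplesPerGroup = sc$organoid$n_samples_per_group,
        nDeGenes = sc$organoid$n_de_genes,
        deLog2fc = sc$organoid$de_log2fc,
        noiseSd = sc$organoid$noise_sd, seed = cfg$seed)
    writeExpressionTsv(SummarizedExperiment::assay(org, "exprs"),
                       file.path(d, "organoid_exprs.tsv"))
    write.table(as.data.frame(rowData(org)),
                file.path(d, "organoid_annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(colData(org))["group"],
                file.path(d, "organoid_groups.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    jsonlite::write_json(
        list(de_genes = as.list(plantedTruth(org)$deGenes)),
        file.path(d, "organoid_truth.json"), auto_unbox = TRUE,
        digits = NA)

    # plant the organoid truth as the cohort's signature so the organoid
    # universe and the tumour cohort share gene ids end to end
    coh <- simulateTumorCohort(
        nSamples = sc$cohort$n_samples,
        classProportions = sc$cohort$class_proportions,
        nGenes = sc$cohort$n_genes,
        signatureSize = sc$cohort$signature_size,
        signature = LineageSignature(plantedTruth(org)$deGenes),
        librarySizeRange = sc$cohort$library_size_range,
        mixFraction = sc$cohort$mix_fraction,
        effectLog2 = sc$cohort$effect_log2,
        noiseSd = sc$cohort$noise_sd, seed = cfg$seed + 1L)
    writeExpressionTsv(SummarizedExperiment::assay(coh, "exprs"),
                       file.path(d, "cohort_exprs.tsv"))
    write.table(as.data.frame(colData(coh))[c("class", "histology")],
                file.path(d, "cohort_annotation.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    jsonlite::write_json(
        list(sample_classes = as.list(plantedTruth(coh)$sampleClasses)),
        file.path(d, "cohort_truth.json"), auto_unbox = TRUE,
        digits = NA)

    sce <- simulateScCounts(
        nCellsGood = sc$sc$n_cells_good,
        nBarcodesJunk = sc$sc$n_barcodes_junk,
        nGenes = sc$sc$n_genes, nMitoGenes = sc$sc$n_mito_genes,
        nClusters = sc$sc$n_clusters, seed = cfg$seed + 2L)
    writeMtxCounts(sce, file.path(d, "sc_counts"))
    tr <- plantedTruth(sce)
    jsonlite::write_json(
        list(cell_clusters = as.list(tr$cellClusters),
             tissues = as.list(tr$tissues),
             junk_barcodes = tr$junkBarcodes),
        file.path(d, "sc_truth.json"), auto_unbox = TRUE, digits = NA)

    stem <- simulateStemComparisons(
        nComparisons = sc$stem$n_comparisons,
        support = sc$stem$support, nGenes = sc$stem$n_genes,
        seed = cfg$seed + 3L)
    sd2 <- file.path(d, "stem_tables")
    dir.create(sd2, showWarnings = FALSE)
    for (i in seq_along(stem$tables))
        write.table(stem$tables[[i]],
                    file.path(sd2, sprintf("comparison_%02d.tsv", i)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(stem$truth, file.path(d, "stem_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(d)
}

.stageSignature <- function(cfg) {
    sim <- file.path(cfg$outdir, "simulate")
    exprsPath <- .requireOutput(file.path(sim, "organoid_exprs.tsv"),
                                "simulate")
    d <- .stageDir(cfg, "signature")
    m <- readExpressionTsv(exprsPath)
    ann <- read.delim(file.path(sim, "organoid_annotation.tsv"),
                      stringsAsFactors = FALSE)
    groups <- read.delim(file.path(sim, "organoid_groups.tsv"),
                         row.names = 1, stringsAsFactors = FALSE)
    norm <- quantileNormalize(m)
    de <- moderatedTTest(log2(norm),
                         rownames(groups)[groups$group == "squamous"],
                         rownames(groups)[groups$group == "columnar"])
    geneDe <- collapseProbes(de, ann, rule = "lowest_p")
    sig <- buildLineageSignature(geneDe,
                                 fdrMax = cfg$signature$fdr_max,
                                 absFcMin = cfg$signature$abs_fc_min)
    .log("signature", sprintf("%d genes in the lineage signature",
                              length(sig)))
    write.table(data.frame(gene = rownames(geneDe),
                           geneDe[, c("log2fc", "t", "p", "fdr", "df")]),
                file.path(d, "gene_de.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeSignatureTsv(sig, file.path(d, "lineage_signature.tsv"),
                      inputHashes = setNames(unname(tools::md5sum(exprsPath)),
                                             basename(exprsPath)))

    stemDir <- file.path(sim, "stem_tables")
    if (dir.exists(stemDir)) {
        tabs <- lapply(sort(list.files(stemDir, full.names = TRUE)),
                       read.delim, stringsAsFactors = FALSE)
        stemSig <- stemCellVoting(tabs, votingParams(
            absLogfcMin = cfg$voting$abs_logfc_min,
            adjPMax = cfg$voting$adj_p_max,
            minSupport = cfg$voting$min_support))
        jsonlite::write_json(
            list(up_genes = upGenes(stemSig),
                 down_genes = downGenes(stemSig),
                 support_threshold = stemSig@supportThreshold,
                 n_comparisons = stemSig@nComparisons),
            file.path(d, "stem_signature.json"), auto_unbox = TRUE)
    }
    invisible(d)
}

.stageClassify <- function(cfg) {
    sim <- file.path(cfg$outdir, "simulate")
    sigPath <- .requireOutput(
        file.path(cfg$outdir, "signature", "lineage_signature.tsv"),
        "signature")
    exprsPath <- .requireOutput(file.path(sim, "cohort_exprs.tsv"),
                                "simulate")
    d <- .stageDir(cfg, "classify")
    m <- readExpressionTsv(exprsPath)
    ann <- read.delim(file.path(sim, "cohort_annotation.tsv"),
                      row.names = 1, stringsAsFactors = FALSE)
    sig <- readSignatureTsv(sigPath)
    sf <- cohortSizeFactors(m)
    z <- preprocessCohort(m, sf, pseudocount = cfg$classify$pseudocount)
    res <- cosqClassify(z, sig, upper = cfg$classify$upper,
                        lower = cfg$classify$lower)
    write.table(as.data.frame(res), file.path(d, "cosq_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    null <- randomSetNull(z, sig, nSets = cfg$classify$n_sets,
                          seed = cfg$seed + 10L)
    jsonlite::write_json(
        list(n_sets = nrow(nullScores(null)),
             set_size = null@setSize, seed = null@seed,
             abs_score_quantiles = as.list(nullQuantiles(null))),
        file.path(d, "null_summary.json"), auto_unbox = TRUE,
        digits = NA)

    logm <- log2(sweep(m, 2L, sf, "/") + cfg$classify$pseudocount)
    markers <- intersect(cfg$classify$marker_genes, rownames(logm))
    thr <- lapply(markers, function(g)
        bimodalThreshold(logm[g, ], marker = g,
                         minSeparation = cfg$classify$marker_min_separation))
    jsonlite::write_json(
        lapply(thr, function(t) list(
            marker = t@marker, threshold = t@threshold,
            component_means = t@componentMeans,
            separation = t@separation, bimodal = t@bimodal)),
        file.path(d, "marker_thresholds.json"), auto_unbox = TRUE,
        digits = NA)

    histology <- setNames(ann$histology, rownames(ann))
    combined <- combineAdenomaDiagnoses(histology,
        adenomaTerms = cfg$classify$adenoma_terms,
        otherTerms = cfg$classify$other_terms)
    ct <- crosstabCompare(sampleLabels(res), combined)
    write.table(as.data.frame.matrix(ct$table),
                file.path(d, "contingency.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    invisible(d)
}

.stageScqc <- function(cfg) {
    sim <- file.path(cfg$outdir, "simulate")
    mtxDir <- file.path(sim, "sc_counts")
    .requireOutput(file.path(mtxDir, "matrix.mtx"), "simulate")
    d <- .stageDir(cfg, "scqc")
    sce <- readMtxCounts(file.path(mtxDir, "matrix.mtx"),
                         file.path(mtxDir, "barcodes.tsv"),
                         file.path(mtxDir, "features.tsv"),
                         mitoPattern = cfg$scqc$mito_pattern)
    qc <- qcFilter(sce, qcThresholds(
        minGenes = cfg$scqc$min_genes, maxGenes = cfg$scqc$max_genes,
        maxUmis = cfg$scqc$max_umis,
        maxMitoFraction = cfg$scqc$max_mito_fraction))
    .log("scqc", sprintf("%d of %d barcodes kept",
                         qc$summary$n_kept, qc$summary$n_barcodes))
    write.table(qc$report, file.path(d, "qc_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        qc$summary[c("n_barcodes", "n_kept", "n_excluded",
                     "n_genes_removed")],
        file.path(d, "qc_summary.json"), auto_unbox = TRUE)
    norm <- logNormalizeCounts(qc$sce)
    hvg <- selectHvg(norm, hvgCriteria(
        nonzeroMeanLow = cfg$scqc$hvg$nonzero_mean_low,
        nonzeroMeanHigh = cfg$scqc$hvg$nonzero_mean_high,
        sdMin = cfg$scqc$hvg$sd_min))
    writeLines(hvg, file.path(d, "hvg.txt"))

    truth <- jsonlite::read_json(file.path(sim, "sc_truth.json"))
    clusters <- unlist(truth$cell_clusters)
    tissues <- unlist(truth$tissues)
    tree <- clusterCentroidTree(norm, clusters[colnames(norm)],
                                geneSubset = if (length(hvg) >= 2) hvg)
    ape::write.tree(tree, file.path(d, "centroid_tree.nwk"))
    comp <- compositionTable(tissues, clusters)
    write.table(as.data.frame.matrix(comp$table),
                file.path(d, "composition.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeManifest <- function(cfg, timings) {
    cfgFile <- tempfile(fileext = ".yaml")
    on.exit(unlink(cfgFile))
    yaml::write_yaml(unclass(cfg), cfgFile)
    outputs <- list.files(cfg$outdir, recursive = TRUE,
                          full.names = FALSE)
    outputs <- setdiff(outputs, "manifest.json")
    hashes <- tools::md5sum(file.path(cfg$outdir, outputs))
    names(hashes) <- outputs
    manifest <- list(
        config_hash = unname(tools::md5sum(cfgFile)),
        software_version = as.character(packageVersion("cosq")),
        timings = timings,
        outputs = as.list(hashes))
    jsonlite::write_json(manifest,
                         file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
}
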