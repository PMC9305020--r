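#' Read a pipeline configuration file
#'
#' YAML key-value configuration with blocks `simulate` (a [simConfig]
#' argument list) *or* `input` (paths to counts/sample sheets/BED/FASTA
#' files), plus optional `thresholds`, `window`, `linkage`, `motifs`,
#' `stats` blocks, `seed`, and `outputDir`. Exactly one of
#' `simulate`/`input` must be present.
#'
#' @param path YAML file path.
#' @return a validated configuration list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg a configuration list (as from `yaml::read_yaml`).
#' @export
validatePipelineConfig <- function(cfg) {
    if (is.null(cfg$simulate) == is.null(cfg$input))
        stop("exactly one of 'simulate' or 'input' must be present")
    defaults <- list(
        seed = 1L,
        thresholds = list(padj = 0.05, lenientGeneP = 0.05,
                          lenientGeneBase = 10, lenientWindowP = 0.01,
                          lenientWindowBase = 15),
        window = list(width = 300L, step = 200L),
        linkage = list(dhsMaxDist = 1000L),
        motifs = list(pwmFile = NULL, minSeqs = 5L),
        stats = list(nTop = 500L, nPerm = 999L))
    for (blk in names(defaults)) {
        if (is.list(defaults[[blk]])) {
            cur <- if (is.null(cfg[[blk]])) list() else cfg[[blk]]
            cfg[[blk]] <- utils::modifyList(defaults[[blk]], cur)
        } else if (is.null(cfg[[blk]])) cfg[[blk]] <- defaults[[blk]]
    }
    th <- cfg$thresholds
    stopifnot(th$padj > 0, th$lenientGeneP > 0, th$lenientWindowP > 0)
    if (cfg$window$width < cfg$window$step)
        stop("window width must be >= step")
    class(cfg) <- "PipelineConfig"
    cfg
}

writeResultTSV <- function(df, path) {
    out <- as.data.frame(df)
    out <- cbind(feature = rownames(out), out)
    rownames(out) <- NULL
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full factorial analysis pipeline
#'
#' Stages, in order: (1) simulate or ingest inputs; (2) gene-level
#' differential testing (four Wald contrasts + interaction LRT);
#' (3) window-level differential testing; (4) window-to-peak joining per
#' contrast; (5) directional significance groups and overlap matrices for
#' genes and peaks; (6) red/blue integration classes; (7) accessibility
#' classification; (8) nearest-gene annotation and binding-sites-per-gene;
#' (9) reciprocal-background motif enrichment on linked DHS sequences;
#' (10) PCA and PERMANOVA per assay. All tables are written as TSV under
#' `outputDir` together with a JSON `manifest.json` recording the seed,
#' package version, and per-file row counts. Re-running with the same
#' configuration reproduces every output byte for byte.
#'
#' @param config a `PipelineConfig` (see [readPipelineConfig]), or a path
#'   to one.
#' @param outputDir overrides `config$outputDir`.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config)) config <- readPipelineConfig(config)
    config <- validatePipelineConfig(unclass(config))
    dir <- outputDir %||% config$outputDir
    if (is.null(dir)) stop("no output directory configured")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = config$seed,
                     package = as.character(utils::packageVersion("FactorialSeq")),
                     outputs = list())
    emit <- function(df, name) {
        path <- writeResultTSV(df, file.path(dir, name))
        manifest$outputs[[name]] <<- list(rows = nrow(df))
        path
    }
    stage <- "load-inputs"
    res <- tryCatch({
        ## stage 1: inputs -------------------------------------------------
        if (!is.null(config$simulate)) {
            scArgs <- config$simulate
            scArgs$seed <- config$seed
            if (!is.null(scArgs$chromLengths))
                scArgs$chromLengths <- unlist(scArgs$chromLengths)
            sc <- do.call(simConfig, scArgs)
            pwms <- if (!is.null(config$motifs$pwmFile))
                readPWMFile(config$motifs$pwmFile) else syntheticPWMs()
            sim <- simulateFactorialData(sc, pwms = pwms)
            rna <- sim$rna; windows <- sim$windows
            h3k27ac <- sim$h3k27ac
            genes <- sim$annotation$genes; peaks <- sim$annotation$peaks
            sites <- sim$annotation$sites
            accessibility <- sim$annotation$accessibility
            dhs <- sim$dhs; sequences <- sim$sequences
        } else {
            ip <- config$input
            pwms <- if (!is.null(config$motifs$pwmFile))
                readPWMFile(config$motifs$pwmFile) else syntheticPWMs()
            rna <- readFactorialExperiment(ip$rnaCounts, ip$rnaSamples)
            genes <- readBEDFile(ip$genes)
            peaks <- readBEDFile(ip$peaks)
            windows <- tileWindows(peaks, config$window$width,
                                   config$window$step)
            h3k27ac <- readFactorialExperiment(ip$windowCounts,
                                               ip$windowSamples)
            sites <- if (!is.null(ip$sites)) readBEDFile(ip$sites)
                     else GRanges()
            accessibility <- list()
            for (nm in names(ip$accessibility))
                accessibility[[nm]] <- readBEDFile(ip$accessibility[[nm]])
            dhs <- if (!is.null(ip$dhs)) readBEDFile(ip$dhs) else NULL
            sequences <- if (!is.null(ip$sequences))
                readDNAStringSet(ip$sequences) else NULL
        }

        th <- config$thresholds
        callArgs <- list(padjCutoff = th$padj, leniGeneP = th$lenientGeneP,
                         leniGeneBase = th$lenientGeneBase,
                         leniWinP = th$lenientWindowP,
                         leniWinBase = th$lenientWindowBase)

        ## stage 2: gene-level differential testing ------------------------
        stage <- "de-genes"
        geneRes <- do.call(factorialResults, c(list(rna), callArgs))
        for (cn in names(geneRes))
            emit(geneRes[[cn]], sprintf("genes_%s.tsv", safeName(cn)))

        ## stage 3: window-level differential testing ----------------------
        stage <- "de-windows"
        winRes <- do.call(factorialResults, c(list(h3k27ac), callArgs))
        for (cn in names(winRes))
            emit(winRes[[cn]], sprintf("windows_%s.tsv", safeName(cn)))

        ## stage 4: window -> peak joining ---------------------------------
        stage <- "join-peaks"
        peakRes <- lapply(names(factorialContrasts()), function(cn)
            joinWindowsToPeaks(winRes[[cn]], windows, flag = "standard"))
        names(peakRes) <- names(factorialContrasts())
        peakRes$interaction <- joinWindowsToPeaks(winRes$interaction,
                                                  windows,
                                                  flag = "lenientWindow")
        for (cn in names(peakRes))
            emit(peakRes[[cn]], sprintf("peaks_%s.tsv", safeName(cn)))

        ## stage 5: directional groups + overlaps --------------------------
        stage <- "group"
        geneGroups <- assignDirectionalGroups(geneRes, flag = "standard")
        emit(geneGroups, "gene_groups.tsv")
        peakContrasts <- peakRes[names(factorialContrasts())]
        peakGroups <- assignDirectionalGroupsFromPeaks(peakContrasts)
        emit(peakGroups, "peak_groups.tsv")
        ov <- overlapMatrix(peakGroups)
        emitMatrix(ov$counts, file.path(dir, "peak_overlap_counts.tsv"))
        manifest$outputs[["peak_overlap_counts.tsv"]] <-
            list(rows = nrow(ov$counts))
        emitMatrix(round(ov$normalized, 6),
                   file.path(dir, "peak_overlap_normalized.tsv"))
        manifest$outputs[["peak_overlap_normalized.tsv"]] <-
            list(rows = nrow(ov$normalized))

        ## stage 6: integration classes ------------------------------------
        stage <- "classify-integration"
        integ <- classifyIntegration(peakGroups)
        emit(integ, "peak_integration_classes.tsv")

        ## stage 7: accessibility ------------------------------------------
        stage <- "classify-accessibility"
        if (length(accessibility) >= 2) {
            acc <- classifyAccessibility(peaks, accessibility)
            rownames(acc) <- names(peaks)
            emit(acc, "peak_accessibility.tsv")
        }

        ## stage 8: annotation ---------------------------------------------
        stage <- "annotate"
        nearest <- nearestFeature(peaks, genes)
        rownames(nearest) <- nearest$query
        emit(nearest, "peak_nearest_gene.tsv")
        spg <- countSitesPerGene(sites, genes)
        spgTab <- DataFrame(sites = as.integer(spg),
                            bin = as.character(binGenesBySiteCount(spg)),
                            row.names = names(spg))
        emit(spgTab, "sites_per_gene.tsv")

        ## stage 9: motif enrichment ---------------------------------------
        stage <- "motifs"
        if (!is.null(dhs) && !is.null(sequences)) {
            links <- nearestFeature(peaks, dhs,
                                    maxDist = config$linkage$dhsMaxDist)
            enr <- withCallingHandlers(
                runReciprocalEnrichment(peakGroups, links, sequences, pwms,
                                        minSeqs = config$motifs$minSeqs),
                warning = function(w) invokeRestart("muffleWarning"))
            for (nm in names(enr))
                emit(enr[[nm]], sprintf("motifs_%s.tsv", safeName(nm)))
        }

        ## stage 10: sample statistics --------------------------------------
        stage <- "stats"
        for (assay in c("rna", "h3k27ac")) {
            fe <- if (assay == "rna") rna else h3k27ac
            st <- sampleStats(fe, nTop = config$stats$nTop,
                              nPerm = config$stats$nPerm,
                              seed = config$seed)
            coords <- DataFrame(st$pca$coordinates)
            rownames(coords) <- colnames(fe)
            emit(coords, sprintf("%s_pca_coordinates.tsv", assay))
            ve <- DataFrame(component = paste0("PC",
                                seq_along(st$pca$varianceExplained)),
                            varianceExplained = st$pca$varianceExplained)
            rownames(ve) <- ve$component
            emit(ve, sprintf("%s_pca_variance.tsv", assay))
            pm <- DataFrame(st$permanova)
            rownames(pm) <- pm$factor
            emit(pm, sprintf("%s_permanova.tsv", assay))
        }
        TRUE
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}

# peak-level contrast tables (from joinWindowsToPeaks) already carry a
# direction; reshape them into the same 8-group layout as
# assignDirectionalGroups()
assignDirectionalGroupsFromPeaks <- function(peakContrasts) {
    need <- names(factorialContrasts())
    stopifnot(all(need %in% names(peakContrasts)))
    feats <- rownames(peakContrasts[[need[1]]])
    out <- DataFrame(row.names = feats)
    for (cn in need) {
        r <- peakContrasts[[cn]][feats, ]
        out[[paste0("direction.", cn)]] <- r$direction
        out[[paste0(cn, ".up")]] <- r$direction == "up"
        out[[paste0(cn, ".down")]] <- r$direction == "down"
    }
    metadata(out)$groups <- groupColumns()
    out
}

safeName <- function(x) gsub("[^A-Za-z0-9._-]", "_", gsub("/", "_vs_", x))

emitMatrix <- function(m, path) {
    df <- data.frame(group = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
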