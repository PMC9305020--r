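#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table
NULL

#' Read and write TSV count matrices
#'
#' Format: a header row of sample ids, then one row per feature with the
#' feature id in the first column.
#'
#' @param path file path.
#' @return `readCountMatrix`: numeric matrix with feature row names.
#' @export
readCountMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "numeric"
    m
}

#' @rdname readCountMatrix
#' @param counts matrix to write (row names = feature ids).
#' @export
writeCountMatrix <- function(counts, path) {
    df <- data.frame(feature = rownames(counts), counts,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write the sample sheet
#'
#' Columns: `sample`, `microbes` (GF/CV), `meal` (none/HFM).
#'
#' @param path file path.
#' @return `readSampleSheet`: data.frame.
#' @export
readSampleSheet <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readSampleSheet
#' @param fe a [FactorialExperiment] whose design to write.
#' @export
writeSampleSheet <- function(fe, path) {
    df <- data.frame(sample = colnames(fe),
                     microbes = as.character(microbes(fe)),
                     meal = as.character(meal(fe)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble a FactorialExperiment from a counts TSV and a sample sheet
#'
#' @param countsPath,sheetPath file paths.
#' @return a [FactorialExperiment].
#' @export
readFactorialExperiment <- function(countsPath, sheetPath) {
    k <- readCountMatrix(countsPath)
    sheet <- readSampleSheet(sheetPath)
    missing <- setdiff(colnames(k), sheet$sample)
    if (length(missing))
        stop("samples in counts missing from sample sheet: ",
             paste(missing, collapse = ", "))
    sheet <- sheet[match(colnames(k), sheet$sample), ]
    FactorialExperiment(k, microbes = sheet$microbes, meal = sheet$meal)
}

#' Read and write BED interval files
#'
#' Standard 0-based half-open BED via rtracklayer; on reading, the BED name
#' field (when present) becomes both `names()` and the `name` metadata
#' column of the returned `GRanges`.
#'
#' @param path file path.
#' @return `readBEDFile`: a `GRanges`.
#' @export
readBEDFile <- function(path) {
    gr <- import(path, format = "BED")
    if (!is.null(gr$name)) names(gr) <- gr$name
    gr
}

#' @rdname readBEDFile
#' @param gr `GRanges` to write; `names(gr)` (or `gr$name`) populate the
#'   BED name field.
#' @export
writeBEDFile <- function(gr, path) {
    if (is.null(gr$name) && !is.null(names(gr))) gr$name <- names(gr)
    export(gr, path, format = "BED")
    invisible(path)
}

#' Write all simulated objects as pipeline input fixtures
#'
#' Emits, under `dir`: `rna_counts.tsv` + `rna_samples.tsv`,
#' `h3k27ac_window_counts.tsv` + `h3k27ac_samples.tsv`, `genes.bed`,
#' `peaks.bed`, `windows.bed` (name = parentPeak:windowIndex),
#' `binding_sites.bed`, `accessibility_<type>.bed`, `dhs.bed`,
#' `dhs_sequences.fa`, `truth_genes.tsv`, `truth_peaks.tsv`,
#' `planted_motifs.tsv`. Everything round-trips losslessly through the
#' package readers.
#'
#' @param sim output of [simulateFactorialData].
#' @param dir output directory (created when absent).
#' @return invisibly, the vector of written paths.
#' @export
writeFixtures <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    written <- character(0)
    w <- function(path) { written <<- c(written, path); path }
    if (!is.null(sim$rna)) {
        writeCountMatrix(counts(sim$rna), w(p("rna_counts.tsv")))
        writeSampleSheet(sim$rna, w(p("rna_samples.tsv")))
    }
    if (!is.null(sim$h3k27ac)) {
        writeCountMatrix(counts(sim$h3k27ac),
                         w(p("h3k27ac_window_counts.tsv")))
        writeSampleSheet(sim$h3k27ac, w(p("h3k27ac_samples.tsv")))
    }
    ann <- sim$annotation
    if (length(ann$genes)) writeBEDFile(ann$genes, w(p("genes.bed")))
    if (length(ann$peaks)) writeBEDFile(ann$peaks, w(p("peaks.bed")))
    if (!is.null(sim$windows))
        writeBEDFile(sim$windows, w(p("windows.bed")))
    if (length(ann$sites))
        writeBEDFile(ann$sites, w(p("binding_sites.bed")))
    for (tp in names(ann$accessibility))
        if (length(ann$accessibility[[tp]]))
            writeBEDFile(ann$accessibility[[tp]],
                         w(p(sprintf("accessibility_%s.bed", tp))))
    if (!is.null(sim$dhs)) writeBEDFile(sim$dhs, w(p("dhs.bed")))
    if (!is.null(sim$sequences))
        writeXStringSet(sim$sequences, w(p("dhs_sequences.fa")))
    for (ft in names(sim$truth)) {
        df <- data.frame(feature = rownames(sim$truth[[ft]]),
                         sim$truth[[ft]], check.names = FALSE)
        write.table(df, w(p(sprintf("truth_%s.tsv", ft))), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    if (!is.null(sim$planted))
        write.table(sim$planted, w(p("planted_motifs.tsv")), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(written)
}

#' Validate pipeline input files
#'
#' Checks BED coordinate sanity, agreement between count matrices and their
#' sample sheets, and agreement between FASTA sequence ids and a region BED.
#'
#' @param counts,samples optional paths to a counts TSV and sample sheet.
#' @param beds optional character vector of BED paths.
#' @param fasta,regions optional FASTA path and matching region BED path.
#' @return a data.frame report with columns `level` (`fatal`/`warning`),
#'   `file`, `message`; zero rows when everything is clean.
#' @export
validateInputs <- function(counts = NULL, samples = NULL, beds = NULL,
                           fasta = NULL, regions = NULL) {
    rep <- list()
    add <- function(level, file, message)
        rep[[length(rep) + 1L]] <<- data.frame(level = level, file = file,
                                               message = message)
    if (!is.null(counts)) {
        k <- tryCatch(readCountMatrix(counts), error = function(e) e)
        if (inherits(k, "error"))
            add("fatal", counts, conditionMessage(k))
        else {
            if (any(!is.finite(k)) || any(k < 0))
                add("fatal", counts, "negative or non-finite counts")
            if (!is.null(samples)) {
                sheet <- readSampleSheet(samples)
                miss <- setdiff(colnames(k), sheet$sample)
                if (length(miss))
                    add("fatal", samples, paste("samples missing from sheet:",
                                                paste(miss, collapse = ", ")))
                badM <- !sheet$microbes %in% c("GF", "CV")
                badF <- !sheet$meal %in% c("none", "HFM")
                if (any(badM | badF))
                    add("fatal", samples, "invalid microbes/meal levels")
            }
        }
    }
    for (b in beds) {
        lines <- readLines(b)
        lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
        parts <- strsplit(lines, "\t")
        for (i in seq_along(parts)) {
            f <- parts[[i]]
            if (length(f) < 3) {
                add("fatal", b, sprintf("line %d: fewer than 3 fields", i))
                next
            }
            s <- suppressWarnings(as.numeric(f[2]))
            e <- suppressWarnings(as.numeric(f[3]))
            if (is.na(s) || is.na(e) || s < 0 || s >= e)
                add("fatal", b, sprintf("line %d: start >= end", i))
        }
    }
    if (!is.null(fasta) && !is.null(regions)) {
        sq <- readDNAStringSet(fasta)
        gr <- readBEDFile(regions)
        miss <- setdiff(names(gr), names(sq))
        if (length(miss))
            add("fatal", fasta, paste("regions without sequence:",
                                      paste(utils::head(miss), collapse = ", ")))
    }
    if (!length(rep))
        return(data.frame(level = character(0), file = character(0),
                          message = character(0)))
    do.call(rbind, rep)
}
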