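#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
#' @importFrom BiocGenerics sizeFactors sizeFactors<- counts
NULL

#' FactorialExperiment: counts under a microbiota-by-meal factorial design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding an
#' integer count matrix (features in rows, samples in columns) together with
#' the two binary experimental factors of the design: `microbes` (germ-free
#' `GF` vs conventionalized `CV`) and `meal` (`none` vs a single high-fat meal
#' `HFM`). All downstream model fitting assumes exactly these factor levels;
#' the reference condition is GF without a meal.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @export
setClass("FactorialExperiment", contains = "SummarizedExperiment")

setValidity("FactorialExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- assay(object, "counts")
        if (!is.numeric(k) || any(k < 0) || any(!is.finite(k)))
            msg <- c(msg, "counts must be finite and non-negative")
        if (any(abs(k - round(k)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    cd <- colData(object)
    for (f in c("microbes", "meal")) {
        if (!f %in% names(cd)) {
            msg <- c(msg, sprintf("colData column '%s' is required", f))
            next
        }
        lev <- levels(cd[[f]])
        want <- if (f == "microbes") c("GF", "CV") else c("none", "HFM")
        if (!is.factor(cd[[f]]) || !identical(lev, want))
            msg <- c(msg, sprintf("'%s' must be a factor with levels %s",
                                  f, paste(want, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a FactorialExperiment
#'
#' @param counts integer matrix, features x samples. Column names are sample
#'   ids; row names are feature ids (generated when absent).
#' @param microbes character or factor, one of `"GF"`, `"CV"` per sample.
#' @param meal character or factor, one of `"none"`, `"HFM"` per sample.
#' @param rowRanges optional [GenomicRanges::GRanges] of feature coordinates.
#' @return a `FactorialExperiment`.
#' @examples
#' k <- matrix(rpois(40, 20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
#' fe <- FactorialExperiment(k,
#'     microbes = rep(c("GF", "CV"), each = 4),
#'     meal     = rep(c("none", "HFM"), 4))
#' condition(fe)
#' @export
FactorialExperiment <- function(counts, microbes, meal, rowRanges = NULL) {
    counts <- as.matrix(counts)
    mode(counts) <- "numeric"
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
    stopifnot(length(microbes) == ncol(counts), length(meal) == ncol(counts))
    cd <- DataFrame(
        microbes = factor(as.character(microbes), levels = c("GF", "CV")),
        meal     = factor(as.character(meal), levels = c("none", "HFM")),
        row.names = colnames(counts))
    if (anyNA(cd$microbes) || anyNA(cd$meal))
        stop("microbes must be GF/CV and meal must be none/HFM")
    args <- list(assays = list(counts = counts), colData = cd)
    if (!is.null(rowRanges)) args$rowRanges <- rowRanges
    se <- do.call(SummarizedExperiment, args)
    new("FactorialExperiment", se)
}

#' @rdname FactorialExperiment
#' @param object,x a `FactorialExperiment`.
#' @export
setGeneric("microbes", function(x) standardGeneric("microbes"))

#' @rdname FactorialExperiment
#' @export
setGeneric("meal", function(x) standardGeneric("meal"))

#' @rdname FactorialExperiment
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname FactorialExperiment
#' @export
setMethod("microbes", "FactorialExperiment", function(x) colData(x)$microbes)

#' @rdname FactorialExperiment
#' @export
setMethod("meal", "FactorialExperiment", function(x) colData(x)$meal)

#' @rdname FactorialExperiment
#' @description `condition()` returns the four-level condition factor
#' (GF, GF+HFM, CV, CV+HFM) implied by the two design factors.
#' @export
setMethod("condition", "FactorialExperiment", function(x) {
    lab <- ifelse(microbes(x) == "CV", "CV", "GF")
    lab <- ifelse(meal(x) == "HFM", paste0(lab, "+HFM"), lab)
    factor(lab, levels = c("GF", "GF+HFM", "CV", "CV+HFM"))
})

#' @rdname FactorialExperiment
#' @export
setMethod("counts", "FactorialExperiment", function(object) {
    assay(object, "counts")
})

#' @rdname FactorialExperiment
#' @export
setMethod("sizeFactors", "FactorialExperiment", function(object) {
    colData(object)$sizeFactor
})

#' @rdname FactorialExperiment
#' @param value numeric vector of per-sample positive size factors.
#' @export
setReplaceMethod("sizeFactors", "FactorialExperiment", function(object, value) {
    stopifnot(length(value) == ncol(object), all(value > 0))
    colData(object)$sizeFactor <- as.numeric(value)
    object
})

#' @export
setMethod("show", "FactorialExperiment", function(object) {
    callNextMethod()
    n <- table(condition(object))
    cat("condition replicates:",
        paste(names(n), n, sep = "=", collapse = " "), "\n")
})

#' Model matrix of the full factorial model
#'
#' Columns: intercept, microbes (CV indicator), meal (HFM indicator), and
#' their interaction. The reduced (additive) model drops the last column.
#'
#' @param fe a `FactorialExperiment`.
#' @return numeric matrix, samples x 4.
#' @export
designMatrix <- function(fe) {
    x <- as.integer(microbes(fe) == "CV")
    y <- as.integer(meal(fe) == "HFM")
    cbind(intercept = 1, microbes = x, meal = y, interaction = x * y)
}

#' Size-factor-normalized counts
#'
#' @param fe a `FactorialExperiment` with size factors set.
#' @return matrix of counts divided by their sample size factor.
#' @export
normalizedCounts <- function(fe) {
    sf <- sizeFactors(fe)
    if (is.null(sf)) stop("size factors not set; run estimateSizeFactorsMedianRatio()")
    sweep(counts(fe), 2, sf, "/")
}
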