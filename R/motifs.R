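#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet
NULL

BASES <- c("A", "C", "G", "T")

#' Position weight matrix with log-odds threshold
#'
#' A position probability matrix (rows = positions, columns = A, C, G, T)
#' together with background base frequencies and a hit threshold in bits.
#' Probabilities get a pseudocount of `pseudocount` per cell and are
#' renormalized; the default threshold is 60% of the maximum achievable
#' log-odds score of the motif.
#'
#' @param mat numeric L x 4 matrix of base probabilities, L >= 4.
#' @param name motif name.
#' @param background length-4 background frequencies (default uniform).
#' @param threshold log-odds hit threshold in bits; `NULL` for the 60%
#'   default.
#' @param pseudocount added to every cell before renormalization.
#' @return an object of class `PWM` with slots `name`, `mat` (probabilities),
#'   `logOdds` (log2 p/bg), `background`, `threshold`.
#' @export
pwm <- function(mat, name = "motif", background = rep(0.25, 4),
                threshold = NULL, pseudocount = 0.001) {
    mat <- as.matrix(mat)
    if (ncol(mat) != 4) stop("PWM must have 4 columns (A, C, G, T)")
    if (nrow(mat) < 4) stop("PWM must have at least 4 positions")
    if (any(abs(rowSums(mat) - 1) > 1e-6))
        stop("PWM rows must sum to 1")
    stopifnot(length(background) == 4, all(background > 0))
    background <- background / sum(background)
    mat <- mat + pseudocount
    mat <- mat / rowSums(mat)
    colnames(mat) <- BASES
    lo <- log2(sweep(mat, 2, background, "/"))
    if (is.null(threshold)) threshold <- 0.6 * sum(apply(lo, 1, max))
    new("PWM", name = name, mat = mat, logOdds = lo,
        background = background, threshold = threshold)
}

#' @rdname pwm
#' @export
setClass("PWM", representation(name = "character", mat = "matrix",
                               logOdds = "matrix", background = "numeric",
                               threshold = "numeric"))

#' @export
setMethod("show", "PWM", function(object) {
    cat("PWM", object@name, ":", nrow(object@mat), "bp, threshold",
        round(object@threshold, 2), "bits, consensus",
        pwmConsensus(object), "\n")
})

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x a `PWM`.
#' @return character string of length L.
#' @export
pwmConsensus <- function(x) {
    paste(BASES[apply(x@mat, 1, which.max)], collapse = "")
}

#' Scan a sequence with a PWM on both strands
#'
#' The score of a window is the sum over positions of `log2(p_base / bg)`.
#' Windows containing `N` are skipped. The reverse strand is scanned by
#' scoring the reverse complement of the motif against the forward sequence,
#' so reported positions are always on the forward strand (1-based start of
#' the matched window).
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   A, C, G, T, N.
#' @param x a `PWM`.
#' @return `data.frame` with `position`, `strand`, `score` for every window
#'   scoring at or above the threshold; zero rows when the sequence is
#'   shorter than the motif.
#' @export
scanPWM <- function(sequence, x) {
    s <- toupper(as.character(sequence))
    chars <- strsplit(s, "")[[1]]
    L <- nrow(x@mat)
    n <- length(chars)
    empty <- data.frame(position = integer(0), strand = character(0),
                        score = numeric(0))
    if (n < L) return(empty)
    code <- match(chars, BASES)          # NA for N and friends
    nW <- n - L + 1L
    offs <- seq_len(L) - 1L
    # score matrix lookups for each strand
    fwd <- x@logOdds
    rev <- x@logOdds[L:1, 4:1, drop = FALSE]   # reverse complement motif
    scoreWith <- function(lo) {
        sc <- numeric(nW); bad <- logical(nW)
        for (k in seq_len(L)) {
            b <- code[k:(k + nW - 1L)]
            miss <- is.na(b)
            bad <- bad | miss
            b[miss] <- 1L
            sc <- sc + lo[k, b]
        }
        sc[bad] <- -Inf
        sc
    }
    scF <- scoreWith(fwd)
    scR <- scoreWith(rev)
    hitF <- which(scF >= x@threshold)
    hitR <- which(scR >= x@threshold)
    rbind(
        if (length(hitF)) data.frame(position = hitF, strand = "+",
                                     score = scF[hitF]) else empty,
        if (length(hitR)) data.frame(position = hitR, strand = "-",
                                     score = scR[hitR]) else empty)
}

#' Motif enrichment of input sequences against a background set
#'
#' Zero-or-one-occurrence-per-sequence (ZOOPS) counting: each sequence either
#' has at least one hit or none. Significance is the hypergeometric upper
#' tail of drawing the observed number of input hits when sampling
#' `length(input)` sequences from the pooled input + background collection;
#' fold enrichment is the ratio of hit rates. A binomial alternative
#' (input hits vs the background hit rate) is available via `model`.
#'
#' @param input,background named `DNAStringSet` or character vectors of
#'   sequences (deduplicated by name when names are present).
#' @param pwms list of `PWM` objects.
#' @param model `"hypergeometric"` (default) or `"binomial"`.
#' @return `DataFrame` with one row per motif: `motif`, `inputHits`,
#'   `inputN`, `backgroundHits`, `backgroundN`, `fold`, `p`, `minusLog10P`.
#' @export
enrichMotifs <- function(input, background, pwms,
                         model = c("hypergeometric", "binomial")) {
    model <- match.arg(model)
    dedup <- function(s) {
        nm <- names(s)
        s <- as.character(s)
        names(s) <- nm
        if (!is.null(names(s))) s <- s[!duplicated(names(s))]
        s
    }
    input <- dedup(input); background <- dedup(background)
    if (!length(input) || !length(background))
        stop("both sequence sets must be non-empty")
    if (inherits(pwms, "PWM")) pwms <- list(pwms)
    rows <- lapply(pwms, function(w) {
        hitI <- sum(vapply(input, function(s) nrow(scanPWM(s, w)) > 0,
                           logical(1)))
        hitB <- sum(vapply(background, function(s) nrow(scanPWM(s, w)) > 0,
                           logical(1)))
        nI <- length(input); nB <- length(background)
        K <- hitI + hitB
        p <- if (K == 0) 1 else if (model == "hypergeometric")
            stats::phyper(hitI - 1, K, nI + nB - K, nI, lower.tail = FALSE)
        else
            stats::pbinom(hitI - 1, nI, max(hitB / nB, 1e-12),
                          lower.tail = FALSE)
        rateI <- hitI / nI; rateB <- hitB / nB
        fold <- if (rateB > 0) rateI / rateB else
            if (rateI > 0) Inf else NA_real_
        DataFrame(motif = w@name, inputHits = hitI, inputN = nI,
                  backgroundHits = hitB, backgroundN = nB,
                  fold = fold, p = p, minusLog10P = -log10(max(p, 1e-300)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- out$motif
    out
}

#' Reciprocal-direction motif enrichment across the 8 directional groups
#'
#' For each pairwise contrast, the up- and down-group linked sequences are
#' tested against each other: the input is one direction's sequences and the
#' background is the reciprocal direction of the same contrast. A direction
#' pair runs only when both sides have at least `minSeqs` linked sequences;
#' otherwise the pair is skipped with a warning.
#'
#' @param groups output of [assignDirectionalGroups] for peaks/regions.
#' @param links `DataFrame` from [nearestFeature] mapping region ids
#'   (`query`) to sequence ids (`feature`), e.g. chromatin sites to their
#'   closest DNase site within 1 kb.
#' @param sequences named `DNAStringSet` (or character vector) keyed by
#'   sequence id.
#' @param pwms list of `PWM`s.
#' @param minSeqs minimum linked sequences per direction (default 5).
#' @return named list (one element per run, e.g. `"CV/GF.up"` meaning that
#'   group as input vs its reciprocal) of [enrichMotifs] tables.
#' @export
runReciprocalEnrichment <- function(groups, links, sequences, pwms,
                                    minSeqs = 5L) {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
    if (is.null(names(seqs)))
        stop("sequences must be named by sequence id")
    linked <- function(regionIds) {
        ids <- unique(links$feature[links$query %in% regionIds])
        seqs[names(seqs) %in% ids]
    }
    out <- list()
    for (cn in names(factorialContrasts())) {
        up <- rownames(groups)[as.logical(groups[[paste0(cn, ".up")]])]
        dn <- rownames(groups)[as.logical(groups[[paste0(cn, ".down")]])]
        sUp <- linked(up); sDn <- linked(dn)
        if (length(sUp) < minSeqs || length(sDn) < minSeqs) {
            warning("contrast ", cn, ": fewer than ", minSeqs,
                    " linked sequences in a direction; pair skipped")
            next
        }
        out[[paste0(cn, ".up")]] <- enrichMotifs(sUp, sDn, pwms)
        out[[paste0(cn, ".down")]] <- enrichMotifs(sDn, sUp, pwms)
    }
    out
}

#' Read and write PWMs in a simple text format
#'
#' Format: one or more motifs, each a header line `>name` followed by L rows
#' of 4 whitespace-separated base probabilities (A, C, G, T).
#'
#' @param path file path.
#' @param ... passed to [pwm] (background, threshold, pseudocount).
#' @return `readPWMFile`: named list of `PWM`s.
#' @export
readPWMFile <- function(path, ...) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    starts <- grep("^>", lines)
    if (!length(starts)) stop("no motif headers ('>name') in ", path)
    ends <- c(starts[-1] - 1L, length(lines))
    out <- list()
    for (i in seq_along(starts)) {
        nm <- sub("^>\\s*", "", lines[starts[i]])
        block <- lines[(starts[i] + 1L):ends[i]]
        mat <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
        out[[nm]] <- pwm(mat, name = nm, ...)
    }
    out
}

#' @rdname readPWMFile
#' @param pwms named list of `PWM`s to write.
#' @export
writePWMFile <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (w in pwms) {
        writeLines(paste0(">", w@name), con)
        utils::write.table(format(w@mat, digits = 6), con,
                           row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
    }
    invisible(path)
}

#' Bundled synthetic test motifs
#'
#' A small synthetic PWM set for testing: a nuclear-receptor-like direct
#' repeat (DR1-style, the spacing class the HNF4A motif belongs to), a
#' palindromic control, and a low-information control. These are constructed
#' matrices for exercising the scanner and enrichment code, not curated
#' database motifs.
#'
#' @return named list of `PWM`s.
#' @export
syntheticPWMs <- function() {
    readPWMFile(system.file("extdata", "pwms_synthetic.txt",
                            package = "FactorialSeq", mustWork = TRUE))
}
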