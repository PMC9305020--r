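# shared fixture builders and brute-force oracles

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
    library(Biostrings)
})

# FactorialExperiment with given per-condition means (GF, GF+HFM, CV, CV+HFM),
# replicate counts, and NB dispersion; exact = TRUE repeats the means as
# counts (no noise), useful for closed-form checks.
makeFE <- function(cellMeans, nPerCell = c(2L, 2L, 2L, 2L), alpha = 0,
                   nFeatures = 1L, seed = 1L, exact = FALSE) {
    stopifnot(length(cellMeans) == 4)
    set.seed(seed)
    cond <- rep(c("GF", "GF+HFM", "CV", "CV+HFM"), nPerCell)
    mu <- rep(cellMeans, nPerCell)
    k <- t(vapply(seq_len(nFeatures), function(i) {
        if (exact) mu
        else if (alpha < 1e-10) rpois(length(mu), mu)
        else rnbinom(length(mu), mu = mu, size = 1 / alpha)
    }, numeric(length(mu))))
    rownames(k) <- sprintf("f%04d", seq_len(nFeatures))
    colnames(k) <- paste0(gsub("[+/]", "", cond), "_",
                          unlist(lapply(nPerCell, seq_len)))
    FactorialExperiment(k,
        microbes = ifelse(grepl("^CV", cond), "CV", "GF"),
        meal = ifelse(grepl("HFM", cond), "HFM", "none"))
}

# derivative-free NB GLM oracle: maximize the log-likelihood over the
# coefficients with Nelder-Mead, independent of the IRLS path
oracleNBLogLik <- function(y, X, offset, alpha) {
    nll <- function(b) {
        mu <- exp(pmin(pmax(drop(offset + X %*% b), -30), 30))
        -nbLogLik(y, mu, alpha)
    }
    start <- c(log(max(mean(y), 0.5)), rep(0, ncol(X) - 1))
    fit <- optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    fit2 <- optim(fit$par, nll, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
    -fit2$value
}

# plain-list interval representation for brute-force oracles:
# data.frame(chrom, start, end) in 0-based half-open coordinates
grToDf <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = bedStart(gr), end = bedEnd(gr),
               stringsAsFactors = FALSE)
}

randomIntervalDf <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000,
                             maxLen = 300) {
    start <- sample.int(maxPos, n, replace = TRUE) - 1L
    len <- sample.int(maxLen, n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + len, stringsAsFactors = FALSE)
}

dfToGr <- function(df) bedRanges(df$chrom, df$start, df$end)

# O(n^2)-style per-bp union via coverage over a small coordinate space
bruteMerge <- function(df) {
    out <- list()
    for (chr in sort(unique(df$chrom))) {
        d <- df[df$chrom == chr, ]
        maxEnd <- max(d$end)
        cov <- logical(maxEnd)
        for (i in seq_len(nrow(d)))
            cov[(d$start[i] + 1):d$end[i]] <- TRUE
        r <- rle(cov)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths[] + 1L
        keep <- r$values
        if (any(keep))
            out[[chr]] <- data.frame(chrom = chr, start = starts[keep] - 1L,
                                     end = ends[keep])
    }
    if (!length(out)) return(data.frame(chrom = character(0),
                                        start = integer(0),
                                        end = integer(0)))
    d <- do.call(rbind, out)
    rownames(d) <- NULL
    d
}

bruteSubtract <- function(a, b) {
    out <- list()
    for (chr in sort(unique(a$chrom))) {
        da <- a[a$chrom == chr, ]
        db <- b[b$chrom == chr, ]
        maxEnd <- max(da$end, db$end, 1L)
        cov <- logical(maxEnd)
        for (i in seq_len(nrow(da))) cov[(da$start[i] + 1):da$end[i]] <- TRUE
        for (i in seq_len(nrow(db))) cov[(db$start[i] + 1):db$end[i]] <- FALSE
        r <- rle(cov)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values
        if (any(keep))
            out[[chr]] <- data.frame(chrom = chr, start = starts[keep] - 1L,
                                     end = ends[keep])
    }
    if (!length(out)) return(data.frame(chrom = character(0),
                                        start = integer(0),
                                        end = integer(0)))
    d <- do.call(rbind, out)
    rownames(d) <- NULL
    d
}

# gap in bp between 0-based half-open intervals (0 when overlapping/bookended)
bruteGap <- function(s1, e1, s2, e2) pmax(pmax(s2 - e1, s1 - e2), 0)

bruteNearest <- function(q, r, ids) {
    ord <- order(r$chrom, r$start, r$end, ids)
    vapply(seq_len(nrow(q)), function(i) {
        d <- ifelse(r$chrom == q$chrom[i],
                    bruteGap(q$start[i], q$end[i], r$start, r$end), Inf)
        best <- ord[which.min(d[ord])]   # first in sort order among minima
        c(idx = best, dist = min(d))
    }, numeric(2))
}

bruteCountOverlaps <- function(targets, frags) {
    vapply(seq_len(nrow(targets)), function(i) {
        sum(frags$chrom == targets$chrom[i] &
            frags$start < targets$end[i] &
            frags$end > targets$start[i])
    }, numeric(1))
}

# exact hypergeometric upper tail by direct term summation
bruteHyperTail <- function(k, K, N, n) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

randomSeq <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

revcompChar <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
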