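#' @importFrom GenomicRanges GRanges reduce setdiff sort seqnames start end
#'   width strand strand<- countOverlaps distanceToNearest findOverlaps mcols
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Merge interval sets
#'
#' Union of one or more interval sets with overlapping *or bookended*
#' (end == start in 0-based half-open coordinates) intervals coalesced, in
#' sorted order. Strand is ignored.
#'
#' @param ... `GRanges` objects (or a single `GRangesList`/list of them).
#' @return a sorted, disjoint `GRanges`.
#' @examples
#' a <- bedRanges("chr1", c(0, 50), c(100, 150))
#' mergeIntervals(a)        # one interval chr1:0-150
#' @export
mergeIntervals <- function(...) {
    sets <- list(...)
    if (length(sets) == 1 && (is.list(sets[[1]]) || is(sets[[1]], "GRangesList")))
        sets <- as.list(sets[[1]])
    if (!length(sets)) return(GRanges())
    all <- suppressWarnings(do.call(c, lapply(unname(sets), function(g) {
        strand(g) <- "*"
        mcols(g) <- NULL
        names(g) <- NULL
        g
    })))
    sort(reduce(all, min.gapwidth = 1L))
}

#' Subtract one interval set from another
#'
#' Base-pair set difference `a \ b`; intervals of `a` may be split. Names and
#' metadata of `a` are not propagated (the result is a new footprint).
#'
#' @param a,b `GRanges`.
#' @return sorted `GRanges` covering exactly the bases of `a` not in `b`.
#' @export
subtractIntervals <- function(a, b) {
    strand(a) <- "*"; strand(b) <- "*"
    mcols(a) <- NULL; mcols(b) <- NULL
    sort(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
}

#' Tile peaks into fixed-width sliding windows
#'
#' Each peak of length `L` is tiled with windows of `width` bp every `step`
#' bp. A peak no longer than `width` becomes a single window spanning the
#' whole peak. Otherwise full-width windows start at offsets 0, step, 2*step,
#' ... while they fit, and when the last full window stops short of the peak
#' end one extra end-anchored window `[end - width, end)` is added so the
#' peak is always fully covered.
#'
#' @param peaks `GRanges` of merged peaks; names (or `name` metadata) are
#'   used as peak ids, otherwise `peak_<i>`.
#' @param width,step window width and step in bp (defaults 300 and 200,
#'   giving 100 bp of overlap between consecutive windows).
#' @return `GRanges` of windows with metadata columns `parentPeak` and
#'   `windowIndex` and names `<peakId>:<windowIndex>`.
#' @export
tileWindows <- function(peaks, width = 300L, step = 200L) {
    if (width <= 0 || step <= 0 || step > width)
        stop("need 0 < step <= width")
    ids <- names(peaks)
    if (is.null(ids) && !is.null(peaks$name)) ids <- peaks$name
    if (is.null(ids)) ids <- sprintf("peak_%05d", seq_along(peaks))
    s0 <- bedStart(peaks)              # 0-based starts
    e0 <- bedEnd(peaks)
    out <- vector("list", length(peaks))
    for (i in seq_along(peaks)) {
        L <- e0[i] - s0[i]
        if (L <= width) {
            st <- s0[i]; en <- e0[i]
        } else {
            offs <- seq.int(0L, L - width, by = step)
            st <- s0[i] + offs
            en <- st + width
            if (en[length(en)] < e0[i]) {
                st <- c(st, e0[i] - width)
                en <- c(en, e0[i])
            }
        }
        out[[i]] <- data.frame(chrom = as.character(seqnames(peaks))[i],
                               start = st, end = en,
                               parentPeak = ids[i],
                               windowIndex = seq_along(st))
    }
    df <- do.call(rbind, out)
    gr <- bedRanges(df$chrom, df$start, df$end)
    gr$parentPeak <- df$parentPeak
    gr$windowIndex <- df$windowIndex
    names(gr) <- paste0(df$parentPeak, ":", df$windowIndex)
    gr
}

#' Count fragment overlaps per target interval
#'
#' For each sample, counts fragments overlapping each target by at least one
#' base pair. A fragment spanning several (possibly overlapping) windows
#' contributes to all of them. Fragments on chromosomes absent from the
#' targets simply count nowhere (a warning is emitted when a whole sample
#' shares no chromosome with the targets).
#'
#' @param fragments named list of `GRanges`, one per sample.
#' @param targets `GRanges` of windows or peaks.
#' @return integer matrix, targets x samples.
#' @export
countOverlapsMatrix <- function(fragments, targets) {
    stopifnot(is.list(fragments) || is(fragments, "GRangesList"))
    ids <- names(fragments)
    if (is.null(ids)) ids <- sprintf("sample_%02d", seq_along(fragments))
    targetChroms <- unique(as.character(seqnames(targets)))
    m <- vapply(seq_along(fragments), function(j) {
        fr <- fragments[[j]]
        if (length(fr) &&
            !any(unique(as.character(seqnames(fr))) %in% targetChroms))
            warning("sample ", ids[j], " shares no chromosome with targets")
        countOverlaps(targets, fr, ignore.strand = TRUE)
    }, integer(length(targets)))
    m <- matrix(m, nrow = length(targets),
                dimnames = list(names(targets), ids))
    m
}

#' Join window-level results up to their parent peaks
#'
#' A peak is significant for a contrast (and direction) when at least one of
#' its windows carries the chosen significance flag; the peak's reported
#' statistics are those of its minimum-p window (ties broken by the leftmost
#' window).
#'
#' @param windowRes a result `DataFrame` (one contrast) whose rows are
#'   windows, carrying `log2FC`, `p`, flag columns.
#' @param windows the `GRanges` from [tileWindows] aligned with `windowRes`
#'   rows (matched by name).
#' @param flag which significance flag column defines peak significance.
#' @return `DataFrame` with one row per peak: `peak`, `nWindows`,
#'   `bestWindow`, `baseMean`, `log2FC`, `SE`, `p`, `padj`, `significant`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
joinWindowsToPeaks <- function(windowRes, windows, flag = "standard") {
    ids <- rownames(windowRes)
    idx <- match(ids, names(windows))
    if (anyNA(idx)) stop("window result rows missing from window set: ",
                         paste(utils::head(ids[is.na(idx)]), collapse = ", "))
    w <- windows[idx]
    df <- data.frame(peak = w$parentPeak,
                     start = bedStart(w),
                     p = windowRes$p,
                     row = seq_len(nrow(windowRes)))
    # order so the first row per peak is the min-p (ties -> leftmost) window
    ord <- order(df$peak, ifelse(is.na(df$p), Inf, df$p), df$start)
    df <- df[ord, ]
    first <- !duplicated(df$peak)
    rep <- df[first, ]
    sig <- tapply(windowRes[[flag]][df$row], df$peak, any)
    sig <- as.logical(sig[rep$peak])
    nWin <- as.integer(table(df$peak)[rep$peak])
    r <- windowRes[rep$row, , drop = FALSE]
    out <- DataFrame(peak = rep$peak, nWindows = nWin,
                     bestWindow = ids[rep$row],
                     baseMean = r$baseMean, log2FC = r$log2FC, SE = r$SE,
                     p = r$p,
                     padj = if ("padj" %in% colnames(r)) r$padj else NA_real_,
                     significant = sig & !is.na(sig),
                     row.names = rep$peak)
    out$direction <- ifelse(!out$significant, "ns",
                            ifelse(out$log2FC > 0, "up",
                                   ifelse(out$log2FC < 0, "down", "ns")))
    metadata(out) <- metadata(windowRes)
    out[order(rownames(out)), ]
}

#' Nearest reference feature for each query interval
#'
#' Minimum genomic gap in bp (0 for overlapping or bookended intervals),
#' ignoring strand. Ties are broken by the first reference feature in
#' (chrom, start, end, name) sort order. When `maxDist` is set, assignments
#' farther than `maxDist` are dropped.
#'
#' @param query,reference `GRanges`; reference must be non-empty and should
#'   carry names (or a `name` column) for reporting.
#' @param maxDist optional maximum distance in bp (e.g. 1000 for linking
#'   chromatin sites to DNase hypersensitive sites).
#' @return `DataFrame` with `queryIndex`, `query`, `feature` (reference id),
#'   `distance`.
#' @export
nearestFeature <- function(query, reference, maxDist = NULL) {
    if (!length(reference)) stop("reference is empty")
    refIds <- names(reference)
    if (is.null(refIds) && !is.null(reference$name)) refIds <- reference$name
    if (is.null(refIds)) refIds <- sprintf("ref_%05d", seq_along(reference))
    # canonical tie-break order: (chrom, start, end, name)
    ord <- order(as.character(seqnames(reference)), start(reference),
                 end(reference), refIds)
    qChr <- as.character(seqnames(query))
    rChr <- as.character(seqnames(reference))[ord]
    rS <- bedStart(reference)[ord]; rE <- bedEnd(reference)[ord]
    qS <- bedStart(query); qE <- bedEnd(query)
    qh <- integer(0); sh <- integer(0); d <- integer(0)
    for (chr in unique(qChr)) {
        qi <- which(qChr == chr)
        ri <- which(rChr == chr)
        if (!length(ri)) next
        # block-wise gap matrix keeps memory bounded on large inputs
        for (blk in split(qi, ceiling(seq_along(qi) / 512))) {
            gap <- pmax(outer(qS[blk], rE[ri], "-"),
                        outer(-qE[blk], rS[ri], "+"))
            gap[gap < 0] <- 0
            # first column among the row minima = lowest tie-break rank
            best <- max.col(-gap, ties.method = "first")
            qh <- c(qh, blk)
            sh <- c(sh, ord[ri[best]])
            d <- c(d, gap[cbind(seq_along(blk), best)])
        }
    }
    o <- order(qh)
    qh <- qh[o]; sh <- sh[o]; d <- d[o]
    if (!is.null(maxDist)) {
        ok <- d <= maxDist
        qh <- qh[ok]; sh <- sh[ok]; d <- d[ok]
    }
    qIds <- names(query)
    if (is.null(qIds)) qIds <- sprintf("query_%05d", seq_along(query))
    DataFrame(queryIndex = qh, query = qIds[qh], feature = refIds[sh],
              distance = as.integer(d))
}

#' Count binding sites assigned to each gene
#'
#' Every site is assigned to its nearest gene (gene body, no distance cap,
#' ties to the first gene in sort order) and the sites per gene are summed;
#' genes with no site get 0.
#'
#' @param sites `GRanges` of binding sites.
#' @param genes `GRanges` of genes with names.
#' @return named integer vector over all genes.
#' @export
countSitesPerGene <- function(sites, genes) {
    ids <- names(genes)
    if (is.null(ids) && !is.null(genes$name)) ids <- genes$name
    if (is.null(ids)) ids <- sprintf("gene_%05d", seq_along(genes))
    out <- setNames(integer(length(genes)), ids)
    if (length(sites)) {
        nf <- nearestFeature(sites, genes)
        tab <- table(nf$feature)
        out[names(tab)] <- as.integer(tab)
    }
    out
}

#' Bin genes by neighboring binding-site count
#'
#' Default bins follow the convention of flagging genes with more than 10
#' neighboring sites: `0`, `1-4`, `5-10`, `>10`.
#'
#' @param counts named integer vector from [countSitesPerGene].
#' @param breaks increasing integer vector of inclusive upper bin edges
#'   (default `c(0, 4, 10)`); counts above the last edge go to `">last"`.
#' @return factor of bin labels, one per gene.
#' @export
binGenesBySiteCount <- function(counts, breaks = c(0L, 4L, 10L)) {
    if (is.unsorted(breaks, strictly = TRUE))
        stop("breaks must be strictly increasing")
    # label construction: first bin covers [0, breaks[1]]
    lab <- vapply(seq_along(breaks), function(i) {
        lower <- if (i == 1) 0L else breaks[i - 1L] + 1L
        if (lower == breaks[i]) as.character(breaks[i])
        else paste0(lower, "-", breaks[i])
    }, character(1))
    lab <- c(lab, paste0(">", breaks[length(breaks)]))
    idx <- findInterval(counts, breaks + 1L) + 1L
    factor(lab[idx], levels = lab)
}

#' Build a GRanges from 0-based half-open (BED) coordinates
#'
#' @param chrom chromosome names.
#' @param start0,end0 0-based half-open start and end.
#' @param strand,name optional per-interval strand and names.
#' @return `GRanges` (internally 1-based closed, as usual in Bioconductor).
#' @export
bedRanges <- function(chrom, start0, end0, strand = "*", name = NULL) {
    stopifnot(all(start0 >= 0), all(end0 > start0))
    gr <- GRanges(factor(as.character(chrom),
                         levels = sort(unique(as.character(chrom)))),
                  IRanges(start0 + 1L, end0), strand = strand)
    if (!is.null(name)) names(gr) <- name
    gr
}

#' 0-based half-open coordinates of a GRanges
#' @param gr a `GRanges`.
#' @return integer vector of BED starts (`bedStart`) or ends (`bedEnd`).
#' @export
bedStart <- function(gr) start(gr) - 1L

#' @rdname bedStart
#' @export
bedEnd <- function(gr) end(gr)
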