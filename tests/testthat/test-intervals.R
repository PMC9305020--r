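test_that("merge coalesces overlapping and bookended intervals", {
    a <- bedRanges("chr1", c(0, 50), c(100, 150))
    m <- mergeIntervals(a)
    expect_equal(grToDf(m), data.frame(chrom = "chr1", start = 0, end = 150))
    b <- bedRanges("chr1", c(0, 100), c(100, 200))
    expect_equal(grToDf(mergeIntervals(b)),
                 data.frame(chrom = "chr1", start = 0, end = 200))
    expect_length(mergeIntervals(GRanges()), 0)
})

test_that("merge equals the brute-force union and is idempotent", {
    set.seed(21)
    for (rep in 1:10) {
        df <- randomIntervalDf(1000)
        m <- mergeIntervals(dfToGr(df))
        expect_equal(grToDf(m), bruteMerge(df))
        expect_equal(grToDf(mergeIntervals(m)), grToDf(m))
    }
})

test_that("subtraction splits intervals and conserves base pairs", {
    a <- bedRanges("chr1", 0, 300)
    b <- bedRanges("chr1", 100, 200)
    expect_equal(grToDf(subtractIntervals(a, b)),
                 data.frame(chrom = "chr1", start = c(0, 200),
                            end = c(100, 300)))
    expect_equal(grToDf(subtractIntervals(a, GRanges())), grToDf(a))
})

test_that("subtraction matches brute force on random instances", {
    set.seed(22)
    for (rep in 1:10) {
        a <- randomIntervalDf(400)
        b <- randomIntervalDf(200)
        got <- grToDf(subtractIntervals(dfToGr(a), dfToGr(b)))
        want <- bruteSubtract(a, b)
        expect_equal(got, want)
        # bp conservation: bp(a \ b) = bp(merged a) - bp(merged a  n  b)
        bpA <- sum(bruteMerge(a)$end - bruteMerge(a)$start)
        bpGot <- sum(got$end - got$start)
        inter <- bruteSubtract(a, bruteSubtract(a, b))
        expect_equal(bpGot, bpA - sum(inter$end - inter$start))
    }
})

test_that("window tiling follows the stated rule", {
    # peak of exactly the window width: one window
    w1 <- tileWindows(bedRanges("chr1", 0, 300), 300, 200)
    expect_length(w1, 1)
    expect_equal(c(bedStart(w1), bedEnd(w1)), c(0, 300))
    # shorter than width: one whole-peak window
    w2 <- tileWindows(bedRanges("chr1", 1000, 1120), 300, 200)
    expect_equal(c(bedStart(w2), bedEnd(w2)), c(1000, 1120))
    # 1000 bp: offsets 0, 200, 400, 600 plus end-anchored [700, 1000)
    w3 <- tileWindows(bedRanges("chr1", 0, 1000), 300, 200)
    expect_length(w3, 5)
    expect_equal(bedStart(w3), c(0, 200, 400, 600, 700))
    expect_equal(bedEnd(w3), c(300, 500, 700, 900, 1000))
    expect_error(tileWindows(bedRanges("chr1", 0, 500), 300, 0))
    expect_error(tileWindows(bedRanges("chr1", 0, 500), 100, 200))
})

test_that("windows exactly cover their parent peaks", {
    set.seed(23)
    starts <- cumsum(sample(500:2000, 30))
    lens <- sample(150:2000, 30)
    peaks <- bedRanges("chr1", starts, starts + lens)
    names(peaks) <- sprintf("p%02d", 1:30)
    w <- tileWindows(peaks)
    for (i in seq_along(peaks)) {
        wi <- w[w$parentPeak == names(peaks)[i]]
        expect_true(all(bedStart(wi) >= bedStart(peaks[i])))
        expect_true(all(bedEnd(wi) <= bedEnd(peaks[i])))
        cov <- grToDf(mergeIntervals(wi))
        expect_equal(cov, grToDf(peaks[i]))
    }
})

test_that("overlap counting uses the any-overlap rule", {
    targets <- bedRanges("chr1", c(0, 200), c(300, 500))
    frags <- list(s1 = bedRanges("chr1", 250, 350))
    m <- countOverlapsMatrix(frags, targets)
    expect_equal(unname(m[, 1]), c(1, 1))
    expect_equal(unname(countOverlapsMatrix(list(s1 = GRanges()),
                                            targets)[, 1]), c(0, 0))
    expect_warning(countOverlapsMatrix(
        list(s1 = bedRanges("chrX", 0, 100)), targets), "no chromosome")
})

test_that("overlap counts match all-pairs brute force", {
    set.seed(24)
    for (rep in 1:5) {
        t <- randomIntervalDf(300)
        f <- randomIntervalDf(500)
        m <- countOverlapsMatrix(list(s = dfToGr(f)), dfToGr(t))
        expect_equal(unname(m[, 1]), bruteCountOverlaps(t, f))
    }
})

test_that("window-to-peak joining takes the minimum-p window", {
    peaks <- bedRanges("chr1", c(0, 2000), c(1000, 2600))
    names(peaks) <- c("pkA", "pkB")
    w <- tileWindows(peaks)
    pv <- rep(0.5, length(w))
    pv[seq_len(5)] <- c(0.2, 0.001, 0.9, 0.5, 0.5)   # pkA windows
    res <- S4Vectors::DataFrame(
        baseMean = rep(50, length(w)), log2FC = 1, SE = 0.2, stat = 1,
        p = pv, row.names = names(w))
    res$standard <- res$p < 0.05
    joined <- joinWindowsToPeaks(res, w)
    expect_true(joined["pkA", "significant"])
    expect_equal(joined["pkA", "p"], 0.001)
    expect_equal(joined["pkA", "bestWindow"], "pkA:2")
    expect_false(joined["pkB", "significant"])
    expect_equal(joined["pkA", "direction"], "up")
    # ties go to the leftmost window
    res2 <- res
    res2$p <- rep(0.5, length(w))
    j2 <- joinWindowsToPeaks(res2, w)
    expect_equal(j2["pkA", "bestWindow"], "pkA:1")
    # orphan windows are an error
    resBad <- res
    rownames(resBad)[1] <- "nope:1"
    expect_error(joinWindowsToPeaks(resBad, w), "missing")
})

test_that("joining agrees with an exhaustive per-peak scan", {
    set.seed(25)
    starts <- cumsum(sample(500:1500, 40))
    peaks <- bedRanges("chr1", starts, starts + sample(200:1500, 40))
    names(peaks) <- sprintf("p%02d", 1:40)
    w <- tileWindows(peaks)
    res <- S4Vectors::DataFrame(
        baseMean = runif(length(w), 0, 100),
        log2FC = rnorm(length(w)), SE = 0.3, stat = 0,
        p = runif(length(w)), row.names = names(w))
    res$standard <- runif(length(w)) < 0.2
    joined <- joinWindowsToPeaks(res, w)
    for (pk in names(peaks)) {
        rows <- which(w$parentPeak == pk)
        expect_equal(joined[pk, "significant"], any(res$standard[rows]))
        expect_equal(joined[pk, "p"], min(res$p[rows]))
    }
})

test_that("nearest feature handles containment, ties, and distance caps", {
    genes <- bedRanges("chr1", c(1000, 3000), c(2000, 4000),
                       name = c("gA", "gB"))
    names(genes) <- c("gA", "gB")
    inside <- bedRanges("chr1", 1500, 1600)
    nf <- nearestFeature(inside, genes)
    expect_equal(nf$feature, "gA")
    expect_equal(nf$distance, 0L)
    # query exactly between the two genes: 400 bp to each; first in sort
    mid <- bedRanges("chr1", 2400, 2600)
    expect_equal(nearestFeature(mid, genes)$feature, "gA")
    # distance cap drops far assignments
    far <- bedRanges("chr1", 9000, 9100)
    expect_equal(nrow(nearestFeature(far, genes, maxDist = 1000)), 0)
    expect_error(nearestFeature(inside, GRanges()), "empty")
})

test_that("nearest feature matches the brute-force scan", {
    set.seed(26)
    for (rep in 1:8) {
        q <- randomIntervalDf(150)
        r <- randomIntervalDf(60)
        ids <- sprintf("r%03d", seq_len(nrow(r)))
        gr <- dfToGr(r); names(gr) <- ids
        nf <- nearestFeature(dfToGr(q), gr)
        brute <- bruteNearest(q, r, ids)
        finite <- is.finite(brute["dist", ])
        expect_equal(nf$queryIndex, which(finite))
        expect_equal(nf$feature, ids[brute["idx", finite]])
        expect_equal(nf$distance, as.integer(brute["dist", finite]))
    }
})

test_that("sites-per-gene counting conserves the number of sites", {
    set.seed(27)
    starts <- cumsum(sample(3000:8000, 20))
    genes <- bedRanges("chr1", starts, starts + 2000)
    names(genes) <- sprintf("g%02d", 1:20)
    sdf <- randomIntervalDf(200, chroms = "chr1",
                            maxPos = max(starts) + 3000, maxLen = 50)
    counts <- countSitesPerGene(dfToGr(sdf), genes)
    expect_equal(sum(counts), 200)
    expect_equal(unname(countSitesPerGene(GRanges(), genes)),
                 rep(0L, 20))
})

test_that("site-count bins use the stated edges", {
    counts <- c(g1 = 0L, g2 = 3L, g3 = 5L, g4 = 10L, g5 = 11L, g6 = 40L)
    bins <- binGenesBySiteCount(counts)
    expect_equal(as.character(bins),
                 c("0", "1-4", "5-10", "5-10", ">10", ">10"))
    expect_error(binGenesBySiteCount(counts, breaks = c(4, 4, 10)),
                 "increasing")
})
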