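test_that("the generator is deterministic for a fixed configuration", {
    cfg <- simConfig(nGenes = 40, nPeaks = 30, seed = 7)
    s1 <- simulateFactorialData(cfg)
    s2 <- simulateFactorialData(cfg)
    expect_identical(counts(s1$rna), counts(s2$rna))
    expect_identical(counts(s1$h3k27ac), counts(s2$h3k27ac))
    expect_identical(grToDf(s1$annotation$genes),
                     grToDf(s2$annotation$genes))
    expect_identical(as.character(s1$sequences),
                     as.character(s2$sequences))
    s3 <- simulateFactorialData(simConfig(nGenes = 40, nPeaks = 30,
                                          seed = 8))
    expect_false(identical(counts(s1$rna), counts(s3$rna)))
})

test_that("empty gene sets are allowed while peaks still generate", {
    cfg <- simConfig(nGenes = 0, nPeaks = 25, seed = 7)
    ann <- simulateAnnotation(cfg)
    expect_length(ann$genes, 0)
    expect_length(ann$peaks, 25)
    expect_true(all(width(ann$peaks) >= 200))
})

test_that("undersized chromosomes raise an explicit sizing error", {
    cfg <- simConfig(nGenes = 50, nPeaks = 0, seed = 1,
                     chromLengths = c(chrTiny = 20000))
    expect_error(simulateAnnotation(cfg), "too small")
})

test_that("config invariants are enforced", {
    expect_error(simConfig(effectFractions = c(null = 0.5, microbe = 0.1,
                                               meal = 0.1, additive = 0.1,
                                               interactionPos = 0.1,
                                               interactionNeg = 0.2)),
                 "sum to 1")
    expect_error(simConfig(replicates = c(GF = 4L, CV = 4L)), "conditions")
})

test_that("genes do not overlap and binding-site truth is re-countable", {
    cfg <- simConfig(nGenes = 60, nPeaks = 0, seed = 9)
    ann <- simulateAnnotation(cfg)
    g <- ann$genes
    expect_length(reduce(g, ignore.strand = TRUE), length(g))
    ov <- findOverlaps(g, g, ignore.strand = TRUE)
    expect_equal(length(ov), length(g))    # only self-overlaps
    # independent recount of sites per gene equals the stored truth
    recount <- countSitesPerGene(ann$sites, g)
    expect_equal(unname(recount), ann$truth$genes$sitesPerGene)
    high <- ann$truth$genes$sitesPerGene > 10
    expect_equal(sum(high), round(0.1 * 60))
})

test_that("simulated counts have the configured mean", {
    cfg <- simConfig(seed = 10, librarySizeRange = c(1, 1))
    truth <- data.frame(betaM = 0, betaF = 0, betaI = 0,
                        q = rep(50, 1000), alpha = 1e-8)
    fe <- simulateCounts(truth, c("GF" = 4L, "GF+HFM" = 4L, "CV" = 4L,
                                  "CV+HFM" = 4L), cfg)
    m <- mean(counts(fe))
    se <- sqrt(50 / length(counts(fe)))
    expect_lt(abs(m - 50), 3 * se)
})

test_that("a planted interaction of 2 gives a mean ratio-of-ratios near 4", {
    cfg <- simConfig(seed = 11, librarySizeRange = c(1, 1))
    truth <- data.frame(betaM = 0, betaF = 0, betaI = 2,
                        q = rep(500, 500), alpha = 1e-3)
    fe <- simulateCounts(truth, c("GF" = 4L, "GF+HFM" = 4L, "CV" = 4L,
                                  "CV+HFM" = 4L), cfg)
    cond <- condition(fe)
    cellMean <- vapply(levels(cond), function(cl)
        rowMeans(counts(fe)[, cond == cl, drop = FALSE]),
        numeric(nrow(fe)))
    rr <- (cellMean[, "CV+HFM"] / cellMean[, "CV"]) /
        (cellMean[, "GF+HFM"] / cellMean[, "GF"])
    expect_lt(abs(mean(rr) - 4), 0.2)
})

test_that("class labels re-derive exactly from the planted coefficients", {
    cfg <- simConfig(nGenes = 300, nPeaks = 200, seed = 12,
                     chromLengths = c(chr1 = 4e6, chr2 = 3e6))
    ann <- simulateAnnotation(cfg)
    for (tab in ann$truth) {
        derived <- effectClassFromBetas(tab$betaM, tab$betaF, tab$betaI)
        expect_equal(derived, tab$class)
    }
})

test_that("sequence planting follows the designated regions", {
    cfg <- simConfig(seed = 13, motifPlantRate = 0)
    pwms <- syntheticPWMs()
    regions <- bedRanges("chr1", (0:19) * 1000, (0:19) * 1000 + 200)
    names(regions) <- sprintf("r%02d", 1:20)
    sq <- simulateSequences(regions, pwms, cfg)
    expect_true(all(is.na(sq$planted$motif)))
    # forced planting in a region exactly the motif length
    w <- pwms[[1]]
    L <- nrow(w@mat)
    tiny <- bedRanges("chr1", 0, L); names(tiny) <- "t1"
    sq2 <- simulateSequences(tiny, pwms, cfg, plant = names(pwms)[1])
    s <- as.character(sq2$sequences[[1]])
    expect_true(s %in% c(pwmConsensus(w), revcompChar(pwmConsensus(w))))
    # motif longer than region errors
    small <- bedRanges("chr1", 0, L - 1); names(small) <- "t2"
    expect_error(simulateSequences(small, pwms, cfg,
                                   plant = names(pwms)[1]), "longer")
})

test_that("background base composition matches the GC parameter", {
    cfg <- simConfig(seed = 14, gcContent = 0.5, motifPlantRate = 0)
    regions <- bedRanges("chr1", (0:9) * 20000, (0:9) * 20000 + 10000)
    names(regions) <- sprintf("r%02d", 1:10)
    sq <- simulateSequences(regions, list(), cfg)
    s <- paste(as.character(sq$sequences), collapse = "")
    gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    expect_gte(gc, 0.49)
    expect_lte(gc, 0.51)
})

test_that("fixtures round-trip through the readers", {
    cfg <- simConfig(nGenes = 25, nPeaks = 20, seed = 15)
    sim <- simulateFactorialData(cfg)
    dir <- tempfile()
    writeFixtures(sim, dir)
    k <- readCountMatrix(file.path(dir, "rna_counts.tsv"))
    expect_equal(k, counts(sim$rna))
    fe <- readFactorialExperiment(file.path(dir, "rna_counts.tsv"),
                                  file.path(dir, "rna_samples.tsv"))
    expect_equal(counts(fe), counts(sim$rna))
    expect_equal(as.character(condition(fe)),
                 as.character(condition(sim$rna)))
    genes <- readBEDFile(file.path(dir, "genes.bed"))
    expect_equal(grToDf(genes), grToDf(sim$annotation$genes))
    expect_equal(names(genes), names(sim$annotation$genes))
    expect_equal(as.character(strand(genes)),
                 as.character(strand(sim$annotation$genes)))
    sq <- readDNAStringSet(file.path(dir, "dhs_sequences.fa"))
    expect_equal(as.character(sq), as.character(sim$sequences))
})

test_that("BED writing uses 0-based half-open coordinates", {
    gr <- bedRanges("chr1", 100, 400, name = "x")
    tmp <- tempfile(fileext = ".bed")
    writeBEDFile(gr, tmp)
    line <- strsplit(readLines(tmp)[1], "\t")[[1]]
    expect_equal(line[1:3], c("chr1", "100", "400"))
    # count matrix shape: 3 features x 4 samples -> 3 data rows, 5 columns
    m <- matrix(1:12, 3, 4, dimnames = list(paste0("f", 1:3),
                                            paste0("s", 1:4)))
    tmp2 <- tempfile(fileext = ".tsv")
    writeCountMatrix(m, tmp2)
    lines <- readLines(tmp2)
    expect_length(lines, 4)
    expect_length(strsplit(lines[1], "\t")[[1]], 5)
})
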