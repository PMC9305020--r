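makeContrastResults <- function(lfc, sig) {
    # lfc/sig: matrices features x 4 contrasts
    cn <- names(factorialContrasts())
    out <- lapply(seq_along(cn), function(j) {
        r <- S4Vectors::DataFrame(
            baseMean = rep(100, nrow(lfc)), log2FC = lfc[, j], SE = 0.1,
            stat = 0, p = ifelse(sig[, j], 1e-4, 0.8),
            row.names = rownames(lfc))
        r$padj <- r$p
        r$standard <- sig[, j]
        r
    })
    names(out) <- cn
    out
}

test_that("directional groups assign one group per flagged contrast", {
    lfc <- matrix(0, 3, 4, dimnames = list(paste0("f", 1:3), NULL))
    sig <- matrix(FALSE, 3, 4)
    lfc[1, 1] <- 1.2; sig[1, 1] <- TRUE        # CV/GF up only
    lfc[2, 3] <- -2; sig[2, 3] <- TRUE         # GF+HFM/GF down only
    res <- makeContrastResults(lfc, sig)
    g <- assignDirectionalGroups(res)
    memb <- as.matrix(as.data.frame(g[, FactorialSeq:::groupColumns()]))
    expect_equal(unname(rowSums(memb)), c(1, 1, 0))
    expect_true(g[1, "CV/GF.up"])
    expect_true(g[2, "GF+HFM/GF.down"])
})

test_that("flagged features with zero fold change are dropped with warning", {
    lfc <- matrix(0, 1, 4, dimnames = list("f1", NULL))
    sig <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4)
    expect_warning(g <- assignDirectionalGroups(makeContrastResults(lfc, sig)),
                   "cannot be oriented")
    expect_equal(unname(g[1, "direction.CV/GF"]), "ns")
})

test_that("missing contrasts are an error", {
    lfc <- matrix(1, 2, 4, dimnames = list(c("a", "b"), NULL))
    sig <- matrix(TRUE, 2, 4)
    res <- makeContrastResults(lfc, sig)
    expect_error(assignDirectionalGroups(res[1:3]), "missing contrast")
})

test_that("strong planted microbe effects land in the correct groups", {
    set.seed(31)
    fe <- makeFE(c(100, 100, 800, 800), nPerCell = c(4L, 4L, 4L, 4L),
                 alpha = 0.02, nFeatures = 100, seed = 31)
    sizeFactors(fe) <- rep(1, ncol(fe))
    res <- factorialResults(fe)
    g <- assignDirectionalGroups(res)
    okUp <- mean(g[["CV/GF.up"]] & g[["CV+HFM/GF+HFM.up"]])
    expect_gte(okUp, 0.95)
    expect_equal(sum(g[["GF+HFM/GF.up"]] | g[["GF+HFM/GF.down"]]), 0)
})

test_that("overlap matrix matches brute-force set intersection", {
    set.seed(32)
    n <- 300
    lfc <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(sprintf("f%03d", 1:n), NULL))
    sig <- matrix(runif(n * 4) < 0.3, n, 4)
    g <- assignDirectionalGroups(makeContrastResults(lfc, sig))
    ov <- overlapMatrix(g)
    gc <- FactorialSeq:::groupColumns()
    for (i in seq_along(gc)) for (j in seq_along(gc)) {
        a <- which(as.logical(g[[gc[i]]]))
        b <- which(as.logical(g[[gc[j]]]))
        expect_equal(unname(ov$counts[i, j]), length(intersect(a, b)))
    }
    expect_true(isSymmetric(unname(ov$counts)))
    nonEmpty <- ov$sizes > 0
    expect_true(all(diag(ov$normalized)[nonEmpty] == 1))
})

test_that("identical and disjoint groups normalize to 1 and 0", {
    lfc <- matrix(1, 4, 4, dimnames = list(paste0("f", 1:4), NULL))
    sig <- cbind(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE),
                 c(FALSE, FALSE, TRUE, TRUE), c(FALSE, FALSE, FALSE, FALSE))
    g <- assignDirectionalGroups(makeContrastResults(lfc, sig))
    ov <- overlapMatrix(g)
    expect_equal(unname(ov$normalized["CV/GF.up", "CV+HFM/GF+HFM.up"]), 1)
    expect_equal(unname(ov$normalized["CV/GF.up", "GF+HFM/GF.up"]), 0)
    expect_equal(unname(ov$normalized["CV/GF.down", "CV/GF.down"]), 0)
    expect_true("CV/GF.down" %in% ov$emptyGroups)
})

test_that("integration classes follow their definitions", {
    lfc <- rbind(allUp = c(1, 1, 1, 1),
                 blue  = c(0, -1, 1, 0),
                 none  = c(0, 0, 0, 0))
    sig <- rbind(allUp = rep(TRUE, 4),
                 blue  = c(FALSE, TRUE, TRUE, FALSE),
                 none  = rep(FALSE, 4))
    g <- assignDirectionalGroups(makeContrastResults(lfc, sig))
    cls <- classifyIntegration(g)
    expect_equal(as.character(cls["allUp", "class"]), "red")
    expect_equal(as.character(cls["blue", "class"]), "blue")
    expect_equal(as.character(cls["none", "class"]), "none")
    expect_true(all(cls$dualResponsive[cls$class %in% c("red", "blue")]))
})

test_that("red and blue are disjoint for arbitrary group patterns", {
    set.seed(33)
    for (rep in 1:20) {
        n <- 200
        lfc <- matrix(rnorm(n * 4), n, 4,
                      dimnames = list(sprintf("f%03d", 1:n), NULL))
        sig <- matrix(runif(n * 4) < 0.4, n, 4)
        g <- assignDirectionalGroups(makeContrastResults(lfc, sig))
        cls <- classifyIntegration(g)
        expect_equal(sum(cls$class == "red" & cls$class == "blue"), 0)
        reds <- cls$class == "red"; blues <- cls$class == "blue"
        expect_equal(sum(reds & blues), 0)
        expect_true(all(cls$dualResponsive[reds | blues]))
    }
})

test_that("accessibility classes form a partition matching definitions", {
    regions <- bedRanges("chr1", c(0, 100, 200, 300, 400) * 10,
                         c(50, 150, 250, 350, 450) * 10)
    names(regions) <- paste0("r", 1:5)
    acc <- list(
        ISC        = regions[c(1, 3)],
        TA         = regions[c(1, 3)],
        EEC        = regions[1],
        enterocyte = regions[c(1, 2)])
    acc$ISC <- c(acc$ISC)
    cls <- classifyAccessibility(regions, acc)
    expect_equal(as.character(cls$label),
                 c("pan-accessible", "enterocyte-specific", "ISC-restricted",
                   "other", "other"))
    expect_equal(sum(table(cls$label)), length(regions))
})

test_that("simulated accessibility labels are recovered exactly", {
    cfg <- simConfig(nGenes = 0, nPeaks = 150, seed = 34)
    ann <- simulateAnnotation(cfg)
    cls <- classifyAccessibility(ann$peaks, ann$accessibility)
    expect_equal(as.character(cls$label), ann$truth$peaks$accessibility)
})

test_that("moving mean matches a brute-force windowed mean", {
    expect_equal(movingMean(rep(3, 1000), 500), rep(3, 1000))
    set.seed(35)
    x <- rnorm(700)
    x[sample(700, 50)] <- NA
    got <- movingMean(x, 101)
    brute <- vapply(seq_along(x), function(i) {
        lo <- max(i - 50, 1); hi <- min(lo + 100, length(x))
        lo <- max(hi - 100, 1)
        mean(x[lo:hi], na.rm = TRUE)
    }, numeric(1))
    expect_equal(got, brute)
    # series shorter than the window: every output is the overall mean
    y <- c(1, 2, 3, 6)
    expect_equal(movingMean(y, 500), rep(3, 4))
    expect_true(is.na(movingMean(c(NA, NA), 500)[1]))
})

test_that("KS association test matches enumeration on the tiny case", {
    same <- associateDistributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(same$D, 0)
    # A={1,2}, B={3,4}: D=1; exact p = 2 / choose(4,2) = 1/3 by enumeration
    suppressWarnings(r <- associateDistributions(c(1, 2, 3), c(4, 5, 6)))
    expect_equal(r$D, 1)
    combs <- combn(6, 3)
    vals <- 1:6
    Ds <- apply(combs, 2, function(idx)
        suppressWarnings(stats::ks.test(vals[idx], vals[-idx])$statistic))
    pBrute <- mean(Ds >= 1)
    expect_equal(r$p, pBrute, tolerance = 1e-10)
    expect_warning(associateDistributions(c(1, 2), c(3, 4)), "fewer than 3")
})

test_that("compartment summaries are deterministic and ordered", {
    comp <- rep(c("crypt", "V1", "V2", "V3", "V4"), each = 10)
    z <- compartmentSummary(rep(0, 50), comp)
    expect_equal(z$mean, rep(0, 5))
    expect_equal(as.character(z$compartment),
                 c("crypt", "V1", "V2", "V3", "V4"))
    # planted gradient from crypt (+1) to villus tip (-1)
    grad <- rep(seq(1, -1, length.out = 5), each = 10)
    g <- compartmentSummary(grad, comp)
    expect_true(all(diff(g$mean) < 0))
    single <- compartmentSummary(c(1, 2), c("V2", "V2"))
    expect_equal(single$n, c(0L, 0L, 2L, 0L, 0L))
    expect_true(all(is.na(single$mean[-3])))
})
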