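#' Configuration for the synthetic factorial data generator
#'
#' Defines the simulated study: a small genome, gene and peak annotations,
#' a 2x2 factorial negative binomial count model with planted microbe, meal,
#' and interaction effects, binding sites clustered near a subset of genes,
#' per-cell-type accessibility labels, and region sequences with planted
#' motifs.
#'
#' The count model for feature i in sample j is
#' `mu_ij = s_j * q_i * 2^(bm*x_j + bf*y_j + bi*x_j*y_j)` with
#' `x_j = 1` for colonized (CV) samples and `y_j = 1` for high-fat-meal
#' samples, and counts are drawn from NB(mean = mu, variance =
#' mu + alpha_i * mu^2). The interaction coefficient `bi` is the log2 ratio
#' of the meal response with microbes to the meal response without,
#' (CV+HFM/CV)/(GF+HFM/GF) on the log2 scale.
#'
#' Effect classes and their planted coefficients (magnitude `e` drawn from a
#' positive normal with the configured mean and sd, sign random where noted):
#' \describe{
#'   \item{null}{all coefficients 0}
#'   \item{microbe}{`bm = ±e`}
#'   \item{meal}{`bf = ±e`}
#'   \item{additive}{`bm = ±e`, `bf = ±e`, `bi = 0`}
#'   \item{interactionPos}{`bi = +e` only: elevated only in CV+HFM, the
#'     pattern recovered as a "red" integration class}
#'   \item{interactionNeg}{`bf = +e`, `bi = -e`: elevated only in GF+HFM,
#'     the pattern recovered as "blue"}
#' }
#'
#' @param seed integer seed; every stage derives its own sub-seed from it.
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param nGenes,nPeaks number of genes and merged peaks.
#' @param replicates named integer vector of replicates for the conditions
#'   `GF`, `GF+HFM`, `CV`, `CV+HFM` (default the 4/4/4/4 RNA layout; see
#'   [replicateLayouts] for the unbalanced ChIP layouts).
#' @param effectFractions named fractions per effect class (must sum to 1).
#' @param effectSize `c(mean, sd)` of the log2 effect magnitude.
#' @param baseMeanLogRange range of `log(q_i)` (log-uniform base means).
#' @param dispersionParams `c(a0, a1)` of the trend `alpha(q) = a0 + a1/q`.
#' @param librarySizeRange multiplicative range for the size factors `s_j`.
#' @param motifPlantRate fraction of designated region sequences receiving a
#'   planted motif consensus.
#' @param gcContent background GC fraction for simulated sequences.
#' @param highBindingFraction fraction of genes given >10 binding sites.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      chromLengths = c(chr1 = 4e6, chr2 = 3e6),
                      nGenes = 400L, nPeaks = 300L,
                      replicates = c("GF" = 4L, "GF+HFM" = 4L,
                                     "CV" = 4L, "CV+HFM" = 4L),
                      effectFractions = c(null = 0.55, microbe = 0.10,
                                          meal = 0.10, additive = 0.10,
                                          interactionPos = 0.075,
                                          interactionNeg = 0.075),
                      effectSize = c(mean = 2, sd = 0.5),
                      baseMeanLogRange = log(c(20, 2000)),
                      dispersionParams = c(a0 = 0.05, a1 = 2),
                      librarySizeRange = c(0.7, 1.4),
                      motifPlantRate = 0.5,
                      gcContent = 0.42,
                      highBindingFraction = 0.1) {
    cfg <- list(seed = as.integer(seed), chromLengths = chromLengths,
                nGenes = as.integer(nGenes), nPeaks = as.integer(nPeaks),
                replicates = replicates,
                effectFractions = effectFractions,
                effectSize = effectSize,
                baseMeanLogRange = baseMeanLogRange,
                dispersionParams = dispersionParams,
                librarySizeRange = librarySizeRange,
                motifPlantRate = motifPlantRate,
                gcContent = gcContent,
                highBindingFraction = highBindingFraction)
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

validateSimConfig <- function(cfg) {
    stopifnot(is.numeric(cfg$chromLengths), all(cfg$chromLengths > 0),
              !is.null(names(cfg$chromLengths)),
              cfg$nGenes >= 0, cfg$nPeaks >= 0,
              cfg$motifPlantRate >= 0, cfg$motifPlantRate <= 1,
              cfg$gcContent > 0, cfg$gcContent < 1,
              all(cfg$librarySizeRange > 0),
              cfg$effectSize[["mean"]] > 0, cfg$effectSize[["sd"]] >= 0)
    want <- c("GF", "GF+HFM", "CV", "CV+HFM")
    if (!identical(sort(names(cfg$replicates)), sort(want)))
        stop("replicates must name exactly the conditions ",
             paste(want, collapse = ", "))
    if (any(cfg$replicates < 1)) stop("each condition needs >= 1 replicate")
    if (abs(sum(cfg$effectFractions) - 1) > 1e-8)
        stop("effectFractions must sum to 1")
    invisible(cfg)
}

#' Replicate layouts of the study's three assays
#'
#' RNA-seq 4/4/4/4, H3K27ac ChIP-seq 2/5/2/5, and HNF4A ChIP-seq 3/4/3/4
#' replicates for GF, GF+HFM, CV, CV+HFM respectively.
#'
#' @return named list of three replicate maps usable as the `replicates`
#'   field of [simConfig].
#' @export
replicateLayouts <- function() {
    list(rna     = c("GF" = 4L, "GF+HFM" = 4L, "CV" = 4L, "CV+HFM" = 4L),
         h3k27ac = c("GF" = 2L, "GF+HFM" = 5L, "CV" = 2L, "CV+HFM" = 5L),
         hnf4a   = c("GF" = 3L, "GF+HFM" = 4L, "CV" = 3L, "CV+HFM" = 4L))
}

subSeed <- function(seed, stage) {
    (as.integer(seed) * 97L + stage * 7919L) %% 2147483646L + 1L
}

truncNorm <- function(n, mean, sd) {
    abs(stats::rnorm(n, mean, sd))
}

drawEffects <- function(n, cfg) {
    classes <- names(cfg$effectFractions)
    cls <- sample(classes, n, replace = TRUE, prob = cfg$effectFractions)
    e <- truncNorm(n, cfg$effectSize[["mean"]], cfg$effectSize[["sd"]])
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    sgn2 <- sample(c(-1, 1), n, replace = TRUE)
    bm <- bf <- bi <- numeric(n)
    bm[cls == "microbe"] <- (sgn * e)[cls == "microbe"]
    bm[cls == "additive"] <- (sgn * e)[cls == "additive"]
    bf[cls == "meal"] <- (sgn * e)[cls == "meal"]
    bf[cls == "additive"] <- (sgn2 * e)[cls == "additive"]
    bi[cls == "interactionPos"] <- e[cls == "interactionPos"]
    bf[cls == "interactionNeg"] <- e[cls == "interactionNeg"]
    bi[cls == "interactionNeg"] <- -e[cls == "interactionNeg"]
    q <- exp(stats::runif(n, cfg$baseMeanLogRange[1],
                          cfg$baseMeanLogRange[2]))
    alpha <- cfg$dispersionParams[["a0"]] +
        cfg$dispersionParams[["a1"]] / q
    data.frame(class = cls, betaM = bm, betaF = bf, betaI = bi,
               q = q, alpha = alpha, stringsAsFactors = FALSE)
}

#' Re-derive the effect class from planted coefficients
#'
#' Used by the truth-consistency checks: a stored class label must be
#' reproducible from its (betaM, betaF, betaI) signs and magnitudes.
#'
#' @param betaM,betaF,betaI planted log2 coefficients.
#' @return character vector of class labels.
#' @export
effectClassFromBetas <- function(betaM, betaF, betaI) {
    m <- betaM != 0; f <- betaF != 0; i <- betaI != 0
    out <- rep("null", length(betaM))
    out[m & !f & !i] <- "microbe"
    out[!m & f & !i] <- "meal"
    out[m & f & !i] <- "additive"
    out[!m & !f & i & betaI > 0] <- "interactionPos"
    out[!m & f & i & betaF > 0 & betaI < 0] <- "interactionNeg"
    out
}

placeIntervals <- function(chromLengths, n, minLen, maxLen, minGap) {
    if (n == 0)
        return(GRanges())
    # apportion features to chromosomes by length
    nPer <- diff(round(c(0, cumsum(chromLengths) / sum(chromLengths) * n)))
    names(nPer) <- names(chromLengths)
    parts <- list()
    for (chr in names(chromLengths)) {
        k <- nPer[[chr]]
        if (k == 0) next
        L <- chromLengths[[chr]]
        need <- k * (maxLen + minGap) + minGap
        if (need > L)
            stop("chromosome ", chr, " (", L, " bp) too small for ", k,
                 " features of up to ", maxLen, " bp with ", minGap,
                 " bp gaps")
        lens <- round(stats::runif(k, minLen, maxLen))
        slack <- L - sum(lens) - (k + 1) * minGap
        gaps <- minGap + diff(round(c(0, sort(stats::runif(k + 1)) *
                                          slack)))[seq_len(k)]
        starts <- cumsum(gaps) + cumsum(c(0, lens[-k]))
        parts[[chr]] <- bedRanges(chr, starts, starts + lens)
    }
    suppressWarnings(unname(do.call(c, unname(parts))))
}

#' Simulate the genome annotation and ground truth
#'
#' Generates non-overlapping stranded genes, non-overlapping merged-peak
#' intervals (>= 200 bp), binding sites placed inside gene bodies with a
#' configurable subset of genes receiving more than 10 sites, per-cell-type
#' accessibility interval sets over the four epithelial populations
#' (ISC, TA, EEC, enterocyte), and the per-feature effect-class truth.
#'
#' @param cfg a [simConfig].
#' @return list with `genes`, `peaks`, `sites` (GRanges), `accessibility`
#'   (named list of GRanges), and `truth` (list of data.frames `genes`,
#'   `peaks` carrying planted coefficients, base means, dispersions,
#'   sites-per-gene, and accessibility labels).
#' @export
simulateAnnotation <- function(cfg) {
    validateSimConfig(cfg)
    set.seed(subSeed(cfg$seed, 1L))
    genes <- placeIntervals(cfg$chromLengths, cfg$nGenes,
                            minLen = 2000, maxLen = 10000, minGap = 1000)
    if (length(genes)) {
        strand(genes) <- sample(c("+", "-"), length(genes), replace = TRUE)
        names(genes) <- sprintf("gene_%05d", seq_along(genes))
        genes$name <- names(genes)
    }
    peaks <- placeIntervals(cfg$chromLengths, cfg$nPeaks,
                            minLen = 200, maxLen = 1500, minGap = 300)
    if (length(peaks)) {
        names(peaks) <- sprintf("peak_%05d", seq_along(peaks))
        peaks$name <- names(peaks)
    }

    gTruth <- drawEffects(length(genes), cfg)
    if (length(genes)) rownames(gTruth) <- names(genes)
    pTruth <- drawEffects(length(peaks), cfg)
    if (length(peaks)) rownames(pTruth) <- names(peaks)

    # binding sites: high-binding genes get 11-20 sites, others 0-3,
    # all placed inside the gene body so the nearest gene is unambiguous
    sites <- GRanges()
    sitesPerGene <- integer(length(genes))
    if (length(genes)) {
        nHigh <- round(cfg$highBindingFraction * length(genes))
        high <- sample(seq_along(genes), nHigh)
        nSites <- sample(0:3, length(genes), replace = TRUE)
        nSites[high] <- sample(11:20, nHigh, replace = TRUE)
        sitesPerGene <- nSites
        siteW <- 200L
        parts <- lapply(which(nSites > 0), function(i) {
            g <- genes[i]
            maxOff <- width(g) - siteW
            offs <- sort(sample.int(max(maxOff, 1), nSites[i],
                                    replace = maxOff < nSites[i]))
            bedRanges(as.character(seqnames(g)),
                      bedStart(g) + offs - 1L,
                      bedStart(g) + offs - 1L + siteW)
        })
        if (length(parts)) {
            sites <- sort(suppressWarnings(unname(do.call(c, unname(parts)))))
            names(sites) <- sprintf("site_%05d", seq_along(sites))
        }
    }
    gTruth$sitesPerGene <- sitesPerGene

    # accessibility labels for peaks
    cellTypes <- c("ISC", "TA", "EEC", "enterocyte")
    accTruth <- character(length(peaks))
    accSets <- stats::setNames(
        replicate(length(cellTypes), GRanges(), simplify = FALSE), cellTypes)
    if (length(peaks)) {
        labs <- c("pan-accessible", "enterocyte-specific",
                  "enterocyte-restricted", "ISC-specific", "ISC-restricted",
                  "other")
        accTruth <- sample(labs, length(peaks), replace = TRUE,
                           prob = c(0.2, 0.15, 0.15, 0.15, 0.15, 0.2))
        memb <- matrix(FALSE, length(peaks), length(cellTypes),
                       dimnames = list(NULL, cellTypes))
        for (i in seq_along(peaks)) {
            memb[i, ] <- switch(accTruth[i],
                "pan-accessible" = rep(TRUE, 4),
                "enterocyte-specific" = cellTypes == "enterocyte",
                "enterocyte-restricted" = cellTypes %in%
                    c("enterocyte", sample(c("ISC", "TA", "EEC"),
                                           sample(1:2, 1))),
                "ISC-specific" = cellTypes == "ISC",
                "ISC-restricted" = cellTypes %in%
                    c("ISC", sample(c("TA", "EEC"), sample(1:2, 1))),
                "other" = cellTypes %in%
                    (if (stats::runif(1) < 0.5) character(0)
                     else sample(c("TA", "EEC"), 1)))
        }
        for (tp in cellTypes)
            accSets[[tp]] <- peaks[memb[, tp]]
    }
    pTruth$accessibility <- accTruth

    list(genes = genes, peaks = peaks, sites = sites,
         accessibility = accSets,
         truth = list(genes = gTruth, peaks = pTruth))
}

#' Simulate factorial negative binomial counts
#'
#' Draws a feature-by-sample count matrix under the configured mean model
#' (see [simConfig]). Samples are named `<condition>_<replicate>` with `+`
#' and `/` removed for file-system safety.
#'
#' @param truth data.frame with columns `betaM`, `betaF`, `betaI`, `q`,
#'   `alpha` (one row per feature).
#' @param replicates named integer vector over the 4 conditions.
#' @param cfg a [simConfig] (supplies the library-size range and seed).
#' @param stage integer stage index used to derive the sub-seed, so the
#'   different assays of one simulated study get independent draws.
#' @return a [FactorialExperiment] with the true size factors in
#'   `metadata()$trueSizeFactors`.
#' @export
simulateCounts <- function(truth, replicates, cfg, stage = 2L) {
    set.seed(subSeed(cfg$seed, stage))
    condMap <- data.frame(
        condition = c("GF", "GF+HFM", "CV", "CV+HFM"),
        microbes = c("GF", "GF", "CV", "CV"),
        meal = c("none", "HFM", "none", "HFM"))
    condMap <- condMap[rep(seq_len(4), replicates[condMap$condition]), ]
    rep_i <- unlist(lapply(replicates[c("GF", "GF+HFM", "CV", "CV+HFM")],
                           seq_len))
    sample_id <- paste0(gsub("[+/]", "", condMap$condition), "_", rep_i)
    x <- as.integer(condMap$microbes == "CV")
    y <- as.integer(condMap$meal == "HFM")
    s <- stats::runif(nrow(condMap), cfg$librarySizeRange[1],
                      cfg$librarySizeRange[2])
    n <- nrow(truth)
    lfc <- outer(truth$betaM, x) + outer(truth$betaF, y) +
        outer(truth$betaI, x * y)
    mu <- sweep(truth$q * 2^lfc, 2, s, "*")
    if (any(!is.finite(mu))) stop("non-finite simulated means")
    size <- 1 / pmax(truth$alpha, 1e-8)
    k <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = rep(size, ncol(mu))),
                nrow = n,
                dimnames = list(rownames(truth), sample_id))
    fe <- FactorialExperiment(k, microbes = condMap$microbes,
                              meal = condMap$meal)
    metadata(fe)$trueSizeFactors <- stats::setNames(s, sample_id)
    fe
}

#' Simulate region sequences with planted motif consensi
#'
#' Backgrounds are i.i.d. bases at the configured GC content; each
#' designated region receives at least one planted consensus of its assigned
#' motif at a random position and strand.
#'
#' @param regions `GRanges` with names; sequence length = region width.
#' @param pwms named list of [pwm] objects.
#' @param cfg a [simConfig].
#' @param plant character vector over regions: a motif name to plant or
#'   `NA` for background only. Default: the first motif is planted in a
#'   random `motifPlantRate` fraction of regions.
#' @param stage sub-seed stage index.
#' @return list with `sequences` (named `DNAStringSet`) and `planted`
#'   (data.frame region, motif, position, strand; background-only regions
#'   have `NA` motif).
#' @export
simulateSequences <- function(regions, pwms, cfg, plant = NULL, stage = 5L) {
    set.seed(subSeed(cfg$seed, stage))
    n <- length(regions)
    ids <- names(regions)
    if (is.null(ids)) ids <- sprintf("region_%05d", seq_len(n))
    if (is.null(plant)) {
        plant <- rep(NA_character_, n)
        if (length(pwms) && cfg$motifPlantRate > 0 && n > 0)
            plant[stats::runif(n) < cfg$motifPlantRate] <- names(pwms)[1]
    }
    stopifnot(length(plant) == n)
    gc <- cfg$gcContent
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    widths <- width(regions)
    seqs <- character(n)
    planted <- data.frame(region = ids, motif = plant,
                          position = NA_integer_,
                          strand = NA_character_)
    for (i in seq_len(n)) {
        s <- sample(BASES, widths[i], replace = TRUE, prob = probs)
        if (!is.na(plant[i])) {
            w <- pwms[[plant[i]]]
            if (is.null(w)) stop("unknown motif: ", plant[i])
            cons <- pwmConsensus(w)
            L <- nchar(cons)
            if (L > widths[i])
                stop("motif ", plant[i], " (", L, " bp) longer than region ",
                     ids[i], " (", widths[i], " bp)")
            if (stats::runif(1) < 0.5) {
                cons <- as.character(reverseComplement(DNAString(cons)))
                planted$strand[i] <- "-"
            } else planted$strand[i] <- "+"
            pos <- sample.int(widths[i] - L + 1L, 1L)
            planted$position[i] <- pos
            s[pos:(pos + L - 1L)] <- strsplit(cons, "")[[1]]
        }
        seqs[i] <- paste(s, collapse = "")
    }
    out <- DNAStringSet(seqs)
    names(out) <- ids
    list(sequences = out, planted = planted)
}

#' Simulate a complete factorial study
#'
#' One call producing everything the pipeline consumes: annotation and
#' truth, gene-level RNA counts (4/4/4/4), window-level chromatin counts
#' over the tiled merged peaks (2/5/2/5, windows inheriting their parent
#' peak's planted effects), binding sites, accessibility sets, a DNase-site
#' (DHS) set with one site inside each peak, and DHS sequences with the
#' first configured motif planted in regions whose peak carries the
#' negative-interaction ("blue"-pattern) truth class.
#'
#' @param cfg a [simConfig].
#' @param pwms named list of PWMs (default the bundled synthetic set).
#' @return list with elements `config`, `annotation`, `truth`, `rna`,
#'   `h3k27ac` (window-level [FactorialExperiment]), `windows`, `dhs`,
#'   `sequences`, `planted`.
#' @export
simulateFactorialData <- function(cfg = simConfig(), pwms = syntheticPWMs()) {
    ann <- simulateAnnotation(cfg)
    layouts <- replicateLayouts()
    rna <- NULL
    if (nrow(ann$truth$genes))
        rna <- simulateCounts(ann$truth$genes, cfg$replicates, cfg,
                              stage = 2L)
    windows <- NULL; h3k27ac <- NULL; winTruth <- NULL
    if (length(ann$peaks)) {
        windows <- tileWindows(ann$peaks, width = 300L, step = 200L)
        winTruth <- ann$truth$peaks[windows$parentPeak, ]
        rownames(winTruth) <- names(windows)
        # windows share the peak effect; per-window depth varies a little
        set.seed(subSeed(cfg$seed, 3L))
        winTruth$q <- winTruth$q * exp(stats::rnorm(nrow(winTruth), 0, 0.1))
        winTruth$alpha <- cfg$dispersionParams[["a0"]] +
            cfg$dispersionParams[["a1"]] / winTruth$q
        h3k27ac <- simulateCounts(winTruth, layouts$h3k27ac, cfg,
                                  stage = 4L)
    }
    dhs <- NULL; seqinfo <- NULL; planted <- NULL; sequences <- NULL
    if (length(ann$peaks)) {
        # one DHS inside each peak (so the closest DHS is within 1 kb)
        w <- pmin(width(ann$peaks), 300L)
        off <- pmax((width(ann$peaks) - w) %/% 2L, 0L)
        dhs <- bedRanges(as.character(seqnames(ann$peaks)),
                         bedStart(ann$peaks) + off,
                         bedStart(ann$peaks) + off + w)
        names(dhs) <- sprintf("dhs_%05d", seq_along(dhs))
        plant <- rep(NA_character_, length(dhs))
        if (length(pwms)) {
            blue <- ann$truth$peaks$class == "interactionNeg"
            set.seed(subSeed(cfg$seed, 6L))
            plant[blue & stats::runif(length(dhs)) < cfg$motifPlantRate] <-
                names(pwms)[1]
        }
        sq <- simulateSequences(dhs, pwms, cfg, plant = plant, stage = 5L)
        sequences <- sq$sequences
        planted <- sq$planted
    }
    list(config = cfg, annotation = ann, truth = ann$truth,
         rna = rna, h3k27ac = h3k27ac, windows = windows,
         windowTruth = winTruth, dhs = dhs, sequences = sequences,
         planted = planted)
}
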