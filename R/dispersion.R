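#' Method-of-moments dispersion estimation with a mean-dispersion trend
#'
#' The negative binomial model used throughout the package parameterizes the
#' variance as `mu + alpha * mu^2`. Per-feature dispersions are estimated by a
#' method of moments on size-factor-normalized counts pooled over the design
#' cells with at least two replicates, floored at `alphaFloor`. A trend
#' `alpha(mu) = a0 + a1 / mu` is then fitted to the per-feature estimates by
#' robust regression ([MASS::rlm]), and the final estimate geometrically
#' interpolates the feature estimate toward the trend:
#' `alphaHat = alphaMoM^(1 - trendWeight) * alphaTrend^trendWeight`.
#'
#' For normalized counts `y = k / s` within a cell with mean `m`, the model
#' variance is approximately `m * E(1/s) + alpha * m^2`; the moment estimator
#' solves the pooled within-cell residual sum of squares for `alpha`, using
#' the mean inverse size factor for the Poisson part.
#'
#' @param fe a [FactorialExperiment] with size factors set.
#' @param trendWeight interpolation weight toward the trend in `[0, 1]`
#'   (0 = pure per-feature moments, 1 = trend only). Default 0.7: individual
#'   moment estimates from 2-5 replicates per cell are noisy, so most of the
#'   weight goes to the trend, mirroring common shrinkage practice.
#' @param alphaFloor lower bound on every dispersion estimate.
#' @return `fe` with `rowData` columns `baseMean`, `dispMoM`, `dispTrend`,
#'   `dispersion`.
#' @export
estimateDispersionsMoM <- function(fe, trendWeight = 0.7, alphaFloor = 1e-8) {
    stopifnot(trendWeight >= 0, trendWeight <= 1)
    y <- normalizedCounts(fe)
    sf <- sizeFactors(fe)
    cond <- condition(fe)
    baseMean <- rowMeans(y)

    cells <- levels(cond)[tabulate(cond) >= 2L]
    if (!length(cells)) {
        warning("no design cell has >= 2 replicates; using trend-only defaults")
        rowData(fe)$baseMean <- baseMean
        rowData(fe)$dispMoM <- rep(NA_real_, nrow(fe))
        rowData(fe)$dispTrend <- rep(0.1, nrow(fe))
        rowData(fe)$dispersion <- rep(0.1, nrow(fe))
        return(fe)
    }
    ssq <- numeric(nrow(fe))      # pooled within-cell residual SS
    pois <- numeric(nrow(fe))     # Poisson part of expected SS
    quad <- numeric(nrow(fe))     # coefficient of alpha
    df <- 0L
    for (cl in cells) {
        j <- which(cond == cl)
        nc <- length(j)
        m <- rowMeans(y[, j, drop = FALSE])
        r <- y[, j, drop = FALSE] - m
        v <- rowSums(r * r) / (nc - 1L)
        ssq <- ssq + (nc - 1L) * v
        invS <- mean(1 / sf[j])
        pois <- pois + (nc - 1L) * m * invS
        # m^2 overestimates mu^2 by var(m) = E[v]/nc; correct for it
        quad <- quad + (nc - 1L) * pmax(m * m - v / nc, 0)
        df <- df + nc - 1L
    }
    alphaMoM <- ifelse(quad > 0, (ssq - pois) / quad, alphaFloor)
    alphaMoM <- pmax(alphaMoM, alphaFloor)

    use <- baseMean > 1 & alphaMoM > alphaFloor * 2
    if (sum(use) >= 10) {
        fit <- suppressWarnings(
            MASS::rlm(alphaMoM[use] ~ I(1 / baseMean[use]), maxit = 50))
        a0 <- max(coef(fit)[1], alphaFloor)
        a1 <- max(coef(fit)[2], 0)
    } else {
        a0 <- max(stats::median(alphaMoM), alphaFloor)
        a1 <- 0
    }
    alphaTrend <- pmax(a0 + a1 / pmax(baseMean, 1e-8), alphaFloor)
    alphaHat <- exp((1 - trendWeight) * log(alphaMoM) +
                    trendWeight * log(alphaTrend))

    rowData(fe)$baseMean <- baseMean
    rowData(fe)$dispMoM <- alphaMoM
    rowData(fe)$dispTrend <- alphaTrend
    rowData(fe)$dispersion <- pmax(alphaHat, alphaFloor)
    metadata(fe)$dispersionTrend <- c(a0 = unname(a0), a1 = unname(a1))
    fe
}
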