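#' Contrast definitions for the 2x2 factorial
#'
#' Each of the four pairwise condition comparisons is a linear combination of
#' the log2-scale model coefficients (microbes, meal, interaction):
#' \describe{
#'   \item{CV/GF}{microbes}
#'   \item{CV+HFM/GF+HFM}{microbes + interaction}
#'   \item{GF+HFM/GF}{meal}
#'   \item{CV+HFM/CV}{meal + interaction}
#' }
#' The interaction coefficient itself is the log2 ratio of ratios
#' (CV+HFM/CV)/(GF+HFM/GF), tested by the likelihood ratio test.
#'
#' @return named list of length-4 contrast vectors over
#'   (intercept, microbes, meal, interaction).
#' @export
factorialContrasts <- function() {
    list("CV/GF"           = c(0, 1, 0, 0),
         "CV+HFM/GF+HFM"   = c(0, 1, 0, 1),
         "GF+HFM/GF"       = c(0, 0, 1, 0),
         "CV+HFM/CV"       = c(0, 0, 1, 1))
}

#' Wald test for one pairwise contrast
#'
#' The contrast log2 fold change is `c' beta`; its standard error comes from
#' the coefficient covariance, and the p value from a two-sided normal test
#' of `log2FC / SE`. Non-converged fits get missing p values.
#'
#' @param fit a [FactorialFit-class] object.
#' @param contrast one of `names(factorialContrasts())`.
#' @return [S4Vectors::DataFrame] with `baseMean`, `log2FC`, `SE`, `stat`,
#'   `p` per feature; metadata records the contrast name.
#' @export
waldContrast <- function(fit, contrast = names(factorialContrasts())) {
    contrast <- match.arg(contrast)
    cvec <- factorialContrasts()[[contrast]]
    n <- nrow(fit@beta)
    lfc <- unname(drop(fit@beta %*% cvec))
    se <- vapply(seq_len(n), function(i) {
        v <- drop(crossprod(cvec, fit@cov[[i]] %*% cvec))
        if (is.na(v) || v < 0) NA_real_ else sqrt(v)
    }, numeric(1))
    stat <- lfc / se
    p <- 2 * stats::pnorm(-abs(stat))
    p[!fit@converged] <- NA_real_
    res <- DataFrame(baseMean = fit@baseMean, log2FC = lfc, SE = se,
                     stat = stat, p = p, row.names = rownames(fit@beta))
    metadata(res)$contrast <- contrast
    metadata(res)$test <- "Wald"
    res
}

#' Likelihood ratio test for the microbe-by-meal interaction
#'
#' Statistic `2 * (logLik(full) - logLik(reduced))`, floored at zero, against
#' a chi-squared distribution with 1 degree of freedom. The reported log2FC
#' is the interaction coefficient, i.e. the log2 ratio of the meal response
#' with microbes to the meal response without microbes.
#'
#' @param fit a [FactorialFit-class] object.
#' @return [S4Vectors::DataFrame] with `baseMean`, `log2FC`, `SE`, `stat`,
#'   `p`; metadata records contrast `"interaction"`.
#' @export
lrtInteraction <- function(fit) {
    stat <- pmax(2 * (fit@logLikFull - fit@logLikReduced), 0)
    refit <- fit@converged &
        (fit@logLikFull < fit@logLikReduced - 1e-6)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    p[!fit@converged] <- NA_real_
    res <- DataFrame(baseMean = fit@baseMean,
                     log2FC = unname(fit@beta[, "interaction"]),
                     SE = unname(fit@se[, "interaction"]),
                     stat = stat, p = p, refit = refit,
                     row.names = rownames(fit@beta))
    metadata(res)$contrast <- "interaction"
    metadata(res)$test <- "LRT"
    res
}

#' Multiple-testing adjustment and significance calls
#'
#' Benjamini-Hochberg adjustment is applied within each contrast separately,
#' then three flags are added:
#' \describe{
#'   \item{standard}{`padj < padjCutoff` (default 0.05), the cutoff used for
#'     the pairwise comparisons}
#'   \item{lenientGene}{`p < leniGeneP` and `baseMean > leniGeneBase`
#'     (defaults 0.05 and 10), the relaxed interaction-gene cutoff}
#'   \item{lenientWindow}{`p < leniWinP` and `baseMean > leniWinBase`
#'     (defaults 0.01 and 15), the relaxed interaction-window cutoff}
#' }
#'
#' @param res a result `DataFrame` from [waldContrast] or [lrtInteraction],
#'   or a list of them.
#' @param padjCutoff,leniGeneP,leniGeneBase,leniWinP,leniWinBase thresholds.
#' @return the input with `padj`, `standard`, `lenientGene`, `lenientWindow`
#'   columns added.
#' @export
adjustAndCall <- function(res, padjCutoff = 0.05,
                          leniGeneP = 0.05, leniGeneBase = 10,
                          leniWinP = 0.01, leniWinBase = 15) {
    if (is.list(res) && !is(res, "DataFrame"))
        return(lapply(res, adjustAndCall, padjCutoff = padjCutoff,
                      leniGeneP = leniGeneP, leniGeneBase = leniGeneBase,
                      leniWinP = leniWinP, leniWinBase = leniWinBase))
    if (!nrow(res)) {
        res$padj <- numeric(0)
        res$standard <- res$lenientGene <- res$lenientWindow <- logical(0)
        return(res)
    }
    res$padj <- stats::p.adjust(res$p, method = "BH")
    res$standard <- !is.na(res$padj) & res$padj < padjCutoff
    res$lenientGene <- !is.na(res$p) & res$p < leniGeneP &
        res$baseMean > leniGeneBase
    res$lenientWindow <- !is.na(res$p) & res$p < leniWinP &
        res$baseMean > leniWinBase
    res
}

#' Full factorial differential testing
#'
#' Convenience wrapper running normalization, dispersion estimation, model
#' fitting, the four Wald contrasts, the interaction LRT, and per-contrast
#' BH adjustment with significance flags.
#'
#' @param fe a [FactorialExperiment].
#' @param trendWeight dispersion shrinkage weight, see
#'   [estimateDispersionsMoM].
#' @param ... threshold arguments passed to [adjustAndCall].
#' @return named list of five result `DataFrame`s: the four pairwise
#'   contrasts plus `"interaction"`.
#' @examples
#' sim <- simulateFactorialData(simConfig(nGenes = 60, nPeaks = 0, seed = 1))
#' res <- factorialResults(sim$rna)
#' head(res[["CV/GF"]])
#' @export
factorialResults <- function(fe, trendWeight = 0.7, ...) {
    fit <- fitFactorialModel(fe, trendWeight = trendWeight)
    out <- lapply(names(factorialContrasts()), function(cn)
        waldContrast(fit, cn))
    names(out) <- names(factorialContrasts())
    out$interaction <- lrtInteraction(fit)
    adjustAndCall(out, ...)
}
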