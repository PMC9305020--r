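#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over reference
#' features, of the ratio of the sample's count to the feature's geometric
#' mean across samples. Reference features are those with a positive count in
#' every sample; when no such feature exists, geometric means are computed
#' over positive counts only and every feature with a positive count in a
#' given sample contributes to that sample's median. Returned factors are
#' rescaled so their geometric mean is exactly 1.
#'
#' @param object a count matrix (features x samples) or a
#'   [FactorialExperiment].
#' @return for a matrix, a named numeric vector of positive size factors; for
#'   a `FactorialExperiment`, the object with `sizeFactors(object)` set.
#' @examples
#' k <- rbind(c(10, 20), c(100, 200), c(4, 8))
#' estimateSizeFactorsMedianRatio(k)   # 1/sqrt(2), sqrt(2)
#' @export
estimateSizeFactorsMedianRatio <- function(object) {
    if (is(object, "FactorialExperiment")) {
        sf <- estimateSizeFactorsMedianRatio(counts(object))
        sizeFactors(object) <- sf
        return(object)
    }
    k <- as.matrix(object)
    if (all(k == 0)) stop("all-zero count matrix: size factors undefined")
    allPos <- rowSums(k > 0) == ncol(k)
    if (any(allPos)) {
        logGeo <- rowMeans(log(k[allPos, , drop = FALSE]))
        sf <- apply(k[allPos, , drop = FALSE], 2, function(col)
            exp(stats::median(log(col) - logGeo)))
    } else {
        # no feature observed in every sample: positive-only geometric means
        logk <- log(k)
        logk[k == 0] <- NA
        logGeo <- rowMeans(logk, na.rm = TRUE)
        usable <- is.finite(logGeo)
        sf <- vapply(seq_len(ncol(k)), function(j) {
            r <- logk[usable, j] - logGeo[usable]
            r <- r[is.finite(r)]
            if (!length(r)) stop("sample ", j, " shares no positive feature")
            exp(stats::median(r))
        }, numeric(1))
    }
    sf <- sf / exp(mean(log(sf)))
    names(sf) <- colnames(k)
    sf
}
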