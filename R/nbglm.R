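#' Negative binomial log-likelihood at fixed dispersion
#'
#' Log-likelihood of counts `y` under NB(mean = mu, variance = mu + alpha*mu^2).
#' As `alpha` approaches 0 the Poisson log-likelihood is used.
#'
#' @param y integer counts.
#' @param mu positive means.
#' @param alpha dispersion (scalar).
#' @return scalar log-likelihood.
#' @export
nbLogLik <- function(y, mu, alpha) {
    mu <- pmax(mu, 1e-300)
    if (alpha < 1e-10)
        return(sum(stats::dpois(y, mu, log = TRUE)))
    size <- 1 / alpha
    sum(stats::dnbinom(y, size = size, mu = mu, log = TRUE))
}

#' Fit one negative binomial GLM by iteratively reweighted least squares
#'
#' Log-link NB regression at fixed dispersion: `log(mu) = offset + X beta`
#' (natural-log scale). Working weights are `mu / (1 + alpha * mu)`, the
#' Fisher information for the log link. Iteration stops when the largest
#' absolute coefficient change falls below `tol` or after `maxit` iterations.
#'
#' @param y counts for one feature (length = number of samples).
#' @param X design matrix (samples x p), full column rank.
#' @param offset per-sample log size factors (natural log).
#' @param alpha NB dispersion for this feature.
#' @param tol convergence tolerance on coefficients.
#' @param maxit maximum IRLS iterations.
#' @return list with `beta` (natural-log scale), `se` (same scale), `cov`
#'   (coefficient covariance), `logLik`, `converged`, `iter`, `mu`.
#' @export
fitNBGLM <- function(y, X, offset = rep(0, length(y)), alpha = 0,
                     tol = 1e-8, maxit = 100L) {
    X <- as.matrix(X)
    p <- ncol(X)
    # initialize from the log mean (pseudo-count to allow zeros)
    beta <- numeric(p)
    beta[1] <- log(max(mean(y / exp(offset)), 0.1))
    converged <- FALSE
    iter <- 0L
    for (it in seq_len(maxit)) {
        iter <- it
        eta <- drop(offset + X %*% beta)
        eta <- pmin(pmax(eta, -30), 30)   # guard against divergence
        mu <- exp(eta)
        w <- mu / (1 + alpha * mu)
        z <- (eta - offset) + (y - mu) / mu
        XtW <- t(X * w)
        betaNew <- tryCatch(
            drop(solve(XtW %*% X, XtW %*% z)),
            error = function(e) rep(NA_real_, p))
        if (anyNA(betaNew)) break
        delta <- max(abs(betaNew - beta))
        beta <- betaNew
        if (delta < tol) { converged <- TRUE; break }
    }
    eta <- pmin(pmax(drop(offset + X %*% beta), -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    info <- crossprod(X * sqrt(w))
    covB <- tryCatch(solve(info), error = function(e)
        matrix(NA_real_, p, p))
    list(beta = beta, se = sqrt(pmax(diag(covB), 0)), cov = covB,
         logLik = nbLogLik(y, mu, alpha), converged = converged,
         iter = iter, mu = mu)
}

#' Fit the full and reduced factorial NB models for every feature
#'
#' The full model has intercept, microbes, meal, and interaction terms; the
#' reduced model drops the interaction only. A single dispersion per feature
#' (from [estimateDispersionsMoM]) is shared between the two fits so the LRT
#' compares nested means models. Coefficients and standard errors are stored
#' on the log2 scale, matching how fold changes are reported. Features with
#' zero counts in all samples are dropped before fitting.
#'
#' @param fe a [FactorialExperiment]; size factors and dispersions are
#'   estimated first when absent.
#' @param trendWeight passed to [estimateDispersionsMoM] when dispersions are
#'   missing.
#' @return a `FactorialFit` object (see [FactorialFit-class]).
#' @export
fitFactorialModel <- function(fe, trendWeight = 0.7) {
    keep <- rowSums(counts(fe)) > 0
    if (!all(keep)) fe <- fe[keep, ]
    if (is.null(sizeFactors(fe))) fe <- estimateSizeFactorsMedianRatio(fe)
    if (is.null(rowData(fe)$dispersion))
        fe <- estimateDispersionsMoM(fe, trendWeight = trendWeight)

    X <- designMatrix(fe)
    Xr <- X[, 1:3, drop = FALSE]
    off <- log(sizeFactors(fe))
    k <- counts(fe)
    alpha <- rowData(fe)$dispersion
    n <- nrow(k)
    ln2 <- log(2)

    beta <- matrix(NA_real_, n, 4,
                   dimnames = list(rownames(k),
                                   c("intercept", "microbes", "meal",
                                     "interaction")))
    se <- beta
    covs <- vector("list", n)
    llFull <- llRed <- numeric(n)
    conv <- logical(n)
    for (i in seq_len(n)) {
        y <- k[i, ]
        ff <- fitNBGLM(y, X, off, alpha[i])
        fr <- fitNBGLM(y, Xr, off, alpha[i])
        beta[i, ] <- ff$beta / ln2
        se[i, ] <- ff$se / ln2
        covs[[i]] <- ff$cov / ln2^2
        llFull[i] <- ff$logLik
        llRed[i] <- fr$logLik
        conv[i] <- ff$converged && fr$converged
    }
    new("FactorialFit",
        experiment = fe, beta = beta, se = se, cov = covs,
        logLikFull = llFull, logLikReduced = llRed, converged = conv,
        baseMean = rowData(fe)$baseMean, dispersion = alpha)
}

#' FactorialFit: per-feature factorial NB model fits
#'
#' Holds, for every fitted feature, the full-model coefficients and standard
#' errors on the log2 scale, the coefficient covariance, the full and reduced
#' (no-interaction) log-likelihoods, a convergence flag, the mean of
#' normalized counts (`baseMean`), and the dispersion used.
#'
#' @aliases FactorialFit-class
#' @export
setClass("FactorialFit", representation(
    experiment = "FactorialExperiment",
    beta = "matrix", se = "matrix", cov = "list",
    logLikFull = "numeric", logLikReduced = "numeric",
    converged = "logical", baseMean = "numeric", dispersion = "numeric"))

setValidity("FactorialFit", function(object) {
    n <- nrow(object@beta)
    if (length(object@logLikFull) != n || length(object@logLikReduced) != n)
        return("log-likelihood length mismatch")
    bad <- object@converged &
        (object@logLikFull < object@logLikReduced - 1e-4)
    if (any(bad))
        return("full-model log-likelihood below reduced beyond tolerance")
    TRUE
})

#' @export
setMethod("show", "FactorialFit", function(object) {
    cat(class(object), "with", nrow(object@beta), "features;",
        sum(object@converged), "converged\n")
})

#' Accessors for FactorialFit
#' @param object a `FactorialFit`.
#' @return `fitCoefficients`: log2-scale coefficient matrix;
#'   `fitConverged`: logical vector; `fitBaseMean`: numeric vector.
#' @export
fitCoefficients <- function(object) object@beta

#' @rdname fitCoefficients
#' @export
fitConverged <- function(object) object@converged

#' @rdname fitCoefficients
#' @export
fitBaseMean <- function(object) object@baseMean
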