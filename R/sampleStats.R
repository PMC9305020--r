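#' Sample-level PCA of normalized counts
#'
#' Counts are transformed as `log2(normalized count + 1)`, the `nTop` most
#' variable features across samples are kept, features are centered, and the
#' decomposition is computed by SVD. Variance-explained fractions are the
#' squared singular values over their total.
#'
#' @param fe a [FactorialExperiment]; size factors are estimated when
#'   absent.
#' @param nTop number of top-variance features (default 500, the common
#'   plotting default); when fewer features exist all are used with a
#'   warning.
#' @param k number of components to return.
#' @return list with `coordinates` (samples x k), `varianceExplained`,
#'   `features` (the subset used), and `transformed` (the centered matrix,
#'   features x samples, for downstream distance computations).
#' @export
pcaCounts <- function(fe, nTop = 500L, k = 2L) {
    if (ncol(fe) < 3) stop("PCA needs at least 3 samples")
    if (is.null(sizeFactors(fe))) fe <- estimateSizeFactorsMedianRatio(fe)
    y <- log2(normalizedCounts(fe) + 1)
    v <- apply(y, 1, stats::var)
    if (nTop > nrow(y)) {
        warning("only ", nrow(y), " features available; using all")
        nTop <- nrow(y)
    }
    sel <- order(v, decreasing = TRUE)[seq_len(nTop)]
    yc <- y[sel, , drop = FALSE] - rowMeans(y[sel, , drop = FALSE])
    sv <- svd(t(yc))
    k <- min(k, length(sv$d))
    coords <- sv$u[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], k, k)
    dimnames(coords) <- list(colnames(fe), paste0("PC", seq_len(k)))
    varExp <- sv$d^2 / sum(sv$d^2)
    list(coordinates = coords,
         varianceExplained = varExp[seq_len(k)],
         features = rownames(y)[sel],
         transformed = yc)
}

#' One-factor PERMANOVA of a distance matrix
#'
#' Permutational multivariate analysis of variance: the distance matrix is
#' Gower-centered, total and among-group sums of squares are read off the
#' centered inner-product matrix, and the pseudo-F statistic
#' `F = (SSA / (a - 1)) / (SSW / (n - a))` is compared with its permutation
#' distribution under `nPerm` seeded random relabelings. The p value is
#' `(1 + #\{F_perm >= F_obs\}) / (1 + nPerm)`, so it cannot drop below
#' `1 / (nPerm + 1)`. R-squared (`SSA / SST`) does not depend on the
#' permutations.
#'
#' @param d a `dist` or square symmetric matrix of sample distances.
#' @param labels group label per sample (2 or more groups, no singletons).
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `F`, `R2`, `p`, `nPerm`, `df`.
#' @export
permanovaFactor <- function(d, labels, nPerm = 999L, seed = 1L) {
    D <- as.matrix(d)
    stopifnot(nrow(D) == ncol(D), isSymmetric(unname(D)))
    n <- nrow(D)
    labels <- factor(labels)
    stopifnot(length(labels) == n)
    if (any(table(labels) < 2)) stop("singleton group in PERMANOVA")
    a <- nlevels(labels)
    # Gower centering: G = -0.5 * J A J with A = D^2, J = I - 11'/n
    A <- -0.5 * D^2
    G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
    sst <- sum(diag(G))
    pseudoF <- function(lab) {
        H <- stats::model.matrix(~lab)
        H <- H %*% solve(crossprod(H), t(H))    # hat matrix
        ssa <- sum(H * G)                        # tr(H G)
        ssw <- sst - ssa
        (ssa / (a - 1)) / (ssw / (n - a))
    }
    Fobs <- pseudoF(labels)
    H <- stats::model.matrix(~labels)
    H <- H %*% solve(crossprod(H), t(H))
    ssa <- sum(H * G)
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(nPerm))
        if (pseudoF(labels[sample.int(n)]) >= Fobs - 1e-12) ge <- ge + 1L
    list(F = Fobs, R2 = ssa / sst, p = (1 + ge) / (1 + nPerm),
         nPerm = nPerm, df = c(among = a - 1L, within = n - a))
}

#' PCA plus per-factor PERMANOVA for a factorial experiment
#'
#' Runs [pcaCounts], computes Euclidean distances on the transformed
#' top-feature matrix, and tests microbes and meal in separate one-factor
#' PERMANOVAs (the reported per-factor R-squared and p values therefore do
#' not partition a joint model).
#'
#' @param fe a [FactorialExperiment].
#' @param nTop,nPerm,seed see [pcaCounts] and [permanovaFactor].
#' @return list with `pca` and `permanova` (data.frame, one row per factor).
#' @export
sampleStats <- function(fe, nTop = 500L, nPerm = 999L, seed = 1L) {
    pca <- pcaCounts(fe, nTop = nTop)
    d <- stats::dist(t(pca$transformed))
    pm <- lapply(list(microbes = microbes(fe), meal = meal(fe)),
                 function(lab) permanovaFactor(d, lab, nPerm = nPerm,
                                               seed = seed))
    tab <- data.frame(factor = names(pm),
                      F = vapply(pm, `[[`, numeric(1), "F"),
                      R2 = vapply(pm, `[[`, numeric(1), "R2"),
                      p = vapply(pm, `[[`, numeric(1), "p"),
                      nPerm = nPerm, row.names = NULL)
    list(pca = pca, permanova = tab)
}
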