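#' The eight directional significance groups
#'
#' Each of the four pairwise contrasts is split into up- and down-regulated
#' significant features, giving 8 groups in total. Direction is the sign of
#' the log2 fold change among flagged features; features flagged with a fold
#' change of exactly zero cannot be oriented and are dropped with a warning.
#'
#' @param results named list of the four pairwise contrast result
#'   `DataFrame`s (names as in [factorialContrasts]); an `interaction`
#'   element, if present, is ignored here.
#' @param flag which significance flag column to use (default `"standard"`,
#'   i.e. BH-adjusted p < 0.05).
#' @return a `DataFrame` with, per feature, one `direction.<contrast>` column
#'   in \{up, down, ns\} and 8 logical membership columns named
#'   `<contrast>.up` / `<contrast>.down`.
#' @export
assignDirectionalGroups <- function(results, flag = "standard") {
    need <- names(factorialContrasts())
    if (!all(need %in% names(results)))
        stop("missing contrast(s): ",
             paste(setdiff(need, names(results)), collapse = ", "))
    feats <- rownames(results[[need[1]]])
    for (cn in need)
        if (!identical(rownames(results[[cn]]), feats))
            stop("contrast results have inconsistent feature ids")
    out <- DataFrame(row.names = feats)
    for (cn in need) {
        r <- results[[cn]]
        sig <- r[[flag]] & !is.na(r[[flag]])
        zero <- sig & r$log2FC == 0
        if (any(zero)) {
            warning(sum(zero), " flagged feature(s) with log2FC == 0 in ",
                    cn, " cannot be oriented; treated as ns")
            sig <- sig & !zero
        }
        dir <- ifelse(!sig, "ns", ifelse(r$log2FC > 0, "up", "down"))
        out[[paste0("direction.", cn)]] <- dir
        out[[paste0(cn, ".up")]] <- dir == "up"
        out[[paste0(cn, ".down")]] <- dir == "down"
    }
    metadata(out)$flag <- flag
    metadata(out)$groups <- groupColumns()
    out
}

groupColumns <- function() {
    cn <- names(factorialContrasts())
    as.vector(t(outer(cn, c("up", "down"), paste, sep = ".")))
}

#' Pairwise overlap matrix of the directional groups
#'
#' Entry (g, h) counts features in both groups; the normalized matrix
#' divides by the smaller group size ("maximum overlap": the fraction of the
#' smaller group recovered in the larger). Empty groups give a normalized
#' entry of 0 and are listed in the `emptyGroups` metadata.
#'
#' @param groups output of [assignDirectionalGroups].
#' @return list with `counts` (8x8 integer, symmetric), `normalized`
#'   (8x8 numeric, diagonal 1 for non-empty groups), `sizes`.
#' @export
overlapMatrix <- function(groups) {
    gc <- groupColumns()
    member <- vapply(gc, function(g) as.logical(groups[[g]]),
                     logical(nrow(groups)))
    member <- matrix(member, nrow = nrow(groups), dimnames = list(NULL, gc))
    cnt <- crossprod(member)          # |g intersect h|
    sizes <- diag(cnt)
    mins <- outer(sizes, sizes, pmin)
    norm <- ifelse(mins > 0, cnt / mins, 0)
    list(counts = cnt, normalized = norm, sizes = sizes,
         emptyGroups = gc[sizes == 0])
}

#' Red/blue integration classes
#'
#' Classifies features (typically peaks after window-to-peak joining) by how
#' they integrate the microbial and meal signals:
#' \describe{
#'   \item{red}{up with meal in the colonized context and up with microbes:
#'     `CV+HFM/CV`-up and `CV+HFM/GF+HFM`-up}
#'   \item{blue}{up with meal in the germ-free context and down with
#'     microbes: `GF+HFM/GF`-up and `CV+HFM/GF+HFM`-down}
#'   \item{other-dual}{responsive in at least one +CV and one +HFM contrast
#'     but neither red nor blue}
#'   \item{none}{everything else}
#' }
#' Red and blue are mutually exclusive by construction (they require opposite
#' directions of the same contrast).
#'
#' @param groups output of [assignDirectionalGroups].
#' @return `DataFrame` with `class` (factor red/blue/other-dual/none) and
#'   `dualResponsive` (logical).
#' @export
classifyIntegration <- function(groups) {
    g <- function(nm) as.logical(groups[[nm]])
    plusCV <- (g("CV/GF.up") | g("CV/GF.down") |
               g("CV+HFM/GF+HFM.up") | g("CV+HFM/GF+HFM.down"))
    plusHFM <- (g("GF+HFM/GF.up") | g("GF+HFM/GF.down") |
                g("CV+HFM/CV.up") | g("CV+HFM/CV.down"))
    dual <- plusCV & plusHFM
    red <- g("CV+HFM/CV.up") & g("CV+HFM/GF+HFM.up")
    blue <- g("GF+HFM/GF.up") & g("CV+HFM/GF+HFM.down")
    cls <- rep("none", nrow(groups))
    cls[dual] <- "other-dual"
    cls[red] <- "red"
    cls[blue] <- "blue"
    DataFrame(class = factor(cls, levels = c("red", "blue", "other-dual",
                                             "none")),
              dualResponsive = dual,
              row.names = rownames(groups))
}

#' Accessibility class of regions across cell types
#'
#' Each region is flagged accessible in a cell type when it overlaps (by at
#' least 1 bp) that cell type's accessible-region set. Labels, in precedence
#' order pan > specific > restricted:
#' \describe{
#'   \item{pan-accessible}{accessible in every provided cell type}
#'   \item{enterocyte-specific / ISC-specific}{accessible only in that type}
#'   \item{enterocyte-restricted / ISC-restricted}{accessible in that type
#'     plus at least one other, but not all}
#'   \item{other}{anything else, including regions overlapping no set}
#' }
#' When a region is accessible in both enterocytes and ISCs (but not all
#' types) the enterocyte-restricted label wins, keeping labels mutually
#' exclusive.
#'
#' @param regions `GRanges` of regions to classify.
#' @param accessibility named list of `GRanges`, one per cell type; must
#'   include `enterocyte` and `ISC`.
#' @return `DataFrame` with one logical `acc.<type>` column per cell type
#'   and a `label` factor.
#' @export
classifyAccessibility <- function(regions, accessibility) {
    types <- names(accessibility)
    if (length(types) < 2 || !all(c("enterocyte", "ISC") %in% types))
        stop("need >= 2 cell types including 'enterocyte' and 'ISC'")
    hit <- vapply(types, function(tp)
        countOverlaps(regions, accessibility[[tp]],
                      ignore.strand = TRUE) > 0,
        logical(length(regions)))
    hit <- matrix(hit, ncol = length(types), dimnames = list(NULL, types))
    nHit <- rowSums(hit)
    lab <- rep("other", length(regions))
    lab[nHit == length(types)] <- "pan-accessible"
    isc <- hit[, "ISC"]; ent <- hit[, "enterocyte"]
    only <- nHit == 1L
    some <- nHit > 1L & nHit < length(types)
    lab[only & ent] <- "enterocyte-specific"
    lab[only & isc] <- "ISC-specific"
    lab[some & ent] <- "enterocyte-restricted"
    lab[some & isc & !ent] <- "ISC-restricted"
    out <- DataFrame(hit, label = factor(lab, levels = c(
        "pan-accessible", "enterocyte-specific", "enterocyte-restricted",
        "ISC-specific", "ISC-restricted", "other")))
    names(out)[seq_along(types)] <- paste0("acc.", types)
    rownames(out) <- names(regions)
    out
}

#' Centered moving mean over an ordered series
#'
#' Mean over a sliding window of up to `window` consecutive sites advancing
#' one site at a time, truncated at the edges; missing values are excluded
#' from each window's mean, and an all-missing window yields `NA`. Used to
#' summarize per-site values (binding fractions, fold changes) along an
#' ordered site layout with the conventional 500-site window.
#'
#' @param x numeric series, already in the desired site order.
#' @param window window size in sites (default 500).
#' @return numeric vector, same length as `x`.
#' @export
movingMean <- function(x, window = 500L) {
    n <- length(x)
    if (!n) return(numeric(0))
    stopifnot(window >= 1)
    half <- window %/% 2L
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(lo + window - 1L, n)
    lo <- pmax(hi - window + 1L, 1L)
    ok <- !is.na(x)
    cs <- c(0, cumsum(ifelse(ok, x, 0)))
    cn <- c(0, cumsum(ok))
    s <- cs[hi + 1L] - cs[lo]
    m <- cn[hi + 1L] - cn[lo]
    ifelse(m > 0, s / m, NA_real_)
}

#' Two-sample Kolmogorov-Smirnov association test
#'
#' Two-sided two-sample KS test of whether the values linked to one feature
#' group are distributed differently from another group's. The exact p value
#' is computed when `length(a) * length(b) <= 10000` (and there are no ties,
#' as required by the exact method); otherwise the asymptotic approximation
#' is used. Either group with fewer than 3 values gives a missing p with a
#' warning.
#'
#' @param a,b numeric samples.
#' @return list with `D`, `p`, `exact`.
#' @export
associateDistributions <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    if (length(a) < 3 || length(b) < 3) {
        warning("fewer than 3 observations in a group; p value not computed")
        D <- suppressWarnings(
            stats::ks.test(a, b, exact = FALSE)$statistic)
        return(list(D = unname(D), p = NA_real_, exact = FALSE))
    }
    exact <- (as.double(length(a)) * length(b) <= 10000)
    kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
    list(D = unname(kt$statistic), p = kt$p.value,
         exact = exact && !any(duplicated(c(a, b))))
}

#' Per-compartment summary of fold changes
#'
#' Mean log2 fold change of features grouped by the crypt-villus compartment
#' of their linked gene, reported in crypt-to-villus-tip order, with counts.
#' Features without a compartment label are excluded; empty compartments get
#' a missing mean and a count of 0.
#'
#' @param log2FC numeric per-feature fold changes.
#' @param compartment per-feature compartment labels (character or factor).
#' @param levels compartment order, crypt first (default `crypt`, `V1`-`V4`
#'   with `V4` the villus tip, a conventional 5-zone layout).
#' @param group optional per-feature group labels for a per-group breakdown.
#' @return `DataFrame` with `compartment`, `n`, `mean` (and `group` when a
#'   breakdown is requested).
#' @export
compartmentSummary <- function(log2FC, compartment,
                               levels = c("crypt", "V1", "V2", "V3", "V4"),
                               group = NULL) {
    keep <- !is.na(compartment)
    log2FC <- log2FC[keep]
    compartment <- factor(as.character(compartment)[keep], levels = levels)
    one <- function(v, comp) {
        n <- as.integer(table(comp))
        mu <- as.numeric(tapply(v, comp, mean))
        DataFrame(compartment = factor(levels, levels = levels),
                  n = n, mean = mu)
    }
    if (is.null(group)) return(one(log2FC, compartment))
    group <- as.character(group)[keep]
    parts <- lapply(sort(unique(group)), function(g) {
        d <- one(log2FC[group == g], compartment[group == g])
        d$group <- g
        d
    })
    do.call(rbind, parts)
}
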