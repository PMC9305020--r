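---
title: "Integrative factorial analysis of transcriptome and chromatin counts"
author: "FactorialSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative factorial analysis of transcriptome and chromatin counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FactorialSeq)
```

# The experimental design and the model

FactorialSeq analyzes sequencing count data from a 2x2 factorial
experiment on the small intestinal epithelium: mice are either germ-free
(GF) or conventionalized with a microbiota (CV), and are sampled either
after normal feeding or two hours after a single high-fat meal (HFM).
The same four conditions are assayed at the transcript level (RNA-seq,
gene counts) and at the chromatin level (H3K27ac ChIP-seq quantified in
sliding windows over merged peaks; HNF4A ChIP-seq quantified per merged
peak).

For feature $i$ and sample $j$ the counts $K_{ij}$ are modeled as
negative binomial,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

with a log-linear mean

$$\log_2 \mu_{ij} = \log_2 s_j + \beta^0_i + \beta^m_i x_j +
\beta^f_i y_j + \beta^{mf}_i x_j y_j,$$

where $x_j$ indicates colonization, $y_j$ indicates the meal, and $s_j$
is the sample size factor. The four pairwise comparisons are linear
combinations of the coefficients:

| comparison | log2 fold change |
|---|---|
| CV/GF | $\beta^m$ |
| CV+HFM/GF+HFM | $\beta^m + \beta^{mf}$ |
| GF+HFM/GF | $\beta^f$ |
| CV+HFM/CV | $\beta^f + \beta^{mf}$ |

The interaction coefficient $\beta^{mf}$ is the log2 ratio of the meal
response with microbes to the meal response without microbes,
$\log_2[(\mathrm{CV{+}HFM}/\mathrm{CV}) / (\mathrm{GF{+}HFM}/\mathrm{GF})]$.
It is tested with a likelihood ratio test (LRT) of the full model
against the additive model that drops only the interaction term; the
statistic is referred to a $\chi^2_1$ distribution. Pairwise comparisons
use Wald tests of the corresponding coefficient combinations with
standard errors from the observed Fisher information.

## Estimation pipeline

1. **Size factors** are the median-of-ratios estimator: the median over
   reference features of a sample's count divided by the feature's
   geometric mean, rescaled so the size factors have geometric mean 1.
   When no feature is observed in every sample, geometric means are
   taken over positive counts only.
2. **Dispersions** are estimated per feature by a method of moments on
   the within-cell residuals of normalized counts (the estimator
   corrects the squared cell mean for its own sampling variance, which
   otherwise biases the dispersion downward), floored at $10^{-8}$. A
   trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted to the per-feature
   estimates with robust (Huber) regression, and the final dispersion
   geometrically interpolates the feature estimate toward the trend with
   weight `trendWeight` (default 0.7). With 2-5 replicates per cell the
   individual moment estimates are dominated by sampling noise, so most
   of the weight goes to the trend; setting the weight to 0 recovers the
   raw per-feature estimator and 1 the pure trend.
3. **GLM fitting** is iteratively reweighted least squares (IRLS) with
   working weights $\mu/(1 + \alpha\mu)$ at fixed dispersion, run to a
   coefficient change below $10^{-8}$ or 100 iterations. The full and
   reduced fits share the same per-feature dispersion so the LRT
   compares nested mean models. Coefficients are fitted on the natural
   log scale and reported in log2. Features with all-zero counts are
   dropped before fitting.
4. **Significance calls**: Benjamini-Hochberg adjustment is applied
   within each contrast separately. Three flags mirror the study's
   cutoffs: *standard* (padj < 0.05, the pairwise-comparison cutoff),
   *lenient gene* (p < 0.05 and baseMean > 10, for interaction genes),
   and *lenient window* (p < 0.01 and baseMean > 15, for interaction
   windows). `baseMean` is the mean of size-factor-normalized counts.

We deliberately fit the plain maximum-likelihood estimator: there is no
fold-change shrinkage, no independent filtering, and no outlier
replacement. This keeps the estimator transparent and easy to validate
against a derivative-free optimizer, at the cost of noisier fold-change
estimates for weakly expressed features than an empirical-Bayes
pipeline would give.

# Chromatin windows and peak-level calls

Merged ChIP peaks are tiled with 300 bp windows every 200 bp (100 bp
overlap). A peak no longer than 300 bp becomes one whole-peak window;
otherwise full-width windows start at offsets 0, 200, 400, ... and, when
the last full window stops short of the peak end, one extra end-anchored
window `[end - 300, end)` is added so every peak base is covered. How
sub-window peaks and trailing remainders should be tiled is genuinely
underdetermined; the end-anchored rule is our declared choice and the
window tests pin it down exactly.

Fragment counting uses the any-overlap rule (one or more base pairs), so
a fragment spanning two overlapping windows counts in both. Window-level
results are joined back to peaks: a peak is significant for a contrast
and direction when at least one of its windows carries the flag, and the
peak's reported statistics come from its minimum-p window (ties broken
by the leftmost window). Peak-level inference therefore never sums
correlated window counts.

# Directional groups, integration classes, and annotation

Each of the four contrasts splits its significant features into up- and
down-regulated sets, giving 8 directional significance groups. Pairwise
group overlap is reported both as raw counts and normalized by the
smaller group ($|g \cap h| / \min(|g|, |h|)$); the normalization is
configurable because "maximum overlap" admits more than one reading, and
raw counts are always written alongside.

Peaks responsive to both a +CV and a +HFM comparison are *dual
responsive*. Within these,

* **red** = CV+HFM/CV-up **and** CV+HFM/GF+HFM-up (meal-induced only in
  the colonized gut, microbially induced after the meal), and
* **blue** = GF+HFM/GF-up **and** CV+HFM/GF+HFM-down (meal-induced only
  in the germ-free gut, microbially suppressed after the meal).

Red and blue are disjoint by construction since they require opposite
directions of the CV+HFM/GF+HFM contrast. Dual-responsiveness is
evaluated at the peak level after window-to-peak joining.

Regions are linked to genes by nearest gene body (not TSS), ties broken
by the first gene in (chrom, start, end, name) order; binding sites per
gene are summed over these assignments with no distance cap and binned
as 0, 1-4, 5-10, and >10 sites. Chromatin sites are linked to DNase
hypersensitive sites (DHS) within 1 kb for motif work. Accessibility
labels across the four epithelial cell types (ISC, transit-amplifying,
enteroendocrine, enterocyte) classify each region as pan-accessible,
enterocyte/ISC-specific, enterocyte/ISC-restricted, or other, with
precedence pan > specific > restricted; a region accessible in both
enterocytes and ISCs (but not everywhere) takes the enterocyte-restricted
label so the labels partition the regions.

Ordered per-site series (binding fractions, fold changes along the
accessibility layout) are summarized with a centered moving mean over up
to 500 consecutive sites advancing one site at a time, truncated at the
edges, with missing values excluded per window. The site order is
supplied by the caller. Group-versus-group value distributions are
compared with the two-sided two-sample Kolmogorov-Smirnov test, exact
when $n \cdot m \le 10\,000$ and there are no ties, asymptotic
otherwise.

# Motif enrichment with reciprocal backgrounds

Position weight matrices are scanned as log-odds scores
$\sum_k \log_2(p_{k,b}/q_b)$ over both strands, skipping windows with N.
A 0.001 pseudocount is added per cell before log-odds, and the default
hit threshold is 60% of the motif's maximum achievable score — a
conventional operating point that keeps short high-information motifs
findable without flooding background sequence with hits. Enrichment uses
ZOOPS counting (a sequence either has a hit or it does not) and the
hypergeometric upper tail of the input hit count when drawing the input
set from the pooled input + background collection; a binomial
alternative is available. For the 8 directional groups, each direction's
linked DHS sequences are tested against the *reciprocal* direction of
the same contrast, both directions per contrast, skipping a pair when
either side has fewer than 5 linked sequences. The bundled PWM set is
synthetic (a nuclear-receptor-like direct repeat, a palindrome, and a
low-information control) and intended for testing; real analyses should
supply curated motif files.

# Sample-level statistics

PCA uses $\log_2(\text{normalized count} + 1)$, the 500 most variable
features (a standard plotting default), per-feature centering, and SVD.
A variance-stabilizing transform would be preferable for strongly
dispersed data but ties the ordination to the dispersion fit; the
log-plus-one transform is simple, monotone, and adequate for
visualization-scale inference. PERMANOVA runs separately per factor on
the Euclidean distances of the transformed matrix: the Gower-centered
inner-product matrix yields among-group and total sums of squares, the
pseudo-F is compared with seeded label permutations, and
$p = (1 + \#\{F^* \ge F\})/(1 + B)$, so $p$ can never fall below
$1/(B+1)$. $R^2$ is permutation-free. Sequential multi-factor
partitioning is out of scope; the per-factor $R^2$ values do not sum to
a joint-model decomposition.

# The synthetic data generator

`simConfig()` / `simulateFactorialData()` generate a complete miniature
study with known ground truth: non-overlapping stranded genes and merged
peaks on a small genome (defaults: two chromosomes of 4 and 3 Mb, 400
genes, 300 peaks), factorial NB counts at the three assays' replicate
layouts (RNA 4/4/4/4; H3K27ac 2/5/2/5; HNF4A 3/4/3/4), binding sites
placed inside gene bodies with 10% of genes receiving more than 10
sites, per-cell-type accessibility labels, one DHS inside each peak, and
DHS sequences with a nuclear-receptor-like consensus planted in regions
whose peak carries the negative-interaction truth class.

Effect classes and their planted log2 coefficients ($e$ drawn from a
positive normal, default mean 2, sd 0.5):

| class | $\beta^m$ | $\beta^f$ | $\beta^{mf}$ | recovered as |
|---|---|---|---|---|
| null | 0 | 0 | 0 | — |
| microbe | $\pm e$ | 0 | 0 | ±CV groups |
| meal | 0 | $\pm e$ | 0 | ±HFM groups |
| additive | $\pm e$ | $\pm e$ | 0 | both |
| interactionPos | 0 | 0 | $+e$ | red |
| interactionNeg | 0 | $+e$ | $-e$ | blue |

The interactionPos pattern is elevated only in CV+HFM and the
interactionNeg pattern only in GF+HFM, the two single-condition patterns
the integration classes are designed to capture. Base means are
log-uniform on [20, 2000]; dispersions follow the trend
$\alpha(q) = 0.05 + 2/q$, typical magnitudes for bulk sequencing at this
depth; library size factors are uniform on [0.7, 1.4]. The published
study does not report its library sizes or dispersion spread, so these
defaults are chosen as a realistic operating point for a desk-scale
experiment rather than a reproduction of any dataset. All randomness
derives from a single seed through fixed per-stage sub-seeds, so a
configuration reproduces its outputs exactly.

What the generator does **not** emulate: read-level artifacts (GC and
mappability bias, duplicate reads), fragment-size structure, correlated
counts between overlapping windows beyond what shared peak effects
induce, peak-calling noise, and biological correlation between the RNA
and chromatin layers (the two assays draw independent effects).
Passing recovery tests on this generator therefore demonstrates the
statistical machinery is correct under the stated model, not that real
libraries satisfy that model.

# Numerical choices and degenerate inputs

* IRLS guards the linear predictor to $|\eta| \le 30$; non-converged
  fits are flagged and their p values set missing.
* The LRT statistic is floored at 0, and fits where the reduced
  likelihood exceeds the full one beyond $10^{-6}$ carry a refit flag.
* Zero fold-change features cannot be assigned a direction and are
  excluded from the 8 groups with a warning.
* Empty directional groups give normalized overlap 0 and are listed in
  the overlap result; enrichment pairs with fewer than 5 linked
  sequences per side are skipped with a warning.
* An all-zero count matrix, a singleton PERMANOVA group, windows with
  `step > width`, and BED records with `start >= end` are errors.

# Problem sizes used in validation

The test-suite and acceptance checks run at desk scale, chosen so the
complete validation executes in minutes on one CPU: 5000 features for
null calibration, 2000 features (400 non-null) for interaction recovery,
200 random interval instances of up to 1000 intervals against
quadratic-time oracles, an end-to-end run with 200 genes and 250 peaks
for integration-class recovery, 20 seeds for planted-motif ranking, and
200 trials for KS/PERMANOVA calibration. The headline counts printed in
the original full-depth study (hundreds of interaction genes, thousands
of interaction windows) are functions of sequencing depth and replicate
number and are not reproduced at this scale; the package validates the
properties of the procedures instead.

# Known limitations

* The plug-in Wald/LRT tests treat the estimated dispersion as known;
  at 2-5 replicates per cell their null rejection rate at the 0.05 level
  sits nearer 0.06, the familiar small-sample anti-conservativeness of
  this test family.
* Median-of-ratios normalization assumes most features are unchanged;
  fixtures where every feature carries the same effect are absorbed
  into the size factors by design.
* Nearest-gene linkage uses gene bodies; a TSS mode would change
  assignments for long genes.
* The exact KS p value is unavailable under ties; the asymptotic value
  is used there regardless of sample size.
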