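# FactorialSeq

Integrative differential analysis of transcriptome and chromatin
sequencing counts under a 2×2 factorial design: microbiota colonization
(germ-free **GF** vs conventionalized **CV**) crossed with a single
high-fat meal (**HFM**), the paired perturbation used to study how the
small intestinal epithelium integrates microbial and nutritional
signals. The package is aimed at analysts who have gene-level RNA-seq
counts and peak/window-level ChIP-seq counts (e.g. H3K27ac, HNF4A) from
all four conditions and want the full path from raw counts to
interaction calls, regulatory-region classes, and motif enrichment.

## The model

Counts for feature *i* in sample *j* are negative binomial with
variance μ + αμ² and a log-linear mean

```
log2 mu_ij = log2 s_j + beta0_i + betaM_i * x_j + betaF_i * y_j + betaMF_i * x_j * y_j
```

where `x` indicates microbes, `y` indicates the meal, and `s_j` is a
median-of-ratios size factor. The four pairwise comparisons (CV/GF,
CV+HFM/GF+HFM, GF+HFM/GF, CV+HFM/CV) are Wald tests of coefficient
combinations; the microbe-by-meal interaction `betaMF` — the log2 ratio
of the meal response with microbes to the meal response without — is
tested by a likelihood ratio test against the additive model (χ², 1 df).
Dispersions come from a bias-corrected method of moments shrunk toward a
fitted α(μ) = a₀ + a₁/μ trend; GLMs are fitted by iteratively
reweighted least squares.

Downstream, the package provides: 300 bp / 200 bp-step window tiling of
merged ChIP peaks with min-p window→peak joining; the 8 directional
significance groups and their overlap matrices; "red" (meal-up with
microbes, microbe-up after the meal) and "blue" (meal-up without
microbes, microbe-down after the meal) integration classes;
enterocyte/ISC accessibility classification; nearest-gene annotation and
binding-sites-per-gene bins (0, 1–4, 5–10, >10); PWM scanning with
ZOOPS/hypergeometric enrichment against reciprocal-direction
backgrounds; PCA and per-factor PERMANOVA; and a synthetic-data
generator with known ground truth that exercises the whole pipeline.

## Worked example

```r
library(FactorialSeq)

sim <- simulateFactorialData(simConfig(nGenes = 120, nPeaks = 80, seed = 2))
sim$rna
#> class: FactorialExperiment
#> dim: 120 16
#> ...
#> condition replicates: GF=4 GF+HFM=4 CV=4 CV+HFM=4

res <- factorialResults(sim$rna)
head(res[["CV/GF"]][order(res[["CV/GF"]]$padj), ], 4)
#>              baseMean log2FC     SE p padj standard
#> gene_00117 14568.3705 2.4833 0.1937 0    0        1
#> gene_00026  2649.7840 2.7473 0.2488 0    0        1
#> gene_00112   507.0912 1.9102 0.2303 0    0        1
#> gene_00098  3448.9451 1.8629 0.2366 0    0        1
```

`res` holds one table per pairwise contrast plus `res$interaction` (the
LRT). `log2FC` is the contrast fold change, `padj` the within-contrast
BH adjustment, and `standard` / `lenientGene` / `lenientWindow` the
significance flags at the conventional cutoffs (padj < 0.05; p < 0.05 &
baseMean > 10; p < 0.01 & baseMean > 15). Group membership and
sample-level separation:

```r
g <- assignDirectionalGroups(res)
colSums(as.data.frame(g[, -(1:4)]))   # sizes of the 8 directional groups
#>       CV.GF.up     CV.GF.down  CV.HFM.GF.HFM.up  CV.HFM.GF.HFM.down
#>              9             14                16                  24
#>   GF.HFM.GF.up GF.HFM.GF.down      CV.HFM.CV.up      CV.HFM.CV.down
#>             23             15                19                  12

sampleStats(sim$rna, nPerm = 999, seed = 2)$permanova
#>     factor        F        R2     p nPerm
#> 1 microbes 6.951324 0.3317845 0.002   999
#> 2     meal 8.319578 0.3727480 0.001   999
```

Both factors separate the samples (PERMANOVA R² ≈ 0.33 and 0.37), as
expected since the generator planted microbe, meal, and interaction
effects in about half the genes. The full pipeline — window testing,
peak joining, integration classes, accessibility labels, sites-per-gene,
motif enrichment, ordination — runs from one config:

```r
runPipeline(list(seed = 2, outputDir = "run",
                 simulate = list(nGenes = 120, nPeaks = 80)))
```

and writes one TSV per stage plus a JSON manifest. A command-line front
end with per-stage subcommands (`simulate`, `validate`, `de-genes`,
`de-windows`, `join`, `classify`, `annotate`, `motifs`, `stats`,
`run-all`) is installed at
`system.file("scripts", "factorialseq.R", package = "FactorialSeq")`.

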