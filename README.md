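# tzrsig

Integrative identification of mRNAs and lincRNAs associated with
trastuzumab resistance in HER2-positive breast cancer.

Roughly 25–30% of early-stage breast tumors are HER2-positive and are
treated with the monoclonal antibody trastuzumab, but a substantial
fraction of patients develop resistance. A recurring strategy for finding
the genes that drive resistance is to cross clinical tumor profiling with
isogenic cell-culture models: genes differentially expressed between
responder and non-responder tumors *in vivo*, and between
trastuzumab-sensitive (TzS) and chronically resistant (TzR) cell lines
*in vitro*, with the acute drug response removed, converging on a small
stable-resistance signature whose regulation can then be examined at the
enhancer level. `tzrsig` implements that integrative procedure as a
reusable, fully tested pipeline, together with a synthetic-data generator
that plants known truth so every stage can be validated end to end.

## The method

**Expression gating.** A gene enters the analysis only if its FPKM is at
or above a biotype-specific floor in *every* sample of at least one of the
two groups being compared: ≥ 1.0 for mRNAs, ≥ 0.25 for lincRNAs.

**Differential calling, two modes.** With condition means m₁ (resistant)
and m₀ (sensitive) and pseudocount c (default 0.01), the fold change is
FC = (m₁ + c)/(m₀ + c), and a gene is differential when FC ≥ 2.0 or
FC ≤ 0.5:

* *tumor mode* — fold change only. The design this serves is an
  11-responder vs 2-non-responder cohort, where n = 2 makes a per-gene
  test statistic meaningless;
* *cell-line mode* — additionally a two-sided paired t-test on
  log₂(FPKM + c) across replicate pairs, requiring p < 0.05.

**Set integration.** Genes responding to short-term (48 h) drug exposure
of sensitive cells are subtracted (by id) from the cell-line differential
set; the remainder is intersected with the in-vivo set requiring
*concordant direction* (same sign of log₂FC). Overlap enrichment is
assessed with a two-tailed Fisher exact test — the exact hypergeometric
point-probability rule over a universe of genes gated in both datasets.

**Enhancer analysis.** High-confidence ChIP-seq peaks (−log₁₀ p > 9, i.e.
p < 1e-9) for H3K4me1 and H3K27ac are assigned to signature genes when the
peak midpoint lies within 150 kb of the TSS. Per peak, the statistic is
log₂((s₁ + c)/(s₀ + c)) of mean track signal (each track normalized to
length-weighted mean 1), and per gene × mark the median of those ratios —
elevated medians indicate enhancer remodeling consistent with the
expression change.

A `2^−ΔΔCt` helper for qPCR validation is included.

## Worked example

```r
library(tzrsig)

bundle <- simulate_bundle(sim_config(seed = 1))
bundle$expression
#> ExpressionMatrix: 2000 genes x 25 samples
#>   biotypes: lincRNA=300, mRNA=1700
#>   dataset tumor : TzR=2, TzS=11
#>   dataset cellline : TzR=3, TzS=3 (paired)
#>   dataset shortterm : mock=3, treated=3 (paired)

dir <- file.path(tempdir(), "bundle"); write_bundle(bundle, dir)
res <- run_pipeline(pipeline_config(dir, file.path(tempdir(), "run"), seed = 1))
#> ...
#> integrated signature: 27 mRNAs, 3 lincRNAs (Fisher p = 3.21e-28)

res$fisher$pooled
#> $universe    1982      # genes gated in both datasets
#> $n_a         69        # tumor differential genes
#> $n_b         70        # cell-line differential genes after subtraction
#> $overlap     30        # concordant intersection
#> $p_two_tailed 3.214551e-28
#> $odds_ratio  36.01923

truth_report(bundle$truth$genes, res$integrated)
#>     scope tp fp fn   tn sensitivity specificity fdr
#> 1 overall 30  0  0 1970           1           1   0
#> 2    mRNA 27  0  0 1673           1           1   0
#> 3 lincRNA  3  0  0  297           1           1   0

head(res$enhancer$summary, 4)
#>   gene_id    mark n_peaks median_log2_ratio
#> 1  G00151 H3K4me1       6         0.9279637
#> 2  G00161 H3K4me1       6         0.9346686
#> 3  G00261 H3K4me1       6         0.9635729
#> 4  G00276 H3K4me1       6         0.9028335
```

The simulated cohort plants 30 genes at |log₂FC| = 2 concordantly in both
datasets; the pipeline recovers all 30 with no false positives, the
overlap is far beyond chance (p ≈ 3e-28 against a 1982-gene universe), and
genes carrying a 2× resistant-condition ChIP signal shift show per-gene
median log₂ ratios near 1, as a doubled enhancer signal should.

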