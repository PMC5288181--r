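---
title: "Methods: integrative trastuzumab-resistance signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative trastuzumab-resistance signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tzrsig)
```

# The problem and the procedure

Trastuzumab-resistant (TzR) HER2+ tumors are expected to differ
transcriptionally from sensitive (TzS) tumors, but any single comparison is
confounded: clinical cohorts are small and heterogeneous, cell-line
contrasts are clean but artificial, and genes that merely respond acutely
to the drug are uninteresting for *stable* resistance. The procedure
implemented here triangulates:

1. **Tumor contrast** (*in vivo*): responders vs non-responders, called by
   fold change alone.
2. **Cell-line contrast** (*in vitro*): isogenic TzS vs chronically
   resistant TzR lines, called by fold change plus a paired t-test.
3. **Short-term contrast**: mock vs 48-h-treated sensitive cells; its
   differential genes are *subtracted* from the cell-line list, leaving
   only stable-resistance candidates.
4. **Concordant intersection**: a gene survives only if differential in
   both the tumor and the post-subtraction cell-line lists *with the same
   direction*; the overlap is tested for enrichment with a two-tailed
   Fisher exact test.
5. **Enhancer analysis**: per signature gene, the distribution of
   log2 ChIP signal ratios (TzR/TzS) at high-confidence H3K4me1 and
   H3K27ac peaks within 150 kb of the TSS, summarized by its median.

Subtraction deliberately precedes intersection, so the Fisher table
compares the in-vivo set against the *stable* cell-line set.

# Calling rules and their parameters

| parameter | default | meaning |
|---|---|---|
| `fpkm_min_mrna` | 1.0 FPKM | mRNA expression floor for the gate |
| `fpkm_min_lincrna` | 0.25 FPKM | lincRNA floor (lincRNAs are expressed lower) |
| `fc_up`, `fc_down` | 2.0, 0.5 | fold-change cutoffs, inclusive |
| `alpha` | 0.05 | paired-test cutoff, strict `<` |
| `pseudocount` | 0.01 FPKM | added to means and inside log2 |
| `p_threshold_neglog10` | 9 | peak filter, strict `>` (p < 1e-9) |
| `window_bp` | 150,000 bp | TSS-to-peak-midpoint distance, inclusive |
| `signal_pseudocount` | 0.5 | guards zero-coverage peaks in ratios |

**The gate is group-uniform:** a gene passes when *every* sample of at
least one condition reaches its biotype floor. Gating before testing means
a gene whose expression collapses to zero in one condition is still
testable — the other condition carries it through — while genes expressed
nowhere are excluded rather than producing pseudocount-ratio artifacts.

**Boundary conventions.** All printed thresholds are taken at face value:
the gate and the fold-change cutoffs are inclusive (`>=`, `<=`), the
p-value criterion and the peak filter are strict (`<`). Sources describing
this family of analyses are not always internally consistent about
`p < 0.05` vs `p <= 0.05`; this package fixes the strict form and exposes
`alpha` should a user want otherwise.

**Tumor mode computes no p-value.** With two non-responders a per-gene
variance estimate is near-meaningless; the fold-change-only rule is the
honest procedure for that design, and the package keeps the two modes
explicit rather than silently switching on sample size.

**The paired t-test** is computed in closed form on the per-pair
log2(FPKM + c) differences, two-sided. Log transformation makes up- and
down-regulation symmetric and the lognormal noise approximately Gaussian.
The degenerate all-pairs-equal case is defined as t = 0, p = 1 (a gene
with no evidence of change), and a zero-variance nonzero difference as
p = 0; generic R t-test implementations refuse constant data, so the
closed form also buys well-defined edge behavior. No multiple-testing
correction is applied by default, matching the per-gene rule this
procedure historically used; `adjust_method = "BH"` is available.

**Fisher's exact test** uses the hypergeometric point-probability rule:
the two-tailed p is the sum of probabilities of all tables (same margins)
whose point probability does not exceed the observed one, with a relative
tie tolerance of 1e-7 — the convention of standard exact-test
implementations. Probabilities come from `dhyper`; no normal
approximation is involved at any size. The reported odds ratio is the
sample odds ratio (ad/bc, infinity allowed), not the conditional MLE.

**The Fisher universe** is the procedure's one genuinely unstated
parameter: enrichment depends on which genes *could* have been called.
The default universe is the genes passing the expression gate in **both**
datasets (`fisher_universe = "both_gated"`), computed pooled and also per
biotype; `"all"` uses every gene in the matrix. Pooled-vs-per-biotype
testing is reported side by side since either convention is defensible.

**Heatmap standardization** z-scores each differential gene's
log2(FPKM + c) profile across samples with the n−1 standard deviation;
constant rows map to zeros. Row-wise "Z score of log expression" is
ambiguous between per-sample values and per-pair fold changes; per-sample
values are used because they are what a genes × samples heatmap displays.

# Enhancer-level choices

Distance is measured TSS to peak *midpoint* (`floor((start+end)/2)`),
matching the one-dot-per-peak view the summary feeds; "within 150 kb" is
inclusive. Per-peak signal is the length-weighted mean of the normalized
track over the peak interval (summit height would be an alternative; the
mean is robust to ragged peak shapes and is well defined for bedGraph
input at any step size). Tracks are normalized to length-weighted mean 1
over covered bases before ratios, so a global scale factor between
conditions cancels exactly. Peaks present in either condition's filtered
set are analyzed (union), with the signal pseudocount guarding one-sided
zeros. The per-gene median uses the mean-of-middles convention for even
counts; a gene × mark with zero assigned peaks is omitted from the summary
with a notice rather than propagating NaN.

# What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions end to end: 2,000
genes (15% lincRNA), an 11-responder vs 2-non-responder tumor cohort,
3 paired cell-line replicates, a 3-pair mock vs 48-h contrast, 30 planted
concordant genes at |log2FC| = 2 plus 40 in-vivo-only, 40 in-vitro-only
and 30 short-term-response genes (all disjoint), lognormal noise with
sigma = 0.2 on the log2 scale, and per-pair batch offsets (sd 0.3) that
give the paired test something to gain over an unpaired one. The number
of cell-line replicates behind such paired designs is rarely reported;
three pairs is a deliberate, typical choice.

Expression is `2^(baseline + effect + noise)`. mRNA baselines are
N(5, 2) on the log2 scale and lincRNA baselines are shifted down by 3, so
roughly 98% of genes clear the gate — the gate is tested by the data, not
trivially satisfied — while the 0.25 lincRNA floor is genuinely
exercised. Short-term genes are perturbed only in the treated samples.

On the chromatin side, one synthetic chromosome carries one TSS per
160 kb. Sixty genes receive local peaks (six per mark, placed in
non-overlapping slots within ±120 kb of the TSS): the 30 planted
concordant genes, whose peaks carry a 2× resistant-condition signal
shift, and 30 unplanted background genes, whose peaks do not.
Peak-bearing genes are kept ≥ 800 kb apart so no two 150-kb windows share
peaks. Per-peak ratio noise has sd 0.1 on the log2 scale (split
sqrt(2)-evenly between the two condition tracks). Tracks also tile 25% of
the chromosome with baseline coverage, which keeps the whole-track
normalization from transferring the planted shift into an appreciable
background bias (the residual is about −0.03 log2 units, visible in the
background medians). An additional 150 unshifted peaks and 150
below-threshold peaks per mark exercise window assignment and the
significance filter.

The simulator does **not** model: count-level sampling noise or
length/GC bias in FPKM estimation, tumor purity and stromal
contamination, patient-level covariates, correlated co-regulated gene
modules, mappability or copy-number structure (notably the HER2 amplicon
itself), replicate peak-calling discordance, or fragment-level ChIP
background. Passing the planted-truth tests therefore demonstrates that
the pipeline's logic is correct and well-calibrated under its stated
noise model — not that real cohorts of this size would yield equally
clean recovery; with n = 2 non-responders, real fold-change-only calls
are far noisier than lognormal sigma = 0.2 implies.

# Numerical and degenerate-input conventions

* Fold changes use `(mean + c)/(mean + c)` with c = 0.01; the gate makes
  both-means-zero impossible, and c bounds one-sided-zero ratios.
* Exact-test enumeration is over the hypergeometric support only; the
  all-table invariants are verified against an exact-integer enumerator
  (binomial coefficients below 2^53) in the test suite.
* All genomic coordinates are 0-based half-open (BED convention); the TSS
  is a single base. Coordinates are never shifted on I/O.
* Writers emit fixed 10-significant-digit formatting, LF endings and no
  quoting, so identical inputs give byte-identical outputs; the run
  manifest records input checksums, config and package version.
* The only randomness in the package is the simulator's, driven by one
  seed; the pipeline itself is a pure function of its inputs.

# Problem sizes used by the test suite

Unit and property tests run on matrices of tens to hundreds of genes with
brute-force oracles (all-pairs window scans, exhaustive exact-test
enumeration up to a 40-gene universe, per-gene `t.test` recomputation).
End-to-end recovery tests use the full 2,000-gene default bundle;
structural pipeline tests use a 400-gene bundle with proportionally
smaller planted sets, where recovery is asserted for gate-passing planted
genes (at 10 planted genes per bundle, an occasional low-baseline draw
legitimately falls below the expression floor).

# Known limitations

* FPKM is assumed pre-normalized; no library-size or batch correction is
  applied (out of scope by design).
* The concordance rule compares direction only, not magnitude.
* Enhancer analysis is descriptive — no per-peak differential-binding
  statistics are computed, matching the procedure it implements.
* The Fisher universe choice materially affects p-values; both supported
  policies are stated above, and users comparing against other analyses
  should check which universe those used.
* Annotation is opaque user input; no gene catalog ships with the
  package.
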