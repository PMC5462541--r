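---
title: "Bin-based DMR calling and multi-replicate conservation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based DMR calling and multi-replicate conservation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbin)
library(data.table)
```

## The problem

Plant methylomes carry 5-methylcytosine in three sequence contexts — CG,
CHG and CHH (H = A, T or C) — laid down and maintained by distinct
pathways. When a mutant is screened for methylation changes by
whole-genome bisulfite sequencing (WGBS), two facts dominate the
analysis. First, per-cytosine counts are noisy: a typical experiment
gives ~30x coverage and >= 97% bisulfite conversion, so single-cytosine
differences are unreliable. Second, methylation varies naturally between
individuals — even siblings of the same ecotype differ at many loci
("hypervariable regions") — so most differences between any one
mutant-control pair are not caused by the mutation. A credible claim
that a region depends on a gene therefore needs (a) a statistically
controlled per-comparison test and (b) evidence of *conservation* of the
change across independent alleles and biological replicates.

`methbin` implements this workflow end to end: binned per-comparison
DMR calling with context-specific effect-size thresholds and FDR
control; "direct" conservation by N-way interval intersection;
"relaxed" conservation by concordance across a DMR-by-sample
methylation matrix; merging of conserved windows into loci; and the
targeted assays (region quantification, clone bisulfite summaries,
McrBC-qPCR) used to validate individual loci.

## The per-comparison model

The genome is tiled into 100-bp non-overlapping bins (the final partial
bin of each chromosome is kept). Within a bin, for one context, counts
are pooled over all cytosines on both strands with per-cytosine coverage
`n >= 4`:

* `m_sum = sum(m)`, `n_sum = sum(n)`, `level = m_sum / n_sum`.

A bin is *eligible* when it has at least 4 such cytosines in **both**
samples and non-zero pooled coverage in both. For each eligible bin the
2x2 table `[(m_sum, n_sum - m_sum)_mutant; (m_sum, n_sum - m_sum)_control]`
is tested with a two-sided Fisher exact test (sum of all hypergeometric
outcome probabilities not exceeding the observed one). P-values are
adjusted by Benjamini-Hochberg **per context and per comparison** —
contexts are called independently and never share one adjustment family.
A bin is a DMR when

* `q <= 0.01`, and
* `|level_mut - level_ctl| >= 0.40` (CG), `0.20` (CHG) or `0.10` (CHH),

with direction hyper/hypo given by the sign of the difference. The
choice of the Fisher exact test on pooled bin counts is a design
decision of this package: the binned-counts setting fully specifies it,
it is standard for WGBS count comparisons, and it is exactly testable
against an enumeration oracle (the test suite checks agreement to
1e-12 on every table with total <= 50). The interface keeps the test
pluggable: `call_dmrs()` consumes `aggregate_bins()` output, so an
alternative statistic can be slotted in without touching the
aggregation or thresholding.

Pooling counts across cytosines within a bin treats reads at different
cytosines as exchangeable evidence about one regional level; it does
not model biological replicate dispersion. That is deliberate: the
design compares *sample pairs* and pushes replication into the
conservation stage, instead of fitting a dispersion model across
replicates.

## Conservation across comparisons

**Direct.** A window is conserved when it is called independently in
every one of the N comparisons (here, six: three replicates of one
allele, each against its own control, plus three further alleles). Sets
are intersected genomically and the intersection is chopped back into
100-bp pieces (remainder kept) so counts stay comparable with
per-comparison windows; depth stacking also reports windows present in
at least k of the N sets. Intersection is delegated to
GenomicRanges and verified against a per-basepair bitmap oracle.

**Relaxed.** Direct overlap is stringent: a window that misses one
comparison's effect-size cutoff by a hair is discarded. The relaxed
route builds master lists (the union of all per-comparison DMR windows
for one context and direction), quantifies every window in every sample
(pooled level, rounded to 3 decimals — rounding cannot flip a selection
when the true difference exceeds 0.002), and selects windows whose
change is *concordant*: every mutant value lies on the `direction` side
of the control mean, with no re-imposed magnitude or coverage cutoff.
The original workflow made this selection by eye on an
average-linkage/absolute-correlation clustered heatmap; an automated
sign rule is this package's default because it is deterministic and
testable, and a `mode = "cluster"` variant (select whole clusters of a
dendrogram cut in which all rows pass the sign rule) preserves the
shape of the manual workflow. Because the manual step was a human
judgment, no automated rule is expected to reproduce manually curated
counts exactly.

CG-context relaxed sets are filtered against body-methylated genes
(>= 1 bp overlap): gene-body CG methylation is known to vary strongly
between individuals and would otherwise flood the conserved set.
Heatmap display order is the mutant-minus-control mean difference
(mean over all mutant columns minus mean over all control columns),
largest first, ties broken by coordinate.

**Loci.** Conserved windows are merged into loci across contexts and
directions when they overlap or lie within 300 bp — the same distance
used for same-context merging — and each locus reports its member
contexts and a direction summary. The merged "hyper mC" regions used
for cross-mutant comparisons come from same-context 300-bp merging
followed by a cross-context union joining overlapping or directly
adjacent (gap exactly 0) regions.

All interval arithmetic is 0-based half-open, everywhere.

## The synthetic methylome generator

Every stage is testable without external data because the generator
produces the exact input format the callers consume, with known truth.

* **Reference**: seeded random sequence; each chromosome tiled into
  2-kb blocks assigned to `TE_like`, `gene_body_CG` or `unmethylated`
  compartments (defaults 20/20/60%). Unannotated sequence defaults to
  unmethylated. Cytosines within 2 bp of a sequence end whose
  trinucleotide cannot be resolved are dropped.
* **Baselines** (true methylation probability per class and context):
  TE-like 0.85/0.65/0.10 (CG/CHG/CHH), gene-body 0.40/0/0,
  unmethylated 0/0/0 — typical Arabidopsis-like organisation: heavily
  methylated repeats, CG-exclusive gene bodies, clean background.
* **Sequencing model**: per-cytosine coverage ~ Poisson(30),
  independent across sites (only the average coverage is specified by
  the study design, so the simplest count model consistent with it is
  used); methylated reads ~ Binomial(n, p + (1-p)(1-c)) with
  conversion `c = 0.995` by default — non-conversion inflates apparent
  methylation of unmethylated cytosines, which is what the conversion
  estimator (pooled `1 - m/n` over designated unmethylated regions)
  inverts. How conversion was estimated in any given real study is
  often unstated; the estimator's designated-region convention is this
  package's own and is documented as such.
* **Planted effects**: shared DMRs (all mutants) and replicate-private
  hypervariable regions (one sample, per-replicate delta draws) are
  placed on the 100-bp bin grid, inside a single compartment, with at
  least 4 context cytosines — so "recovered" is well defined — and
  never overlap each other. Strands are simulated separately and
  symmetric CG pairs are not merged, matching per-cytosine call files
  from standard mapping tools.

What the generator does *not* emulate: read-level artifacts (mapping
bias, PCR duplicates), correlated coverage (GC waves, copy-number),
spatially autocorrelated methylation within compartments, and partial
overlap of effects with bin boundaries. Passing recovery tests
therefore demonstrate the correctness and calibration of the
*pipeline*, not the field performance of the thresholds on real data.

## Numerical choices and degenerate inputs

* Fisher p-values use the conventional `(1 + 1e-7)` relative tolerance
  when comparing outcome probabilities to the observed one, matching
  `stats::fisher.test`; agreement with that routine and with exhaustive
  enumeration is tested.
* Bins with zero pooled coverage in either sample are ineligible even
  if they pass the cytosine-count rule; contexts with zero qualifying
  coverage report `NA` ("undefined"), never 0.
* A zero-variance matrix row has undefined correlation; it is assigned
  the maximal distance (1) to every other row and reported.
* Clustering ties follow `stats::hclust` order; ranking ties are broken
  by genomic coordinate.
* McrBC values below 0 (treated amplifying before mock) are preserved
  with a warning by default (`clip0 = TRUE` clips); a treated reaction
  with no amplification reports 100%, a mock with none is undefined.
* Clone filtering defaults (remove a clone when >= 95% of >= 5
  informative CHH positions in a 150-bp window are methylated while the
  across-clone mean there is < 20%) are explicit parameters: published
  protocols typically say only that "a small number" of clonal or
  non-converted sequences were removed, so the rule is conservative and
  declared rather than implied.
* Targeted-region coordinates are 1-based inclusive by default, as
  printed in figure legends; the off-by-one conversion is covered by a
  dedicated test.

## Problem sizes used by the tests and acceptance script

Chosen as the package's own validation design: the type-I/null check
simulates six comparisons on a 2-Mb genome at 30x (20 seeds in the test
suite, 8 in the acceptance script); recovery plants 50 shared plus 30
private CG DMRs on a 1-Mb genome; the full-pipeline demonstration runs
a 500-kb genome with 8 shared and 25 private regions per sample, so
private variation dominates each comparison's list the way natural
variation dominates real screens. Interval algebra is verified on 200
random 10-kb fixtures against per-basepair bitmaps; the Fisher oracle
sweeps every table with total <= 50.

## A worked miniature

```{r mini, message = FALSE, warning = FALSE}
ref <- build_reference(c(chr1 = 1e5), seed = 402)
truth <- plant_dmrs(ref,
  data.frame(n = 10, context = "CG", direction = "hyper", delta = 0.5),
  mutant_ids = "mut1", seed = 5)
mut <- simulate_sample(ref, sample_profile("mut1", "mutant", seed = 21), truth)
ctl <- simulate_sample(ref, sample_profile("ctl1", "control", seed = 22), truth)
calls <- compare_methylomes(mut, ctl, comparison_id = "mut1_vs_ctl1")
dmrs <- dmr_intervals(calls)
dmrs[, .(chrom, start, end, context, direction, delta = round(delta, 3))]
```

All ten planted windows return, at their planted coordinates and
effect size, and nothing else is called.

## Known limitations

* No smoothing or HMM segmentation: resolution is the 100-bp bin, and
  an effect straddling a bin boundary dilutes into both bins.
* No replicate dispersion model: a consistently noisy sample pair can
  only be caught at the conservation stage.
* The sign-concordance rule has no magnitude floor by design; with few
  control samples its null selection rate is bounded by chance
  concordance (about `0.5^N_mutants` per direction) rather than by an
  explicit error rate.
* Locus convergence depends on the merge distance; counts on real data
  are sensitive to that choice and the 300-bp default is simply kept
  consistent with the same-context merge distance.
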