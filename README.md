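# methbin

Bin-based differential methylation analysis for whole-genome bisulfite
sequencing (WGBS), with multi-replicate conservation.

## What it is for

Plant genomes are methylated in three cytosine sequence contexts — CG,
CHG and CHH (H = A, T or C). When a mutant is screened for methylation
changes against its paired control, per-cytosine WGBS counts are noisy
and natural epigenetic variation between individuals produces many
differences that have nothing to do with the mutation. `methbin` is for
analysts running such screens: it calls differentially methylated
regions (DMRs) per comparison with full statistical control, then asks
the harder question — which DMRs are *conserved* across independent
alleles and biological replicates?

## The model

The genome is tiled into 100-bp non-overlapping bins. Per bin and
context, counts are pooled over all cytosines (both strands) with
coverage n ≥ 4; bins with ≥ 4 such cytosines in both samples are tested
with a two-sided Fisher exact test on the pooled 2×2 table

    [ m_mut,  n_mut − m_mut ]
    [ m_ctl,  n_ctl − m_ctl ]

with Benjamini–Hochberg adjustment per (comparison × context). A bin is
a DMR when q ≤ 0.01 and |Δ| = |level_mut − level_ctl| exceeds the
context threshold: 0.40 (CG), 0.20 (CHG), 0.10 (CHH). Conservation is
assessed two ways: **direct** N-way genomic intersection of the
per-comparison DMR sets (re-chopped into 100-bp windows), and a
**relaxed** route that unions all per-comparison DMRs into master
lists, quantifies each window in every sample and keeps windows whose
change is sign-concordant in all mutants relative to the control mean,
filtered against body-methylated genes. Conserved windows within
300 bp merge into loci. A seeded synthetic-methylome generator
(compartmentalised baselines, Poisson coverage, binomial counts with
bisulfite non-conversion, planted shared DMRs and replicate-private
hypervariable regions) makes the whole pipeline testable with known
truth. Targeted assays — windowed quantification, clone-based
bisulfite summaries with clone filtering, and McrBC-qPCR relative
methylation `100 − 100·2^(Ct_mock − Ct_treated)` — cover locus-level
validation.

## Worked example

Plant ten CG hyper-DMRs (Δ = +0.5) on a 100-kb synthetic genome,
simulate a mutant and a control at 30× coverage, and call DMRs:

```r
library(methbin)
ref   <- build_reference(c(chr1 = 1e5), seed = 402)
truth <- plant_dmrs(ref,
           data.frame(n = 10, context = "CG", direction = "hyper", delta = 0.5),
           mutant_ids = "mut1", seed = 5)
mut <- simulate_sample(ref, sample_profile("mut1", "mutant",  seed = 21), truth)
ctl <- simulate_sample(ref, sample_profile("ctl1", "control", seed = 22), truth)
calls <- compare_methylomes(mut, ctl, comparison_id = "mut1_vs_ctl1")
dmr_intervals(calls)[, .(chrom, start, end, context, direction, delta = round(delta, 3))]
#>      chrom start   end context direction delta
#>  1:   chr1 11100 11200      CG     hyper 0.504
#>  2:   chr1 16900 17000      CG     hyper 0.526
#>  3:   chr1 30800 30900      CG     hyper 0.511
#>  4:   chr1 32300 32400      CG     hyper 0.477
#>  5:   chr1 52900 53000      CG     hyper 0.488
#>  6:   chr1 54500 54600      CG     hyper 0.522
#>  7:   chr1 70500 70600      CG     hyper 0.541
#>  8:   chr1 77000 77100      CG     hyper 0.509
#>  9:   chr1 78100 78200      CG     hyper 0.427
#> 10:   chr1 98000 98100      CG     hyper 0.475
```

Exactly the ten planted windows are called, at their planted
coordinates, with observed effect sizes scattered around the planted
Δ = 0.5 by binomial noise — and nothing else. `run_pipeline(run_config())`
drives the same machinery across a full six-comparison roster
(3 replicates of one mutant + 3 further mutants, each with a paired
control) and writes per-comparison tables, direct-overlap and relaxed
BED files, merged hyper-mC regions, a loci list and a JSON manifest of
the DMR → window → locus funnel.

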