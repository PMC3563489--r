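---
title: "Evaluating rRNA depletion in bacterial RNA-seq: methods and design"
author: "ribofree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating rRNA depletion in bacterial RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofree)
```

## The problem

Ribosomal RNA makes up roughly 95--98% of a bacterial cell's total RNA.
An RNA-seq library prepared from untreated total RNA therefore spends
almost every read on rRNA: at 40 million reads, an untreated library of
a GC-rich bacterium may leave only ~10% of protein-coding genes with
enough reads to analyse. Depletion protocols remove rRNA before
sequencing -- by hybridisation capture of the 16S/23S molecules, by
selective (not-so-random) priming during cDNA synthesis, or both -- but
each chemistry can distort the mRNA fraction it is meant to preserve.

`ribofree` quantifies both sides of that trade-off: how much rRNA a
treatment removes (and how much sequencing that saves), and how much it
perturbs mRNA relative abundances and differential-expression profiles.

## Read-category accounting

Mapped reads are classified against a genome annotation into **rRNA**,
**mRNA** (CDS), **other** (annotated non-CDS, non-rRNA features) and
**intergenic**, using at least 1 bp of overlap and the priority
rRNA > CDS > other > intergenic. The priority resolves
overlapping-feature ambiguity conservatively toward rRNA, so the
reported mRNA percentage is never inflated by reads that also touch an
rRNA gene. Counting is strand-agnostic by default; both the overlap
threshold and strandedness are arguments of `classify_reads()`.

Two conventions deserve emphasis because published summary tables
rarely state them:

* **Percentages are of mapped reads**, not of total reads. The bundled
  study table is only consistent under this denominator (its control
  row sums to ~100% of mapped reads).
* **Replicates are averaged arithmetically first**, and ratios
  (enrichment folds, sensitivity increases) are taken between group
  means. This mean-then-ratio convention exactly reproduces the
  published summary values from the per-replicate percentages;
  per-replicate folds averaged afterwards do not.

Each mate of a read pair counts as one read. Multi-mapped reads are
expected to arrive as one alignment per read (secondary and
supplementary SAM records are dropped on input). Coordinates are
0-based half-open internally; GFF3 and SAM conversions happen at the
boundary (`read_gff()`, `read_alignments()`).

## The geometric-null detection threshold

Even in a featureless library, random read placement gives every
transcript a small number of reads. To call a gene *expressed* we need
the minimum depth at which real signal separates from this background.
The package models background reads per transcript as geometric:

$$P(X = k) = p^{k-1}\,(1 - p), \qquad k = 1, 2, \dots$$

so the log10 count of transcripts at depth $k$ is linear in $k$ with
slope $\log_{10} p$. `fit_geometric()` fits that line by ordinary least
squares to the depth histogram and reports $\hat p = 10^{\text{slope}}$
together with the fit's $r^2$.

Numerical choices:

* **Fit range.** By default $k$ runs from 1 to the largest depth with
  at least 5 transcripts, capped at 50. Depth 0 is excluded (it is not
  part of the geometric support), and so is the sparse upper tail,
  where log-counts of 1--2 transcripts would otherwise dominate the
  least-squares fit.
* **Threshold rule.** The fitted line is turned into a detection
  threshold (DTh) by one of two labelled criteria.
  `expected_below_one` (default) takes the smallest integer $k$ at
  which the fitted null expects fewer than one transcript
  ($\text{intercept} + \text{slope}\,k < 0$); `departure` takes the
  smallest $k$ at which the observed count exceeds $\tau$ times the
  fitted null. Both are reported with the criterion used, because the
  mapping from fitted line to a single integer admits more than one
  reasonable rule.
* **Degenerate inputs.** A non-negative slope (no decaying background)
  is an error: the threshold is undefined, and the pipeline records
  that rather than inventing a number. This happens routinely for
  deeply depleted, deeply sequenced samples, which barely have a
  background regime -- the threshold concept targets rRNA-dominated
  libraries.

`genes_above_dth()` uses *at least* semantics: a gene with exactly DTh
reads is expressed. DTh is estimated per reference sample and applied
to its comparison set; the pipeline estimates it on pooled replicate
counts of each treatment.

## Efficiency metrics

From category percentages and threshold results the package derives
(`enrichment_report()`):

* **Enrichment fold**: treatment mean mRNA% / control mean mRNA%.
* **Sensitivity increase**, in two deliberately coexisting modes:
  relative increase of the mapped-mRNA read proportion, and relative
  increase of the number of CDS above the detection threshold. The two
  answer different questions and can differ by orders of magnitude;
  both are first-class outputs and every value is labelled with its
  mode.
* **Required reads**: `observed_reads / fraction_covered`, the linear
  extrapolation of sequencing depth needed to bring all annotated CDS
  above the threshold. A treatment whose observed depth already covers
  the transcriptome has `fraction_covered = 1`, so its requirement is
  its observed depth.
* **Scale-down**: ratio of required depths versus a baseline treatment.

## Abundance robustness

Expression is summarised as RPKM
($\text{count} \times 10^9 / (\text{length}_{bp} \times \text{depth})$),
with the per-million denominator defaulting to the sample's total
mapped reads (reads mapped to annotated features is a selectable
alternative). Robustness of relative abundance is the Pearson
correlation and least-squares slope of log10 RPKM between a treated
sample and its reference, computed over the reference's above-DTh
genes with replicate-averaged RPKM per treatment. A slope below 1 is
the signature of dynamic-range compression: high expressors are
understated, low expressors overstated.

Genes with zero RPKM in either sample are excluded rather than
pseudocounted -- the intended subsets are above-threshold genes where
zeros are rare, and a pseudocount would bend the log-log relation at
the low end. A pseudocount mode exists for diagnostics. Note that when
abundances (not length-normalised counts) are compressed by a factor
$\gamma$, the slope between RPKM profiles also carries a small term
from the spread of gene lengths, which is shared by both axes but not
compressed; recovery tests therefore use fixed-length genes.

## Differential-expression robustness

Counts are normalised with median-of-ratios size factors (each
sample's factor is the median over genes, zero-free across samples, of
count / geometric-mean count), and fold changes are
$\log_2(\bar n_B / \bar n_A)$ of normalised condition means. When
exactly one mean is zero a pseudocount of 0.5 keeps the fold change
finite and the gene is flagged; both-zero genes are flagged undefined.

P-values come from a deliberately simple **stand-in** test, labelled as
such in every output: a per-gene negative-binomial dispersion is
estimated by method of moments from the within-condition spread, counts
are transformed with the matching variance-stabilising function
$f(k) = \tfrac{2}{\sqrt{\alpha}} \operatorname{asinh}\sqrt{\alpha k}$
(the Poisson $2\sqrt{k}$ in the $\alpha \to 0$ limit), and the
difference of condition means on the stabilised scale is referred to a
normal distribution. With two replicates per condition this screening
statistic is somewhat anti-conservative (the test suite bounds null
leakage at p < 0.01 below 10%); full negative-binomial inference with
dispersion shrinkage is intentionally out of scope. Two design
consequences follow:

* the pipeline restricts DE analysis to genes above the detection
  threshold in **every** compared treatment, mirroring standard
  practice; without this, low-count false positives with large noise
  fold-changes contaminate every downstream correlation;
* DEG sets use the strict filters p < 0.01 and |log2FC| > 1 (both
  configurable), and raw p-values -- no multiple-testing correction is
  applied, matching the convention of the summary statistics the
  package reproduces.

Robustness between two treatments is then the Pearson correlation of
their per-gene log2 fold changes over the first treatment's
significant genes, reported side by side with the same pair's
abundance-level correlation. A protocol can distort relative
abundances (per-gene bias) yet preserve fold changes perfectly, because
a multiplicative per-gene bias that is a fixed property of the
chemistry cancels between conditions.

## The synthetic-data generator

`simulate_study()` generates the situation the analysis is built for,
end to end and fully seeded:

* a single ~3.5 Mb contig carrying 3000 CDS (300--1500 bp) and two
  rRNA operons (23S/16S/5S-like gene lengths), placed disjointly in
  random order with random strands -- a desk-scale stand-in for a
  large GC-rich bacterial genome of roughly twice that size;
* lognormal CDS abundances (`expr_log_sd = 1.5`, about four decades of
  dynamic range) scaled so rRNA takes `rrna_read_fraction = 0.96` of
  the library -- the middle of the 95--98% range quoted for bacterial
  total RNA -- and a flat intergenic pseudo-feature takes 2%;
* reads assigned to features by one multinomial draw and placed
  uniformly within a feature, clipped to fit; the multinomial truth is
  attached to the read set so classification can be checked exactly.

Depletion treatments are abundance-level transformations
(`treatment_model()`):

* **rRNA retention**: rRNA weights are multiplied by a factor in
  [0, 1].
* **Per-gene bias**: each mRNA weight is multiplied by a lognormal
  factor with standard deviation `mrna_bias_sd`. Passing a precomputed
  bias vector (as `simulate_study()` does, drawing it once per
  treatment) models a chemistry whose distortion is gene-specific but
  reproducible -- the mechanism behind high fold-change robustness
  despite imperfect abundance fidelity.
* **Compression**: mRNA weights are flattened on the log scale about
  their geometric mean, $w \mapsto g\,(w/g)^{\gamma}$ with
  $g = \exp(\overline{\ln w})$. Anchoring at the geometric mean leaves
  a typical gene untouched while pulling extremes toward the centre,
  which is what a flattened treated-vs-control regression line means.
  Because the abundance distribution is right-skewed, Jensen's
  inequality makes stronger compression also shrink the aggregate mRNA
  pool slightly, so a heavily compressive protocol shows a somewhat
  smaller enrichment fold than an equally depleted but unbiased one --
  the direction observed in practice.

The default panel (`default_treatments()`) spans the contrasts of
interest: untreated control; capture-like (retention 0.9, no bias);
selective-priming-like (retention 0.02, bias sd 0.35, gamma 0.8); and
combined (retention 0.02, bias sd 0.15, gamma 0.9).

**What the generator does not emulate** -- and hence what passing tests
do not show about real data: no nucleotide sequences, sequencing
errors, GC- or position-dependent coverage, operon structure, paired
ends or multi-mapping; intergenic transcription is a single flat
pseudo-feature scaled with the mRNA pool (real antisense/sRNA signal is
structured); treatment bias is purely multiplicative per gene. Results
on real libraries depend on exactly these omitted effects, which is why
the package consumes real alignments through the same interfaces.

## Problem sizes and reproducibility

Simulated studies use per-replicate depths of 2M (control), 1.4M
(capture), 0.7M (selective) and 0.5M (combined) reads -- the study
design they emulate, scaled by 1/20 -- with two replicates per
condition. These sizes were chosen by a variance budget computed before
freezing the validation suite: the smallest effect probed (the
combined treatment's bias, sd 0.15, costs ~0.4% of log-RPKM
correlation) must exceed the counting noise of the above-threshold
gene subset, and the planted regulon (400 genes at |log2FC| = 2,
echoing a contrast in which ~17% of analysed genes responded) must
yield enough significant genes for a stable fold-change correlation.
The fold-change recovery experiment plants 100 effects at 1M
reads/replicate so that per-gene counting noise (~0.5 on log2FC at the
eligibility floor) averages to ~0.05 on the reported mean.

All randomness flows from one integer seed in `sim_config()`. The draw
order is fixed and documented (annotation; abundances; DE genes and
signs; per-treatment bias vectors; reads sample by sample), so a given
configuration is byte-reproducible end to end, including every file
`run_pipeline()` writes.

## Known limitations

* The geometric-null threshold needs a visible background regime; on
  deeply depleted libraries it degenerates by design and the pipeline
  says so instead of reporting a threshold.
* The stand-in significance test is a screening statistic; its
  p-values are labelled and should not be quoted as calibrated.
* Replicate handling assumes technical-scale agreement (correlation
  > 0.99); strongly divergent biological replicates would call for the
  out-of-scope full inference machinery.
* Percentages, folds and extrapolations inherit the printed precision
  of any external summary table they are computed from.
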