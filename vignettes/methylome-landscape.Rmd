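---
title: "Methods: WGBS methylome landscape analysis"
author: "methLandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGBS methylome landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methLandscape)
library(GenomicRanges)
```

# The analytical model

Whole-genome bisulfite sequencing yields, per sample, a beta value
(methylated-read fraction) and a read coverage for every CpG. Cancer
methylomes typically show two coupled phenomena that this package is
built to quantify: loss of methylation in late-replicating partially
methylated domains (PMDs), most visible at solo-WCGW CpGs, and gain of
methylation at CpG islands (CGIs), often along a continuous per-patient
gradient (a CIMP-like phenotype). Every stage below consumes
coverage-filtered calls (10--150 reads, autosomes only; a 5-read profile
exists for low-coverage cell lines) represented as a GRanges-backed
`SampleMethylome`.

## Summaries and averages

The global methylation of a sample is the unweighted arithmetic mean of
all covered CpGs *outside* CGIs; the CGI methylation is the mean of CpGs
inside. The two partition a sample's CpGs, and the count-weighted
combination reproduces the all-CpG mean (asserted in the tests). Feature
means are unweighted means of the CpGs inside each interval, reported
only for features with at least 3 CpGs. Subtype averages keep a CpG when
at least 80% of the group's samples cover it; the cutoff trades CpG
universe size against per-CpG precision and is the convention in
multi-sample WGBS work.

## Sliding-window domain profiling

Windows of 1 kb every 250 bp (bedtools `makewindows` semantics: starts
every step while inside the chromosome, trailing windows truncated) are
averaged over subtype-average CpGs excluding CGIs, require >= 3 eligible
CpGs in both subtypes, and are classed hypomethylated below a
tumor-minus-control delta of -0.1 and hypermethylated above +0.1, both
strict. Windows take the HMD/PMD label with the largest overlap; ties go
to the partition interval with the smaller start, then the
lexicographically smaller label, so results are order-independent.

## DMV calling

DNA methylation valleys are called on a reference cell type's subtype
average: 5 kb / 1 kb windows (excluding CGI CpGs) and CGIs (scored
separately) qualify below mean 0.15 with >= 10 CpGs; qualifying regions
are merged by transitive interval union, including book-ended regions
(the merge radius is a documented choice --- 1 bp overlap versus
touching changes nothing in practice because windows overlap heavily);
merged regions supported only by CGIs with no qualifying flanking window
are discarded, so an isolated unmethylated island is not a valley. The
>= 10 CpG floor is applied per qualifying region before merging; applying
it to the merged valley instead would only relax the criterion for
regions that already qualified piecewise.

## DMR enrichment against a resampled background

Externally called DMRs are filtered at |mean difference| > 0.2 and
q < 0.05 (both strict). The background null reproduces the two
properties that make naive genome shuffling wrong for WGBS: coverage
structure and CpG density. Eligible regions are maximal runs of covered
CpGs with successive gaps <= 300 bp; background pseudo-DMRs match the
observed length multiset exactly in every one of the 1,000 replicates,
with starts drawn uniformly over eligible-region bases (length-weighted)
and intervals accepted only when they lie wholly inside one eligible
region and contain >= 10 covered CpGs. Containment makes the <= 300 bp
internal-gap condition automatic, which is what allows the fully
vectorised rejection sampler. Background intervals may overlap each
other and the observed DMRs; excluding them would bias the null on small
genomes. Enrichment per feature class is the fraction of DMRs with a
qualifying overlap (>= 20% of the DMR or >= 20% of the feature) divided
by the same fraction among background intervals. The ChromHMM 15-state
grouping into seven classes is hard-coded in `chromStateGroups`.

A deliberately simple mean-difference caller (`toyDMRCaller`) ships so
synthetic cohorts can be run end to end; it is plumbing, not a
segmentation statistic: candidate runs need per-CpG differences > 0.2 in
a consistent direction across >= 10 CpGs within 300 bp gaps, and the q
value comes from an exact two-sided Wilcoxon rank-sum test (a rank
permutation of sample labels) on per-sample candidate means,
BH-adjusted. A max-statistic label-permutation null was tried first and
abandoned: with a planted per-sample gain gradient, label shuffles that
concentrate high-gain samples exceed the observed tumor-versus-control
statistic, making the null far too conservative.

## CGI clustering and sample grouping

Variable CGIs are those not below 0.2 in all samples and not above 0.8
in all samples (strict, idempotent). PCA is centered but not scaled ---
beta values share a scale, and scaling would inflate near-constant CGIs;
held-out samples (e.g. cell lines) are projected with the training
centering and loadings so they cannot steer the decomposition.

Consensus clustering follows the Monti resampling scheme: for each k in
2..12, 100 subsamples of 80% of items (all features kept) are
partitioned with PAM under Euclidean distance, and consensus(i,j) is the
co-clustering count over the co-sampling count. PAM's deterministic
BUILD+SWAP means all replicate variation comes from item subsampling,
so one seed fixes the whole consensus matrix. Final assignments cut an
average-linkage tree of 1 - consensus at k, and clusters are renumbered
1..k by ascending mean methylation. k is *not* chosen automatically:
consensus-CDF area and delta-area diagnostics are returned and the
leukemia-style workflow defaults to k = 4 downstream.

Sample grouping clusters samples hierarchically (Euclidean, average
linkage --- the linkage is exposed as an argument since reasonable
alternatives exist) on the variable-CGI matrix, cuts the top-level three
clusters and names them LM/IM/HM by ascending mean methylation. Rows are
internally sorted by name before tree construction so the labels depend
only on the matrix values, never on input order; identical samples are
rejected rather than silently split.

Covariate association uses two-sided Fisher's exact tests for
categorical covariates (a seeded Monte-Carlo p beyond 10 cells, where
exact enumeration gets expensive) and two-sided Wilcoxon rank-sum tests
for continuous ones; chi-squared comparisons of chromatin-state
composition report Cramér's V because "effect size" needs a concrete
measure for r x k tables.

## Epiallele entropy

For a locus of 4 consecutive CpGs with pattern counts n_1..n_16 over N
reads, the entropy is E = -(1/4) * sum(p_i log2 p_i) with 0 log 0 := 0,
so E is 0 for a single pattern and reaches 1 only at the uniform
distribution; the 1/4 normalisation (number of CpGs) keeps the range
[0,1]. Loci require 10--150 reads. A locus is assigned to a CGI when its
span (first to last CpG) overlaps it by >= 1 bp --- the simplest rule,
documented because reasonable alternatives (majority span, containment)
exist. Both genome-wide and CGI-restricted per-sample summaries are
emitted since group comparisons can sensibly use either.

## Regulator screen

Promoters are strand-aware TSS windows (1,500 bp upstream, 500 bp
downstream, clipped at chromosome bounds). Promoter-CGI assignment is
*conjunctive* (>= 20% of the promoter AND >= 20% of the island), unlike
the disjunctive DMR rule --- both rules live in the overlap module and
are bound per context. Multiple assigned CGIs are averaged; genes
without a promoter CGI fall back to the promoter-region CpG mean
(>= 3 CpGs, else "uncallable"); hypermethylated means strictly > 0.2.
The expression screen correlates log2(TPM + 1) --- the pseudocount
avoids -Inf at zero and is the dominant convention --- with per-sample
global and CGI methylation via Spearman correlation (average ranks;
exact p for n <= 9 via `cor.test`, t approximation otherwise, the two
cross-checked in tests), excludes genes with mean TPM < 0.5 before
testing, and calls hits at BH-adjusted p < 0.01. Variable-gene
clustering ranks genes by the sd of log2(TPM + 1) with no expression
pre-filter (a documented choice; the TPM floor already guards the
correlation screen) and clusters samples with Ward (ward.D2) linkage.

# The synthetic methylome generator

The generator exists so that every pipeline stage has a ground truth to
recover. `simConfig()` fixes the reference conditions used across the
tests: 2 chromosomes of 1 Mb; ~1 CpG per 100 bp outside CGIs (Poisson),
30 CGIs of 1 kb per chromosome with CpGs every 10 bp; PMDs assigned to
50 kb segments with probability 0.4 and merged, so PMD+HMD always
partition each chromosome; 5 controls and 10 tumors; planted PMD loss
0.15 and HMD loss 0.03; per-tumor CGI-gain gradient gamma on [0.05,
0.95]; truncated-normal beta noise with sd 0.05 (simple, variance
directly controllable; clipping to [0,1] is the truncation); coverage
1 + Poisson(29). Flanking bases are drawn with A/T enriched so a
realistic subset of non-CGI CpGs is solo-WCGW (W[CG]W context, no
neighbouring CpG within 35 bp, the published definition's window).

CGIs carry one of five planted profiles: *unmethylated* (baseline 0.05
everywhere), *sporadic* (0.6 gain in a random 15% of CGI-sample pairs),
*gradient-heterogeneous* (gain gamma x susceptibility, only in tumors
with gamma > 0.45), *gradient-homogeneous* (gain gamma x susceptibility
in every tumor) and *constitutively methylated* (0.75 in everyone ---
deliberately a notch below the 0.85 non-CGI baseline so these islands
stay inside the variable-CGI band rather than being filtered at 0.8).
Per-CGI susceptibility is uniform on [0.85, 1]: wide enough to spread
binarisation thresholds (so status-PCA preserves the gamma ordering),
narrow enough that within-profile spread never exceeds the
between-profile separation that consensus clustering must resolve.

Planted expression couples regulator genes to a methylation summary on
the log2 scale: log2 TPM = a + b x summary + noise. The acceptance
screen plants b = 6 with noise sd 0.5, i.e. a true correlation near
0.90. The slope is a power choice: detection at BH-adjusted p < 0.01
against 2,000 null genes at n = 30 requires a realised |rho| above
roughly 0.73, and a true rho of 0.90 puts the per-replicate miss
probability near 1e-6, so a 50-replicate detection check is stable; at
b = 5 (true rho ~0.84) roughly one replicate in fifty fails, which is a
statement about power, not about the screen.

Epiallele disorder is a two-component mixture: each read is the locus's
modal pattern (fully methylated outside CGIs, fully unmethylated inside)
with probability 1 - disorder and uniform over the 16 patterns
otherwise, making entropy exactly 0 at disorder 0 and uniform at 1, with
monotone behaviour in between.

## What the generator does and does not emulate

It reproduces the *structure* the analyses assume --- CpG density
contrast between CGIs and background, a PMD/HMD partition, solo-WCGW
context, coverage filtering, a gain gradient, cluster profiles, entropy
classes, regulator coupling --- with independent truncated-normal noise
per CpG. It does not emulate spatial autocorrelation of methylation
along the genome, strand structure, bisulfite conversion error,
copy-number effects or realistic sequence composition. Passing recovery
tests therefore demonstrates correctness of the estimators and
procedures under the stated noise model, not robustness to every
artefact of real WGBS data.

# Numerical and degenerate-input choices

- Coordinates are 0-based half-open on disk (BED convention) and
  1-based closed inside R (GRanges convention); conversions happen only
  at I/O boundaries.
- Per-CpG standard deviations use the sample (n-1) denominator.
- Top-k selections break ties at the cutoff by genomic order; largest
  overlap breaks ties by partition start, then label.
- The class boundary at delta = +/-0.1 is a strict inequality; the test
  for it uses dyadic levels so window means are exact in floating point.
- Zero eligible CpGs for a global or CGI mean, fewer than 3 samples for
  grouping, identical samples, unknown group labels, empty genomes and
  depth-0 epiallele draws all raise errors with messages rather than
  returning NA.
- All randomised stages (simulation, background sampling, consensus
  subsampling, Monte-Carlo Fisher) take explicit seeds and restore the
  RNG state afterwards (`withr::with_seed`), so identical seeds give
  byte-identical outputs.

# Problem sizes used by the tests and the acceptance script

Oracle-equivalence checks run 100 random instances per primitive on
genomes up to 100 kb. The cohort-level checks use the reference 2 x 1 Mb
genome: 5+5 samples for window-delta recovery, a 2 Mb chromosome with
three 20--30 kb canyons for DMV recovery, 200 CGIs x 20 samples for
consensus clustering (maxK 12, 100 reps), 100 null-calibration runs of
1,500 pseudo-DMRs against 1,000 background replicates for enrichment,
and 50 screen replicates of 2,000 genes at n = 30. These sizes were
chosen so each planted effect is recovered with comfortable statistical
margin while a full test run stays in the minutes range on one CPU.

# Known limitations

- PMD/HMD boundaries are consumed as annotation (or synthetic truth),
  never re-derived from data; de novo PMD segmentation is out of scope.
- The toy DMR caller is not a replacement for a real segmentation
  method; its q values are honest but its boundaries are naive.
- k for consensus clustering is a user decision informed by the CDF
  diagnostics, as automatic k selection on consensus matrices is
  unreliable.
- The entropy module consumes epiallele counts; extracting them from
  alignments is upstream of this package.
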