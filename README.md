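# methLandscape

Analysis of the DNA methylation landscape of whole-genome bisulfite
sequencing (WGBS) cohorts, built for leukemia-style methylome studies in
which tumors simultaneously *retain* methylation in partially methylated
domains (PMDs) and *gain* methylation at CpG islands (CGIs).

## Who this is for

Computational epigenomics groups analysing per-CpG methylation calls
(bedGraph-like tables of level and coverage) against standard BED
annotations: CGIs, PMD/HMD segmentations, solo-WCGW CpGs, chromatin
states, gene models and externally called differentially methylated
regions (DMRs). Because patient WGBS is usually controlled-access, the
package ships a fully seeded synthetic-methylome generator with planted
ground truth so every stage of the pipeline can be exercised, tested and
power-checked without real data.

## What it computes

- **Sample summaries** — global methylation (arithmetic mean of CpGs
  outside CGIs, autosomes only, coverage 10–150) and CGI methylation
  (mean of CpGs inside CGIs); per-CpG subtype averages over CpGs covered
  by ≥80% of a group.
- **Domain landscape** — 1 kb / 250 bp sliding-window tumor−control
  deltas excluding CGI CpGs, windows classed hypo/hyper at the strict
  ±0.1 bound and assigned HMD or PMD by largest overlap; DNA methylation
  valley (DMV) calling from 5 kb / 1 kb windows and CGIs with mean < 0.15
  and ≥10 CpGs, merged, discarding CGI-only regions; per-domain solo-WCGW
  means.
- **DMR enrichment** — filtering (|Δ| > 0.2, q < 0.05), eligible regions
  (consecutive CpGs ≤ 300 bp apart), a length-matched random background
  resampled 1,000× under the same ≥10-CpG constraint, and per-class
  enrichment ratios (CGI, shores, shelves, DMVs, PMDs, grouped ChromHMM
  states) under the 20%-of-either overlap rule.
- **CGI clustering** — variable-CGI selection (not <0.2 or >0.8 in all
  samples), centered PCA with projection of held-out samples,
  Monti-style consensus clustering (PAM, Euclidean, maxK 12, 100 reps,
  80% item subsampling) with clusters relabelled by ascending
  methylation, LM/IM/HM sample grouping from the top-level three
  clusters, and cluster characterisation with chi-squared tests and
  Cramér's V.
- **Methylation entropy** — normalised Shannon entropy of 4-CpG
  epiallele patterns, E = −(1/4) Σ pᵢ log₂ pᵢ over the 16 patterns
  (10–150 reads per locus), aggregated per CGI, with Wilcoxon group
  comparisons.
- **Regulator screen** — strand-aware promoters (TSS −1500/+500),
  promoter-CGI methylation panel (conjunctive 20%/20% assignment,
  multi-CGI averaging, promoter-region fallback, hypermethylated at
  >0.2), and a transcriptome-wide Spearman screen of log₂ TPM against
  global/CGI methylation with BH correction at adjusted p < 0.01.

## Worked example

```r
library(methLandscape)
library(GenomicRanges)

## a seeded 2 x 1 Mb cohort: 5 controls, 10 tumors with planted
## PMD loss 0.15, HMD loss 0.03 and a CGI-gain gradient
co <- simulateCohort(simConfig(seed = 1))
tr <- co$truth

s <- co$samples$tumor_10
globalMean(s, tr$cgis)
#> [1] 0.7727004
cgiMean(s, tr$cgis)
#> [1] 0.4215877

tumorAvg   <- subtypeAverage(co$samples[tr$groups == "tumor"])
controlAvg <- subtypeAverage(co$samples[tr$groups == "control"])
wd <- windowDeltas(tumorAvg, controlAvg, makeWindows(tr$chromLengths),
                   tr$cgis, tr$hmdPmd)
tapply(wd$delta, wd$domain, median)
#>         HMD         PMD 
#> -0.02979137 -0.15065403
```

The tumor's global (non-CGI) mean sits ~0.08 below the control baseline
of 0.85 (a mix of PMD and HMD losses), its CGI mean is elevated by the
planted gain gradient, and the sliding-window medians recover the
planted domain-specific losses of −0.15 (PMD) and −0.03 (HMD).

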