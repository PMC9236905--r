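suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## quick SampleMethylome from position/level vectors (1-based positions)
mkMeth <- function(pos, level, chrom = "chr1", coverage = 30L,
                   id = "s1", group = "unknown", seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L), level = level,
                coverage = rep_len(coverage, length(pos)))
  if (!is.null(seqlen)) seqlengths(gr) <- seqlen
  SampleMethylome(gr, id, group)
}

mkIv <- function(start0, end0, chrom = "chr1", label = NULL,
                 strand = NULL, seqlen = NULL) {
  gr <- GRanges(rep_len(chrom, length(start0)),
                IRanges(start0 + 1L, end0),
                strand = if (is.null(strand)) "*" else strand)
  if (!is.null(label)) mcols(gr)$label <- label
  if (!is.null(seqlen))
    seqlengths(gr) <- setNames(rep_len(seqlen, length(seqlevels(gr))),
                               seqlevels(gr))
  gr
}

## small default cohort shared across tests (computed once per test run)
smallCohortCache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCohort(simConfig(
        seed = 424, nChroms = 2, chromLength = 400000, nCGIsPerChrom = 25,
        nControl = 4, nTumor = 8, nGenesPerChrom = 12, geneLength = 8000,
        segmentLength = 40000))
    cache
  }
})
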