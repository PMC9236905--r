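## dmr_enrichment: filtering externally called DMRs, eligible-region
## construction, random-background resampling and feature-class enrichment.

#' Chromatin-state grouping (ChromHMM 15-state model)
#'
#' Named character vector mapping the 15 ChromHMM states to the seven
#' grouped classes used for enrichment and CGI characterisation.
#' @export
chromStateGroups <- c(
  "1_TssA" = "Active TSS", "2_TssAFlnk" = "Active TSS",
  "10_TssBiv" = "Bivalent TSS", "11_BivFlnk" = "Bivalent TSS",
  "3_TxFlnk" = "Transcript", "4_Tx" = "Transcript", "5_TxWk" = "Transcript",
  "6_EnhG" = "Enhancer", "7_Enh" = "Enhancer", "12_EnhBiv" = "Enhancer",
  "8_ZNF/Rpts" = "Heterochromatin", "9_Het" = "Heterochromatin",
  "13_ReprPC" = "Repressive", "14_ReprPCWk" = "Repressive",
  "15_Quies" = "Quiescent")

#' Filter a raw DMR table to significant DMRs
#'
#' Retains DMRs with absolute mean methylation difference strictly greater
#' than \code{minDiff} and q value strictly below \code{maxQ}; direction is
#' derived from the sign of the difference (hyper = tumor gain).
#'
#' @param raw data.frame with columns \code{chrom}, \code{start} (0-based),
#'   \code{end}, \code{diff} (tumor - control) and \code{q}.
#' @param minDiff absolute-difference threshold (default 0.2, strict >).
#' @param maxQ q-value threshold (default 0.05, strict <).
#' @return GRanges with metadata \code{diff}, \code{q}, \code{direction}.
#' @export
filterDMRs <- function(raw, minDiff = 0.2, maxQ = 0.05) {
  need <- c("chrom", "start", "end", "diff", "q")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("DMR table lacks column(s): ", paste(miss, collapse = ", "))
  keep <- abs(raw$diff) > minDiff & raw$q < maxQ
  raw <- raw[keep, , drop = FALSE]
  GRanges(raw$chrom, IRanges(raw$start + 1L, raw$end),
          diff = raw$diff, q = raw$q,
          direction = ifelse(raw$diff > 0, "hyper", "hypo"))
}

#' Regions that could contain a DMR given CpG coverage
#'
#' Maximal runs of covered CpGs in which consecutive CpGs are at most
#' \code{maxGap} bp apart, returned as intervals spanning the first to the
#' last CpG of each run. These are the only places a DMR (or a background
#' pseudo-DMR) can live.
#'
#' @param cpgs GRanges of the covered CpG universe of the comparison
#'   (e.g. the CpGs common to tumor and control averages).
#' @param maxGap maximum gap between consecutive CpGs in bp (default 300).
#' @return GRanges of eligible regions with metadata \code{n_cpgs}.
#' @export
eligibleRegions <- function(cpgs, maxGap = 300L) {
  if (!length(cpgs)) return(GRanges(n_cpgs = integer()))
  cpgs <- GenomicRanges::sort(granges(cpgs))
  pos <- start(cpgs)
  chr <- as.character(seqnames(cpgs))
  newRun <- c(TRUE, chr[-1] != chr[-length(chr)] |
                    pos[-1] - pos[-length(pos)] > maxGap)
  run <- cumsum(newRun)
  st <- tapply(pos, run, min)
  en <- tapply(pos, run, max)
  firstChr <- chr[!duplicated(run)]
  GRanges(firstChr, IRanges(as.integer(st), as.integer(en)),
          n_cpgs = as.integer(table(run)))
}

#' Sample random background pseudo-DMRs
#'
#' Draws \code{nReps} background replicates, each matching the observed DMR
#' length multiset exactly: for every DMR length a start is drawn uniformly
#' over eligible-region bases (length-weighted) and accepted iff the
#' resulting interval lies entirely inside one eligible region (hence all
#' internal CpG gaps are <= \code{maxGap}) and covers at least
#' \code{minCpGs} CpGs. Rejection sampling with an attempt cap; fully
#' seeded and reproducible.
#'
#' @param dmrs GRanges of observed DMRs (lengths are reused).
#' @param regions GRanges from \code{\link{eligibleRegions}}.
#' @param cpgs GRanges of the covered CpG universe.
#' @param nReps number of background replicates (default 1000).
#' @param minCpGs minimum CpGs per background interval (default 10).
#' @param maxGap maximum internal CpG gap (default 300; enforced via region
#'   containment).
#' @param seed integer RNG seed.
#' @param maxAttempts rejection-sampling rounds before giving up (default
#'   1000).
#' @return GRanges of \code{nReps * length(dmrs)} background intervals with
#'   metadata \code{rep}.
#' @export
sampleBackground <- function(dmrs, regions, cpgs, nReps = 1000L,
                             minCpGs = 10L, maxGap = 300L, seed = 1L,
                             maxAttempts = 1000L) {
  stopifnot(length(regions) > 0, length(dmrs) > 0)
  cpgs <- GenomicRanges::sort(granges(cpgs))
  posByChr <- split(start(cpgs), as.character(seqnames(cpgs)))
  regChr <- as.character(seqnames(regions))
  regStart <- start(regions); regEnd <- end(regions)
  lens <- rep(width(dmrs), times = nReps)
  repIdx <- rep(seq_len(nReps), each = length(dmrs))
  cum <- cumsum(as.numeric(width(regions)))
  total <- cum[length(cum)]
  cum0 <- c(0, cum)
  n <- length(lens)
  starts <- integer(n); chroms <- character(n)
  need <- rep(TRUE, n)
  withr::with_seed(seed, {
    for (round in seq_len(maxAttempts)) {
      idx <- which(need)
      if (!length(idx)) break
      u <- runif(length(idx), 0, total)
      ri <- findInterval(u, cum) + 1L
      st <- regStart[ri] + as.integer(floor(u - cum0[ri]))
      en <- st + lens[idx] - 1L
      fit <- en <= regEnd[ri]
      ok <- fit
      for (ch in unique(regChr[ri[fit]])) {
        sel <- fit & regChr[ri] == ch
        p <- posByChr[[ch]]
        nc <- if (is.null(p)) 0L
              else findInterval(en[sel], p) - findInterval(st[sel] - 1L, p)
        ok[sel] <- nc >= minCpGs
      }
      acc <- idx[ok]
      starts[acc] <- st[ok]
      chroms[acc] <- regChr[ri[ok]]
      need[acc] <- FALSE
    }
  })
  if (any(need))
    stop("could not place a background interval of length ",
         lens[which(need)[1]], " after ", maxAttempts,
         " attempts; genome too sparse")
  GRanges(chroms, IRanges(starts, width = lens), rep = repIdx)
}

#' Feature-class enrichment of DMRs over a resampled background
#'
#' For every feature class, the fraction of DMRs with at least one
#' qualifying overlap (the 20\%-of-either rule,
#' \code{\link{overlapTwentyPct}}) divided by the same fraction among the
#' background pseudo-DMRs.
#'
#' @param dmrs GRanges of observed DMRs.
#' @param background GRanges from \code{\link{sampleBackground}}.
#' @param featureSets named list of GRanges, e.g. CGI, shore, shelf, DMV,
#'   PMD and the grouped chromatin states.
#' @param frac overlap fraction for the qualifying rule (default 0.2).
#' @return data.frame: class, observed, background, ratio. A class with
#'   background fraction 0 gets ratio Inf with a warning.
#' @export
dmrEnrichment <- function(dmrs, background, featureSets, frac = 0.2) {
  stopifnot(length(background) > 0, is.list(featureSets),
            !is.null(names(featureSets)))
  obs <- vapply(featureSets, function(fs) .fracOverlap(dmrs, fs, frac), 0)
  bg <- vapply(featureSets, function(fs) .fracOverlap(background, fs, frac), 0)
  ratio <- obs / bg
  if (any(bg == 0 & obs >= 0))
    warning("feature class(es) with zero background fraction: ",
            paste(names(featureSets)[bg == 0], collapse = ", "))
  data.frame(class = names(featureSets), observed = obs, background = bg,
             ratio = ratio, row.names = NULL, stringsAsFactors = FALSE)
}

## fraction of query intervals with >= 1 overlap passing the 20% rule
.fracOverlap <- function(query, features, frac) {
  if (!length(query)) return(0)
  if (!length(features)) return(0)
  hits <- findOverlaps(query, features, ignore.strand = TRUE)
  if (!length(hits)) return(0)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  ov <- pmin(end(query)[qh], end(features)[sh]) -
        pmax(start(query)[qh], start(features)[sh]) + 1L
  pass <- ov >= frac * width(query)[qh] | ov >= frac * width(features)[sh]
  length(unique(qh[pass])) / length(query)
}

#' Minimal mean-difference DMR caller for synthetic cohorts
#'
#' A deliberately simple caller for end-to-end synthetic runs (it is
#' plumbing, not a reimplementation of a segmentation statistic): within
#' each eligible region, CpGs where the tumor-minus-control mean difference
#' exceeds \code{minDiff} in absolute value and agrees in sign are grown
#' into runs; runs with >= \code{minCpGs} CpGs become candidate DMRs and an
#' exact two-sided Wilcoxon rank-sum test (a rank permutation of sample
#' labels) on per-sample candidate means supplies the p value,
#' Benjamini-Hochberg adjusted into q over candidates.
#'
#' @param tumorSamples,controlSamples lists of
#'   \linkS4class{SampleMethylome}.
#' @param maxGap eligible-region gap (default 300).
#' @param minDiff per-CpG mean-difference threshold (default 0.2).
#' @param minCpGs minimum CpGs per candidate (default 10).
#' @return data.frame in the \code{\link{filterDMRs}} input schema.
#' @export
toyDMRCaller <- function(tumorSamples, controlSamples, maxGap = 300L,
                         minDiff = 0.2, minCpGs = 10L) {
  nt <- length(tumorSamples)
  mat <- .cohortCpGMatrix(c(tumorSamples, controlSamples))
  mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]  # commonly covered
  keyParts <- strsplit(rownames(mat), ":", fixed = TRUE)
  avgGr <- GRanges(vapply(keyParts, `[`, "", 1L),
                   IRanges(as.integer(vapply(keyParts, `[`, "", 2L)),
                           width = 1L))
  ord <- order(as.integer(seqnames(avgGr)), start(avgGr))
  avgGr <- avgGr[ord]; mat <- mat[ord, , drop = FALSE]
  dv <- rowMeans(mat[, seq_len(nt), drop = FALSE]) -
        rowMeans(mat[, -seq_len(nt), drop = FALSE])
  cand <- .diffRuns(avgGr, dv, maxGap, minDiff, minCpGs)
  if (!nrow(cand)) return(cand)
  ## per-candidate rank permutation p: exact two-sided Wilcoxon rank-sum
  ## on per-sample candidate means (tumor vs control), BH-adjusted
  candGr <- GRanges(cand$chrom, IRanges(cand$start + 1L, cand$end))
  hits <- findOverlaps(candGr, avgGr, ignore.strand = TRUE)
  idxList <- split(subjectHits(hits), queryHits(hits))
  pvals <- vapply(seq_len(nrow(cand)), function(i) {
    sm <- colMeans(mat[idxList[[as.character(i)]], , drop = FALSE])
    suppressWarnings(wilcox.test(sm[seq_len(nt)], sm[-seq_len(nt)],
                                 exact = TRUE)$p.value)
  }, 0)
  cand$q <- p.adjust(pvals, method = "BH")
  cand
}

.diffRuns <- function(avgGr, dv, maxGap, minDiff, minCpGs) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), diff = numeric(), q = numeric(),
                      n_cpgs = integer(), stringsAsFactors = FALSE)
  sig <- abs(dv) > minDiff
  if (!any(sig)) return(empty)
  chr <- as.character(seqnames(avgGr)); pos <- start(avgGr)
  n <- length(pos)
  brk <- c(TRUE, chr[-1] != chr[-n] | pos[-1] - pos[-n] > maxGap |
                 sign(dv[-1]) != sign(dv[-n]) | !sig[-1] | !sig[-n])
  run <- cumsum(brk)
  keep <- sig
  counts <- tapply(keep, run, sum)
  good <- as.integer(names(counts)[counts >= minCpGs])
  if (!length(good)) return(empty)
  rows <- lapply(good, function(g) {
    i <- which(run == g & keep)
    data.frame(chrom = chr[i[1]], start = pos[i[1]] - 1L,
               end = pos[i[length(i)]], diff = mean(dv[i]), q = NA_real_,
               n_cpgs = length(i), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
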