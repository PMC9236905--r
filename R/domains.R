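## domain_landscape: sliding-window HMD/PMD methylation-difference
## profiling, DMV calling and solo-WCGW per-domain summaries.

#' Sliding genome windows (bedtools 'makewindows' semantics)
#'
#' Windows start at 0 and every \code{step} bp thereafter while the start is
#' inside the chromosome; the end is truncated at the chromosome length, so
#' trailing windows are shorter than \code{width}.
#'
#' @param chromLengths named integer vector of chromosome lengths, or a
#'   GRanges carrying seqlengths.
#' @param width window width in bp (default 1000).
#' @param step step between window starts in bp (default 250).
#' @return GRanges of windows with seqlengths set.
#' @export
makeWindows <- function(chromLengths, width = 1000L, step = 250L) {
  if (is(chromLengths, "GRanges")) chromLengths <- seqlengths(chromLengths)
  stopifnot(width > 0, step > 0, length(chromLengths) > 0,
            !is.null(names(chromLengths)))
  pieces <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    starts <- seq.int(0L, len - 1L, by = step)
    GRanges(chr, IRanges(starts + 1L, pmin(starts + width, len)),
            seqlengths = chromLengths)
  })
  do.call(c, pieces)
}

#' Tumor-control methylation deltas in sliding windows over HMDs/PMDs
#'
#' Computes, per 1-kb sliding window (or any window set), the mean of the
#' subtype-average CpG levels excluding CpGs in CGIs, for a tumor and a
#' control subtype average; windows need >= \code{minCpGs} eligible CpGs in
#' both averages. Each retained window gets the HMD/PMD label with the
#' largest overlap and is classed hypomethylated if the tumor-minus-control
#' delta is below -0.1, hypermethylated if above 0.1 (both strict),
#' otherwise unchanged.
#'
#' @param tumorAvg,controlAvg subtype averages from
#'   \code{\link{subtypeAverage}} (GRanges with a \code{mean} column).
#' @param windows GRanges from \code{\link{makeWindows}}.
#' @param cgis GRanges of CpG islands (their CpGs are excluded).
#' @param hmdPmd GRanges partition with \code{label} "HMD"/"PMD".
#' @param minCpGs minimum eligible CpGs per window per subtype (default 3).
#' @param threshold class threshold on |delta| (default 0.1).
#' @return data.frame: chrom, start (0-based), end, domain, tumor_mean,
#'   control_mean, delta, class.
#' @export
windowDeltas <- function(tumorAvg, controlAvg, windows, cgis, hmdPmd,
                         minCpGs = 3L, threshold = 0.1) {
  if (!length(GenomicRanges::intersect(granges(tumorAvg),
                                       granges(controlAvg))))
    stop("tumor and control subtype averages share no CpGs")
  tm <- .windowMeans(tumorAvg, windows, cgis, minCpGs)
  cm <- .windowMeans(controlAvg, windows, cgis, minCpGs)
  keep <- !is.na(tm) & !is.na(cm)
  w <- windows[keep]
  delta <- tm[keep] - cm[keep]
  cls <- ifelse(delta < -threshold, "hypo",
                ifelse(delta > threshold, "hyper", "unchanged"))
  data.frame(chrom = as.character(seqnames(w)), start = start(w) - 1L,
             end = end(w), domain = assignLargestOverlap(w, hmdPmd),
             tumor_mean = tm[keep], control_mean = cm[keep],
             delta = delta, class = cls, stringsAsFactors = FALSE)
}

## mean of avg$mean per window over CpGs outside CGIs; NA below minCpGs
.windowMeans <- function(avg, windows, cgis, minCpGs) {
  cp <- avg[!overlapsAny(avg, cgis, ignore.strand = TRUE)]
  hits <- findOverlaps(windows, cp, ignore.strand = TRUE)
  f <- factor(queryHits(hits), levels = seq_along(windows))
  n <- as.integer(table(f))
  s <- as.numeric(tapply(mcols(cp)$mean[subjectHits(hits)], f, sum,
                         default = 0))
  ifelse(n >= minCpGs, s / n, NA_real_)
}

#' Call DNA methylation valleys (DMVs)
#'
#' DMVs are large, very lowly methylated regions of a reference cell type.
#' The caller (1) computes 5-kb/1-kb sliding-window means of the subtype
#' average, excluding CGI CpGs; (2) computes CGI means separately; (3)
#' collects windows and CGIs with mean methylation < \code{maxLevel} and at
#' least \code{minCpGs} CpGs; (4) merges overlapping (and book-ended)
#' qualifying regions; and (5) discards merged regions supported only by
#' CGIs without any qualifying flanking window.
#'
#' @param avg subtype average GRanges (from \code{\link{subtypeAverage}}).
#' @param cgis GRanges of CpG islands.
#' @param chromLengths named chromosome lengths (for window construction).
#' @param width,step sliding-window geometry (defaults 5000/1000).
#' @param maxLevel qualifying mean methylation bound, strict (default 0.15).
#' @param minCpGs minimum CpGs per qualifying region (default 10).
#' @return GRanges of disjoint DMVs with metadata \code{mean} (CpG-level
#'   mean over the merged region) and \code{n_cpgs}.
#' @export
callDMVs <- function(avg, cgis, chromLengths, width = 5000L, step = 1000L,
                     maxLevel = 0.15, minCpGs = 10L) {
  windows <- makeWindows(chromLengths, width = width, step = step)
  wm <- .windowMeans(avg, windows, cgis, minCpGs)  # NA below minCpGs
  qualWin <- windows[!is.na(wm) & wm < maxLevel]

  hits <- findOverlaps(cgis, avg, ignore.strand = TRUE)
  f <- factor(queryHits(hits), levels = seq_along(cgis))
  n <- as.integer(table(f))
  s <- as.numeric(tapply(mcols(avg)$mean[subjectHits(hits)], f, sum,
                         default = 0))
  qualCgi <- granges(cgis)[n >= minCpGs & ifelse(n > 0, s / n, NA) < maxLevel]
  qualCgi <- qualCgi[!is.na(start(qualCgi))]

  if (!length(qualWin) && !length(qualCgi))
    return(GRanges(mean = numeric(), n_cpgs = integer()))
  merged <- reduce(c(granges(qualWin), granges(qualCgi)),
                   min.gapwidth = 1L)  # book-ended regions merge
  hasWin <- overlapsAny(merged, qualWin, ignore.strand = TRUE)
  dmvs <- merged[hasWin]
  if (!length(dmvs)) return(GRanges(mean = numeric(), n_cpgs = integer()))
  h2 <- findOverlaps(dmvs, avg, ignore.strand = TRUE)
  f2 <- factor(queryHits(h2), levels = seq_along(dmvs))
  n2 <- as.integer(table(f2))
  s2 <- as.numeric(tapply(mcols(avg)$mean[subjectHits(h2)], f2, sum,
                          default = 0))
  mcols(dmvs)$mean <- ifelse(n2 > 0, s2 / n2, NA_real_)
  mcols(dmvs)$n_cpgs <- n2
  dmvs
}

#' Per-domain solo-WCGW mean methylation per sample
#'
#' For each PMD/HMD region, the arithmetic mean of the sample's solo-WCGW
#' CpG levels; only regions with at least \code{minCpGs} solo CpGs covered
#' in \emph{every} sample are reported. Solo-WCGW CpGs (A/T flanks, no
#' neighbouring CpG nearby) are the most faithful reporters of PMD
#' hypomethylation.
#'
#' @param samples list of \linkS4class{SampleMethylome}.
#' @param soloSites GRanges of solo-WCGW CpG positions.
#' @param hmdPmd GRanges with \code{label} "HMD"/"PMD".
#' @param minCpGs minimum solo CpGs per region per sample (default 1).
#' @return data.frame: region, chrom, start, end, domain, then one mean
#'   column per sample id.
#' @export
soloWCGWDomainMeans <- function(samples, soloSites, hmdPmd, minCpGs = 1L) {
  ids <- vapply(samples, sampleId, "")
  means <- matrix(NA_real_, length(hmdPmd), length(samples),
                  dimnames = list(NULL, ids))
  for (j in seq_along(samples)) {
    gr <- cpgCalls(samples[[j]])
    solo <- gr[overlapsAny(gr, soloSites, ignore.strand = TRUE)]
    hits <- findOverlaps(hmdPmd, solo, ignore.strand = TRUE)
    f <- factor(queryHits(hits), levels = seq_along(hmdPmd))
    n <- as.integer(table(f))
    s <- as.numeric(tapply(mcols(solo)$level[subjectHits(hits)], f, sum,
                           default = 0))
    means[, j] <- ifelse(n >= minCpGs, s / n, NA_real_)
  }
  keep <- rowSums(is.na(means)) == 0
  out <- data.frame(region = .featureIds(hmdPmd)[keep],
                    chrom = as.character(seqnames(hmdPmd))[keep],
                    start = start(hmdPmd)[keep] - 1L,
                    end = end(hmdPmd)[keep],
                    domain = as.character(mcols(hmdPmd)$label)[keep],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(means[keep, , drop = FALSE]))
}

#' Classify CpGs as solo-WCGW
#'
#' A CpG is solo-WCGW iff its immediate 5' and 3' flanking bases are both
#' A or T (W[CG]W context) and no other CpG lies within \code{window} bp
#' on either side.
#'
#' @param cpgs GRanges of CpG positions (width-1, the C of the CpG).
#' @param flank5,flank3 character vectors of the immediate flanking bases.
#' @param window exclusion window for neighbouring CpGs in bp (default 35).
#' @return logical vector.
#' @export
classifySoloWCGW <- function(cpgs, flank5, flank3, window = 35L) {
  stopifnot(length(flank5) == length(cpgs), length(flank3) == length(cpgs))
  wcgw <- toupper(flank5) %in% c("A", "T") & toupper(flank3) %in% c("A", "T")
  ord <- order(as.integer(seqnames(cpgs)), start(cpgs))
  pos <- start(cpgs)[ord]
  chr <- as.integer(seqnames(cpgs))[ord]
  n <- length(pos)
  dl <- c(Inf, ifelse(chr[-1] == chr[-n], pos[-1] - pos[-n], Inf))
  dr <- c(dl[-1], Inf)
  solo <- rep(NA, n)
  solo[ord] <- dl > window & dr > window
  wcgw & solo
}
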