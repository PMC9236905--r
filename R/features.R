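## feature_methylation: mean-methylation summarisation over features,
## sample-level global/CGI summaries, subtype averages, shared overlap rules
## and variable-CpG selection.

#' Mean methylation per feature
#'
#' For each feature interval, the unweighted arithmetic mean of the sample's
#' CpG levels falling inside it. Features covered by fewer than
#' \code{minCpGs} CpGs are omitted (default 3, the standard reporting
#' threshold).
#'
#' @param sample a \linkS4class{SampleMethylome} (already coverage-filtered).
#' @param features GRanges of features; names or \code{label} column used as
#'   feature ids when present.
#' @param minCpGs minimum CpGs per reported feature.
#' @return data.frame with columns \code{feature}, \code{chrom},
#'   \code{start} (0-based), \code{end}, \code{mean}, \code{n_cpgs}.
#' @export
featureMeans <- function(sample, features, minCpGs = 3L) {
  stopifnot(is(sample, "SampleMethylome"))
  gr <- cpgCalls(sample)
  ids <- .featureIds(features)
  hits <- findOverlaps(features, gr, ignore.strand = TRUE)
  lev <- mcols(gr)$level[subjectHits(hits)]
  f <- factor(queryHits(hits), levels = seq_along(features))
  n <- as.integer(table(f))
  s <- as.numeric(tapply(lev, f, sum, default = 0))
  keep <- n >= minCpGs
  data.frame(feature = ids[keep],
             chrom = as.character(seqnames(features))[keep],
             start = start(features)[keep] - 1L,
             end = end(features)[keep],
             mean = s[keep] / n[keep],
             n_cpgs = n[keep],
             stringsAsFactors = FALSE)
}

.featureIds <- function(features) {
  if (!is.null(names(features)) && !anyDuplicated(names(features)))
    return(names(features))
  if (!is.null(mcols(features)$label) &&
      !anyDuplicated(mcols(features)$label))
    return(as.character(mcols(features)$label))
  paste0(seqnames(features), ":", start(features) - 1L, "-", end(features))
}

#' Global (non-CGI) mean methylation of a sample
#'
#' Arithmetic mean of the methylation levels of all covered CpGs lying
#' outside CpG islands -- the per-sample global methylation summary.
#'
#' @param sample a \linkS4class{SampleMethylome}.
#' @param cgis GRanges of CpG islands.
#' @return single numeric level in [0,1].
#' @export
globalMean <- function(sample, cgis) {
  gr <- cpgCalls(sample)
  out <- !overlapsAny(gr, cgis, ignore.strand = TRUE)
  if (!any(out)) stop("no covered CpGs outside CGIs for sample '",
                      sampleId(sample), "'")
  mean(mcols(gr)$level[out])
}

#' CGI mean methylation of a sample
#'
#' Arithmetic mean of the methylation levels of all covered CpGs inside
#' CpG islands. Together with \code{\link{globalMean}} this partitions the
#' CpGs of a sample: the count-weighted combination of the two equals the
#' all-CpG mean.
#'
#' @inheritParams globalMean
#' @return single numeric level in [0,1].
#' @export
cgiMean <- function(sample, cgis) {
  gr <- cpgCalls(sample)
  inside <- overlapsAny(gr, cgis, ignore.strand = TRUE)
  if (!any(inside)) stop("no covered CpGs inside CGIs for sample '",
                         sampleId(sample), "'")
  mean(mcols(gr)$level[inside])
}

#' Per-CpG average over a sample group (subtype average)
#'
#' For every CpG covered by at least \code{minFraction} of the samples
#' (default 80\%), the mean methylation level over the covering samples.
#'
#' @param samples list of \linkS4class{SampleMethylome}.
#' @param minFraction minimum fraction of samples covering a CpG for it to
#'   be retained.
#' @return GRanges of retained CpGs with metadata columns \code{mean},
#'   \code{n_samples} and \code{fraction}.
#' @export
subtypeAverage <- function(samples, minFraction = 0.8) {
  stopifnot(length(samples) >= 1)
  ns <- length(samples)
  keys <- lapply(samples, function(s) {
    gr <- cpgCalls(s)
    paste0(seqnames(gr), ":", start(gr))
  })
  all <- unlist(keys, use.names = FALSE)
  lev <- unlist(lapply(samples, methLevel), use.names = FALSE)
  u <- unique(all)
  idx <- match(all, u)
  n <- tabulate(idx, nbins = length(u))
  s <- as.numeric(tapply(lev, factor(idx, levels = seq_along(u)), sum,
                         default = 0))
  keep <- n / ns >= minFraction
  parts <- strsplit(u[keep], ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                mean = (s / n)[keep], n_samples = n[keep],
                fraction = (n / ns)[keep])
  GenomicRanges::sort(gr)
}

#' 20 percent reciprocal-or overlap rule
#'
#' TRUE iff the overlap between two intervals covers at least 20\% of the
#' first \emph{or} at least 20\% of the second (the disjunctive rule used
#' for DMR-feature annotation). Symmetric in its arguments. Set
#' \code{mode = "both"} for the conjunctive variant used for promoter-CGI
#' assignment (>= 20\% of promoter \emph{and} >= 20\% of island).
#'
#' @param a,b GRanges of equal length (element-wise comparison) or length 1.
#' @param frac overlap fraction threshold (default 0.2).
#' @param mode "either" (default) or "both".
#' @return logical vector.
#' @export
overlapTwentyPct <- function(a, b, frac = 0.2, mode = c("either", "both")) {
  mode <- match.arg(mode)
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  ov <- rep(0L, n)
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  lo <- pmax(start(a), start(b)); hi <- pmin(end(a), end(b))
  ov[same] <- pmax(hi - lo + 1L, 0L)[same]
  fa <- ov / width(a); fb <- ov / width(b)
  if (mode == "either") fa >= frac | fb >= frac else fa >= frac & fb >= frac
}

#' Assign each query interval the partition label with largest overlap
#'
#' Used e.g. to classify sliding windows as PMD or HMD and CGIs to a
#' chromatin state. Ties broken by smaller partition-interval start, then
#' lexicographic label; queries with zero overlap get \code{"none"}.
#'
#' @param query GRanges.
#' @param partition GRanges with a \code{label} metadata column.
#' @return character vector of labels, one per query.
#' @export
assignLargestOverlap <- function(query, partition) {
  stopifnot(length(partition) > 0, !is.null(mcols(partition)$label))
  hits <- findOverlaps(query, partition, ignore.strand = TRUE)
  out <- rep("none", length(query))
  if (!length(hits)) return(out)
  ovw <- width(pintersect(query[queryHits(hits)],
                          partition[subjectHits(hits)]))
  h <- data.frame(q = queryHits(hits), s = subjectHits(hits), w = ovw,
                  st = start(partition)[subjectHits(hits)],
                  lab = as.character(mcols(partition)$label)[subjectHits(hits)])
  h <- h[order(h$q, -h$w, h$st, h$lab), ]
  first <- !duplicated(h$q)
  out[h$q[first]] <- h$lab[first]
  out
}

#' Most variable CpGs across a cohort
#'
#' Ranks CpGs covered by at least \code{minSampleFraction} of the samples by
#' the sample standard deviation (n-1 denominator) of their levels across
#' covering samples, and returns the top \code{fraction} as a CpG-by-sample
#' matrix (NA where a sample does not cover a CpG) ready for hierarchical
#' clustering. Ties at the cutoff are broken by genomic order.
#'
#' @param samples list of \linkS4class{SampleMethylome} (>= 2).
#' @param fraction fraction of eligible CpGs to retain (default 0.05).
#' @param minSampleFraction minimum covering-sample fraction (default 0.8).
#' @return numeric matrix, rows "chrom:pos" in genomic order, columns sample
#'   ids; attribute \code{sd} carries the per-row standard deviations.
#' @export
topVariableCpGs <- function(samples, fraction = 0.05,
                            minSampleFraction = 0.8) {
  stopifnot(length(samples) >= 2)
  mat <- .cohortCpGMatrix(samples)
  n <- rowSums(!is.na(mat))
  eligible <- n / ncol(mat) >= minSampleFraction & n >= 2
  mat <- mat[eligible, , drop = FALSE]
  sds <- apply(mat, 1L, sd, na.rm = TRUE)
  k <- floor(fraction * nrow(mat))
  ord <- order(-sds, seq_len(nrow(mat)))   # genomic order breaks sd ties
  sel <- sort(ord[seq_len(k)])
  out <- mat[sel, , drop = FALSE]
  attr(out, "sd") <- sds[sel]
  out
}

## CpG (rows, "chrom:pos" keys in genomic order) x sample matrix of levels
.cohortCpGMatrix <- function(samples) {
  grs <- lapply(unname(samples), cpgCalls)
  u <- GenomicRanges::sort(unique(do.call(c, lapply(grs, granges))))
  mat <- matrix(NA_real_, length(u), length(samples),
                dimnames = list(paste0(seqnames(u), ":", start(u)),
                                vapply(samples, sampleId, "")))
  for (j in seq_along(samples)) {
    i <- GenomicRanges::match(grs[[j]], u)
    mat[i, j] <- mcols(grs[[j]])$level
  }
  mat
}

#' Non-overlapping 1-kb genome tiles
#'
#' Fixed-width segmentation of the genome (step = width), the tiling used
#' for tile-level methylation summaries.
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param width tile width in bp (default 1000).
#' @return GRanges of tiles.
#' @export
makeTiles <- function(chromLengths, width = 1000L) {
  makeWindows(chromLengths, width = width, step = width)
}
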