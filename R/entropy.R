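## entropy_heterogeneity: read-level intratumor methylation heterogeneity
## via Shannon entropy of 4-CpG epiallele patterns.

#' All 16 binary patterns of a 4-CpG epiallele
#' @export
epialleles4 <- apply(expand.grid(rep(list(0:1), 4))[, 4:1], 1,
                     paste, collapse = "")

#' Normalised Shannon entropy of a 4-CpG epiallele locus
#'
#' For pattern counts n_1..n_16 with total N, the entropy is
#' \deqn{E = -\frac{1}{4} \sum_{i: n_i > 0} \frac{n_i}{N}
#'       \log_2 \frac{n_i}{N}}
#' normalised by the 4 CpGs so it lies in [0,1]: 0 when all reads share one
#' pattern, 1 only at the uniform distribution over the 16 patterns
#' (0 log 0 := 0).
#'
#' @param counts numeric vector of length 16 (or a matrix of loci x 16).
#' @return numeric entropy value(s) in [0,1].
#' @export
entropy4 <- function(counts) {
  if (is.matrix(counts)) return(apply(counts, 1, entropy4))
  stopifnot(length(counts) == 16, all(counts >= 0))
  N <- sum(counts)
  if (N == 0) stop("locus with zero reads")
  p <- counts[counts > 0] / N
  -sum(p * log2(p)) / 4
}

#' Read an epiallele-count table
#'
#' TSV with columns chrom, pos1..pos4 (0-based CpG positions of the 4-mer)
#' and 16 pattern-count columns in the order of \code{epialleles4}
#' (0000, 0001, ..., 1111).
#'
#' @param path TSV file with header.
#' @return data.frame with a \code{total} column appended.
#' @export
readEpialleles <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 21)
  df$total <- rowSums(df[, 6:21])
  df
}

#' Per-CGI mean epiallele entropy
#'
#' Filters loci to the read-depth window (default 10..150 reads), computes
#' \code{\link{entropy4}} per locus, assigns each locus to CGIs by >= 1 bp
#' overlap of its span (first to last CpG) and averages entropies per CGI.
#' CGIs with no qualifying locus are omitted.
#'
#' @param epi data.frame from \code{\link{readEpialleles}} (or the same
#'   schema built in memory).
#' @param cgis GRanges of CpG islands.
#' @param minReads,maxReads depth window per locus (defaults 10 and 150).
#' @return data.frame: cgi, chrom, start, end, mean_entropy, n_loci.
#' @export
cgiEntropy <- function(epi, cgis, minReads = 10L, maxReads = 150L) {
  tot <- rowSums(epi[, 6:21])
  keep <- tot >= minReads & tot <= maxReads
  epi <- epi[keep, , drop = FALSE]
  ids <- .featureIds(cgis)
  if (!nrow(epi))
    return(data.frame(cgi = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mean_entropy = numeric(), n_loci = integer()))
  ent <- entropy4(as.matrix(epi[, 6:21]))
  span <- GRanges(epi$chrom, IRanges(epi$pos1 + 1L, epi$pos4 + 1L))
  hits <- findOverlaps(cgis, span, ignore.strand = TRUE)
  f <- factor(queryHits(hits), levels = seq_along(cgis))
  n <- as.integer(table(f))
  s <- as.numeric(tapply(ent[subjectHits(hits)], f, sum, default = 0))
  keep <- n > 0
  data.frame(cgi = ids[keep], chrom = as.character(seqnames(cgis))[keep],
             start = start(cgis)[keep] - 1L, end = end(cgis)[keep],
             mean_entropy = s[keep] / n[keep], n_loci = n[keep],
             stringsAsFactors = FALSE)
}

#' Genome-wide and CGI-restricted per-sample entropy summaries
#'
#' Mean locus entropy over all qualifying loci (genome-wide) and over loci
#' overlapping CGIs.
#'
#' @inheritParams cgiEntropy
#' @return named numeric vector c(genome_wide, cgi).
#' @export
sampleEntropySummary <- function(epi, cgis, minReads = 10L,
                                 maxReads = 150L) {
  tot <- rowSums(epi[, 6:21])
  keep <- tot >= minReads & tot <= maxReads
  epi <- epi[keep, , drop = FALSE]
  if (!nrow(epi)) return(c(genome_wide = NA_real_, cgi = NA_real_))
  ent <- entropy4(as.matrix(epi[, 6:21]))
  span <- GRanges(epi$chrom, IRanges(epi$pos1 + 1L, epi$pos4 + 1L))
  inCgi <- overlapsAny(span, cgis, ignore.strand = TRUE)
  c(genome_wide = mean(ent),
    cgi = if (any(inCgi)) mean(ent[inCgi]) else NA_real_)
}

#' Compare per-sample entropy between sample groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on per-sample mean entropies;
#' groups with fewer than 2 samples are skipped with a note.
#'
#' @param groups named character vector sample -> group.
#' @param entropies named numeric vector of per-sample mean entropies.
#' @return data.frame: group1, group2, n1, n2, median1, median2, p, note.
#' @export
compareEntropy <- function(groups, entropies) {
  entropies <- entropies[names(groups)]
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- entropies[groups == pr[1]]; b <- entropies[groups == pr[2]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(group1 = pr[1], group2 = pr[2],
                        n1 = length(a), n2 = length(b),
                        median1 = NA_real_, median2 = NA_real_,
                        p = NA_real_, note = "group of size < 2; skipped"))
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(a),
               n2 = length(b), median1 = median(a), median2 = median(b),
               p = p, note = "")
  }))
}
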