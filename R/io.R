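## methylome_io: reading/writing methylation tables and BED intervals with
## uniform 0-based half-open coordinates and coverage filtering.

AUTOSOME_RE <- "^chr([0-9]+)$"

#' Read a per-sample CpG methylation table
#'
#' Reads a bedGraph-like TSV (columns: chrom, start, end, level, coverage;
#' 0-based half-open, one CpG per row) and applies the standard WGBS
#' coverage filter: only CpGs covered by at least \code{minCov} and at most
#' \code{maxCov} reads are retained, and by default only autosomes
#' (chr1..chrN) are kept -- chrX is excluded because methylation differs
#' between female and male samples.
#'
#' @param path TSV file (plain or gzip); no header.
#' @param sampleId sample identifier; defaults to the file base name.
#' @param group group/subtype label.
#' @param minCov,maxCov inclusive coverage bounds (defaults 10 and 150; use
#'   \code{minCov = 5} for the low-coverage cell-line profile).
#' @param autosomesOnly drop non-autosomal chromosomes (default TRUE).
#' @return A \linkS4class{SampleMethylome}. The numbers of retained and
#'   dropped CpGs are reported via \code{message}.
#' @export
readMethylome <- function(path, sampleId = NULL, group = "unknown",
                          minCov = 10, maxCov = 150, autosomesOnly = TRUE) {
  if (is.null(sampleId))
    sampleId <- sub("\\.(tsv|txt|bedgraph|bedGraph)(\\.gz)?$", "",
                    basename(path))
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               colClasses = c("character", "integer", "integer",
                              "numeric", "integer")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL
      else stop("malformed methylation table '", path, "': ",
                conditionMessage(e), call. = FALSE)
    })
  if (is.null(df) || nrow(df) == 0) {
    warning("empty methylation file: ", path)
    return(SampleMethylome(GRanges(level = numeric(), coverage = integer()),
                           sampleId, group))
  }
  bad <- which(is.na(df[[2]]) | is.na(df[[4]]) | is.na(df[[5]]))
  if (length(bad))
    stop("malformed record at line ", bad[1], " of '", path, "'")
  bad <- which(df[[4]] < 0 | df[[4]] > 1)
  if (length(bad))
    stop("methylation level outside [0,1] at line ", bad[1], " of '",
         path, "'")
  n0 <- nrow(df)
  keep <- df[[5]] >= minCov & df[[5]] <= maxCov
  if (autosomesOnly) keep <- keep & grepl(AUTOSOME_RE, df[[1]])
  df <- df[keep, , drop = FALSE]
  message(sampleId, ": retained ", nrow(df), "/", n0,
          " CpGs after coverage [", minCov, ",", maxCov, "]",
          if (autosomesOnly) " and autosome" else "", " filtering")
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, width = 1L),
                level = df[[4]], coverage = df[[5]])
  SampleMethylome(gr, sampleId, group)
}

#' Write a SampleMethylome as a bedGraph-like TSV
#'
#' Inverse of \code{\link{readMethylome}} on already-filtered calls:
#' columns chrom, start (0-based), end, level, coverage.
#'
#' @param x a \linkS4class{SampleMethylome}.
#' @param path output path (".gz" suffix writes gzip).
#' @export
writeMethylome <- function(x, path) {
  stopifnot(is(x, "SampleMethylome"))
  gr <- cpgCalls(x)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   level = mcols(gr)$level, coverage = mcols(gr)$coverage)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of labelled intervals
#'
#' BED4/BED6 (chrom, start, end, optional name/score/strand), 0-based
#' half-open on disk; returned as a GRanges with a \code{label} metadata
#' column and a \code{setName} attribute.
#'
#' @param path BED file (plain or gzip).
#' @param name a set name, e.g. "CGI", "PMD"; stored in
#'   \code{metadata}-style attribute \code{setName}.
#' @return GRanges with \code{label} column.
#' @export
readIntervals <- function(path, name = basename(path)) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character")
  if (ncol(df) < 3) stop("BED file needs >= 3 columns: ", path)
  st <- as.integer(df[[2]]); en <- as.integer(df[[3]])
  if (any(is.na(st) | is.na(en))) stop("non-integer coordinates in ", path)
  bad <- which(st >= en)
  if (length(bad))
    stop("interval with start >= end at line ", bad[1], " of '", path, "'")
  lab <- if (ncol(df) >= 4) df[[4]] else rep(".", nrow(df))
  strand <- if (ncol(df) >= 6) df[[6]] else rep("*", nrow(df))
  gr <- GRanges(df[[1]], IRanges(st + 1L, en), strand = strand, label = lab)
  attr(gr, "setName") <- name
  gr
}

#' Write labelled intervals as BED
#'
#' @param gr GRanges (optionally with \code{label}); written as BED4 (BED6
#'   when any strand is set). \code{writeIntervals} then
#'   \code{\link{readIntervals}} round-trips to an identical set.
#' @param path output path.
#' @export
writeIntervals <- function(gr, path) {
  lab <- if (!is.null(mcols(gr)$label)) as.character(mcols(gr)$label)
         else rep(".", length(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr), label = lab)
  if (any(strand(gr) != "*")) {
    df$score <- 0L
    df$strand <- as.character(strand(gr))
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Derive CGI shores and shelves
#'
#' Shores are the 2 kb flanking each CpG island on either side; shelves are
#' the next 2 kb outward from the shores. Both are clipped at chromosome
#' bounds (when seqlengths are set) and trimmed so that no shore or shelf
#' base overlaps any CGI; shelf bases overlapping a shore of a neighbouring
#' island are likewise removed, so CGI/shore/shelf are disjoint.
#'
#' @param cgis GRanges of CpG islands.
#' @param flank band width in bp (default 2000).
#' @return list with GRanges elements \code{shores} and \code{shelves}
#'   (reduced, i.e. merged where bands from adjacent islands abut).
#' @export
deriveShoresShelves <- function(cgis, flank = 2000L) {
  cgis <- reduce(granges(cgis))
  shoreRaw <- .flankBoth(cgis, flank, 0L)
  shelfRaw <- .flankBoth(cgis, flank, flank)
  shores <- GenomicRanges::setdiff(shoreRaw, cgis, ignore.strand = TRUE)
  shelves <- GenomicRanges::setdiff(shelfRaw,
                                    GenomicRanges::union(cgis, shores),
                                    ignore.strand = TRUE)
  list(shores = shores, shelves = shelves)
}

## both-side flank band at `offset` bp away from the interval, clipped at
## [1, seqlength] before construction so no invalid range is ever built
.flankBoth <- function(gr, width, offset) {
  chr <- rep(as.character(seqnames(gr)), 2)
  st <- c(start(gr) - offset - width, end(gr) + offset + 1L)
  en <- c(start(gr) - offset - 1L, end(gr) + offset + width)
  st <- pmax(st, 1L)
  sl <- seqlengths(gr)[chr]
  clip <- !is.na(sl)
  en[clip] <- pmin(en[clip], sl[clip])
  keep <- en >= st
  out <- GRanges(chr[keep], IRanges(st[keep], en[keep]),
                 seqlengths = seqlengths(gr))
  reduce(out)
}
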