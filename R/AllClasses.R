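#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps pintersect reduce gaps tileGenome mcols mcols<- start<-
#'   end<- strand<-
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   sortSeqlevels keepSeqlevels
#' @importFrom stats cor cutree dist hclust mad median p.adjust pchisq
#'   prcomp pt quantile rbinom rnorm rpois runif sd setNames rmultinom
#'   chisq.test fisher.test wilcox.test cor.test ks.test
#' @importFrom utils read.table write.table head tail
NULL

#' SampleMethylome: filtered per-CpG methylation calls for one sample
#'
#' Holds the per-CpG methylation level and read coverage of a single WGBS
#' sample as a sorted \link[GenomicRanges]{GRanges} (one-base ranges, one per
#' CpG) with metadata columns \code{level} (beta value in [0,1]) and
#' \code{coverage} (read count). The object is the atomic input of every
#' downstream stage; construct it with \code{\link{readMethylome}} or
#' \code{\link{simulateSample}}.
#'
#' @slot calls GRanges of width-1 CpG positions with \code{level} and
#'   \code{coverage} metadata columns, sorted, unique per (chrom, pos).
#' @slot sampleId single character sample identifier.
#' @slot group single character group/subtype label (e.g. "control",
#'   "tumor").
#' @export
setClass("SampleMethylome",
  representation(calls = "GRanges", sampleId = "character",
                 group = "character"))

setValidity("SampleMethylome", function(object) {
  msg <- character()
  gr <- object@calls
  mc <- mcols(gr)
  if (!all(c("level", "coverage") %in% colnames(mc)))
    msg <- c(msg, "calls must carry 'level' and 'coverage' metadata columns")
  else {
    lv <- mc$level
    if (length(lv) && (anyNA(lv) || any(lv < 0 | lv > 1)))
      msg <- c(msg, "methylation levels must lie in [0,1]")
    if (length(mc$coverage) && any(mc$coverage < 0))
      msg <- c(msg, "coverage must be non-negative")
  }
  if (length(gr) && any(width(gr) != 1))
    msg <- c(msg, "CpG calls must be width-1 ranges")
  if (is.unsorted(order(as.integer(seqnames(gr)), start(gr))))
    msg <- c(msg, "calls must be sorted by (chrom, pos)")
  if (length(object@sampleId) != 1) msg <- c(msg, "sampleId must be length 1")
  if (length(object@group) != 1) msg <- c(msg, "group must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleMethylome
#'
#' @param calls GRanges of width-1 CpG positions with \code{level} and
#'   \code{coverage} metadata columns.
#' @param sampleId sample identifier.
#' @param group group/subtype label.
#' @return A \linkS4class{SampleMethylome}.
#' @export
SampleMethylome <- function(calls, sampleId, group = "unknown") {
  calls <- GenomicRanges::sort(calls)
  if (anyDuplicated(paste0(seqnames(calls), ":", start(calls))))
    stop("duplicate CpG positions in '", sampleId, "'")
  new("SampleMethylome", calls = calls, sampleId = as.character(sampleId),
      group = as.character(group))
}

#' @describeIn SampleMethylome-accessors CpG calls as a GRanges
#' @export
setGeneric("cpgCalls", function(x) standardGeneric("cpgCalls"))

#' @describeIn SampleMethylome-accessors methylation levels
#' @export
setGeneric("methLevel", function(x) standardGeneric("methLevel"))

#' @describeIn SampleMethylome-accessors read coverage
#' @export
setGeneric("methCoverage", function(x) standardGeneric("methCoverage"))

#' @describeIn SampleMethylome-accessors sample identifier
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @describeIn SampleMethylome-accessors group label
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))

#' Accessors for SampleMethylome
#'
#' @param x a \linkS4class{SampleMethylome}.
#' @name SampleMethylome-accessors
NULL

#' @rdname SampleMethylome-accessors
#' @export
setMethod("cpgCalls", "SampleMethylome", function(x) x@calls)

#' @rdname SampleMethylome-accessors
#' @export
setMethod("methLevel", "SampleMethylome", function(x) mcols(x@calls)$level)

#' @rdname SampleMethylome-accessors
#' @export
setMethod("methCoverage", "SampleMethylome",
          function(x) mcols(x@calls)$coverage)

#' @rdname SampleMethylome-accessors
#' @export
setMethod("sampleId", "SampleMethylome", function(x) x@sampleId)

#' @rdname SampleMethylome-accessors
#' @export
setMethod("sampleGroup", "SampleMethylome", function(x) x@group)

setMethod("show", "SampleMethylome", function(object) {
  cat("SampleMethylome '", object@sampleId, "' (group: ", object@group,
      ")\n", sep = "")
  cat("  ", length(object@calls), " CpG calls on ",
      length(unique(as.character(seqnames(object@calls)))),
      " chromosome(s)\n", sep = "")
  if (length(object@calls))
    cat("  mean level ", round(mean(mcols(object@calls)$level), 3),
        ", median coverage ", median(mcols(object@calls)$coverage),
        "\n", sep = "")
})

setMethod("length", "SampleMethylome", function(x) length(x@calls))

#' ConsensusResult: output of Monti-style consensus clustering
#'
#' @slot consensus named list of item-by-item consensus matrices, one per k
#'   in 2..maxK; entries are co-clustering frequencies in [0,1], diagonal 1.
#' @slot assignments named list of integer item assignments per k, clusters
#'   relabelled 1..k by ascending mean methylation.
#' @slot diagnostics data.frame of consensus-CDF area and delta-area per k,
#'   the basis on which a caller judges k.
#' @slot itemMeans numeric per-item mean methylation used for relabelling.
#' @export
setClass("ConsensusResult",
  representation(consensus = "list", assignments = "list",
                 diagnostics = "data.frame", itemMeans = "numeric"))

setValidity("ConsensusResult", function(object) {
  for (cm in object@consensus) {
    if (!isSymmetric(unname(cm))) return("consensus matrices must be symmetric")
    if (any(cm < -1e-9 | cm > 1 + 1e-9)) return("consensus values must lie in [0,1]")
    if (any(abs(diag(cm) - 1) > 1e-9)) return("consensus diagonal must be 1")
  }
  TRUE
})

setMethod("show", "ConsensusResult", function(object) {
  ks <- names(object@assignments)
  cat("ConsensusResult over", nrow(object@consensus[[1]]), "items, k =",
      paste(ks, collapse = ","), "\n")
  print(object@diagnostics, row.names = FALSE)
})

#' @describeIn ConsensusResult-accessors consensus matrix for a given k
#' @export
setGeneric("consensusMatrix", function(x, k) standardGeneric("consensusMatrix"))

#' @describeIn ConsensusResult-accessors item assignments for a given k
#' @export
setGeneric("clusterAssignments",
           function(x, k) standardGeneric("clusterAssignments"))

#' Accessors for ConsensusResult
#'
#' @param x a \linkS4class{ConsensusResult}.
#' @param k number of clusters (2..maxK used at construction).
#' @name ConsensusResult-accessors
NULL

#' @rdname ConsensusResult-accessors
#' @export
setMethod("consensusMatrix", "ConsensusResult",
          function(x, k) x@consensus[[as.character(k)]])

#' @rdname ConsensusResult-accessors
#' @export
setMethod("clusterAssignments", "ConsensusResult",
          function(x, k) x@assignments[[as.character(k)]])
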