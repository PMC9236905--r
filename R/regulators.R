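## regulator_screen: promoter definition, epigenetic-regulator promoter
## methylation panel, expression-methylation correlation screen and
## variable-gene sample clustering.

#' Epigenetic regulators screened for promoter methylation and expression
#'
#' DNA methyltransferases and TET enzymes, recruiters/regulators reported
#' in leukemia, Polycomb core members, H3K9 methyltransferases, chromatin
#' remodellers and related factors. SUV39H1 is X-linked and excluded by
#' default analyses (autosome-only policy).
#' @export
regulatorPanelGenes <- c(
  "DNMT1", "DNMT3A", "DNMT3B", "TET1", "TET2", "TET3",
  "MYC", "WT1", "IDH1", "IDH2",
  "EED", "EZH2", "SUZ12", "RING1", "RNF2", "KDM2B", "BAP1",
  "SUV39H1", "SUV39H2", "EHMT2",
  "ARID1A", "ARID1B", "ARID2", "PBRM1", "SMARCA4", "SMARCB1",
  "QSER1", "HELLS")

#' Strand-aware promoter intervals
#'
#' Promoters span 1,500 bp upstream and 500 bp downstream of the annotated
#' TSS: plus strand [TSS-1500, TSS+500), minus strand [TSS-500, TSS+1500)
#' in 0-based half-open coordinates; clipped at chromosome bounds.
#'
#' @param genes GRanges of gene models with strand set (+/-) and names (or
#'   a \code{label} column) giving gene ids; the TSS is the 5' end.
#' @param upstream,downstream promoter extent in bp (defaults 1500/500).
#' @return GRanges of promoters named by gene.
#' @export
definePromoters <- function(genes, upstream = 1500L, downstream = 500L) {
  if (any(strand(genes) == "*"))
    stop("gene models must have strand '+' or '-'")
  ids <- .featureIds(genes)
  plus <- as.logical(strand(genes) == "+")
  tss <- ifelse(plus, start(genes), end(genes))
  st <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  en <- ifelse(plus, tss + downstream - 1L, tss + upstream)
  st <- pmax(st, 1L)
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  clip <- !is.na(sl)
  en[clip] <- pmin(en[clip], sl[clip])
  out <- GRanges(seqnames(genes), IRanges(st, en), strand = strand(genes),
                 seqlengths = seqlengths(genes))
  names(out) <- ids
  out
}

#' Promoter methylation panel
#'
#' Per panel gene: CGIs are assigned to the promoter when at least 20\% of
#' the promoter AND at least 20\% of the island overlap (the conjunctive
#' rule); the promoter methylation is the mean of all assigned CGI means.
#' Genes with no promoter CGI fall back to the mean of CpG levels within
#' the promoter region itself (requiring >= \code{minCpGs} CpGs, else the
#' status is "uncallable"). Hypermethylated iff the mean is strictly
#' greater than \code{threshold}.
#'
#' @param sample a \linkS4class{SampleMethylome}.
#' @param promoters GRanges of promoters (named by gene), e.g. from
#'   \code{\link{definePromoters}}.
#' @param cgis GRanges of CpG islands.
#' @param threshold hypermethylation cutoff (default 0.2, strict >).
#' @param minCpGs minimum CpGs for CGI means and the region fallback
#'   (default 3).
#' @param frac overlap fraction of the conjunctive rule (default 0.2).
#' @return data.frame: gene, mean, source ("promoter_cgi" |
#'   "promoter_region" | "uncallable"), n_cgis, hypermethylated.
#' @export
promoterPanel <- function(sample, promoters, cgis, threshold = 0.2,
                          minCpGs = 3L, frac = 0.2) {
  stopifnot(is(sample, "SampleMethylome"))
  cgiMeans <- featureMeans(sample, cgis, minCpGs = minCpGs)
  cgiKey <- paste0(as.character(seqnames(cgis)), ":", start(cgis) - 1L,
                   "-", end(cgis))
  cgiMeanByIdx <- setNames(cgiMeans$mean,
                           paste0(cgiMeans$chrom, ":", cgiMeans$start,
                                  "-", cgiMeans$end))
  hits <- findOverlaps(promoters, cgis, ignore.strand = TRUE)
  ov <- width(pintersect(promoters[queryHits(hits)], cgis[subjectHits(hits)],
                         ignore.strand = TRUE))
  pass <- ov >= frac * width(promoters)[queryHits(hits)] &
          ov >= frac * width(cgis)[subjectHits(hits)]
  hq <- queryHits(hits)[pass]; hs <- subjectHits(hits)[pass]
  gr <- cpgCalls(sample)
  rows <- lapply(seq_along(promoters), function(i) {
    gene <- names(promoters)[i]
    cgiIdx <- hs[hq == i]
    if (length(cgiIdx)) {
      m <- cgiMeanByIdx[cgiKey[cgiIdx]]
      m <- m[!is.na(m)]
      if (length(m))
        return(data.frame(gene = gene, mean = mean(m),
                          source = "promoter_cgi", n_cgis = length(m),
                          stringsAsFactors = FALSE))
    }
    inProm <- overlapsAny(gr, promoters[i], ignore.strand = TRUE)
    if (sum(inProm) >= minCpGs)
      return(data.frame(gene = gene, mean = mean(mcols(gr)$level[inProm]),
                        source = "promoter_region", n_cgis = 0L,
                        stringsAsFactors = FALSE))
    data.frame(gene = gene, mean = NA_real_, source = "uncallable",
               n_cgis = 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$hypermethylated <- !is.na(out$mean) & out$mean > threshold
  out
}

#' Correlate gene expression with sample methylation summaries
#'
#' Spearman correlation of per-gene log2(TPM + 1) with a per-sample
#' methylation summary (global non-CGI mean and/or CGI mean), across
#' samples. Genes with average TPM below \code{minTPM} are excluded before
#' testing; constant expression vectors are skipped with a note; p values
#' are Benjamini-Hochberg adjusted across tested genes and hits called at
#' adjusted p < \code{alpha}.
#'
#' @param expr numeric gene x sample TPM matrix.
#' @param summaries named list of per-sample methylation summaries (named
#'   numeric vectors over the same samples), e.g.
#'   \code{list(global = ..., cgi = ...)}.
#' @param minTPM expression floor on the average TPM (default 0.5).
#' @param alpha adjusted-p hit threshold (default 0.01).
#' @return named list of data.frames (gene, rho, p, padj, hit), one per
#'   summary, plus \code{overlap}: genes hit in every summary.
#' @export
correlationScreen <- function(expr, summaries, minTPM = 0.5,
                              alpha = 0.01) {
  stopifnot(is.matrix(expr), is.list(summaries))
  samples <- colnames(expr)
  if (length(samples) < 5) stop("need >= 5 samples with both data types")
  keep <- rowMeans(expr) >= minTPM
  lex <- log2(expr[keep, , drop = FALSE] + 1)
  res <- lapply(summaries, function(ms) {
    ms <- ms[samples]
    const <- apply(lex, 1, function(v) length(unique(v)) == 1)
    tested <- lex[!const, , drop = FALSE]
    ct <- spearmanRows(tested, ms)
    padj <- p.adjust(ct$p, method = "BH")
    out <- data.frame(gene = rownames(tested), rho = ct$rho, p = ct$p,
                      padj = padj, hit = padj < alpha,
                      stringsAsFactors = FALSE)
    if (any(const))
      attr(out, "skipped") <- rownames(lex)[const]
    out
  })
  hitSets <- lapply(res, function(d) d$gene[d$hit])
  res$overlap <- Reduce(intersect, hitSets)
  res
}

#' Row-wise Spearman correlation with p values
#'
#' Spearman rho of each matrix row against a single vector, with average
#' ranks for ties; p values from the t approximation for n > 9 and from
#' \code{cor.test}'s exact distribution for n <= 9 without ties.
#'
#' @param mat numeric matrix (rows tested) and \code{y} a vector of length
#'   \code{ncol(mat)}.
#' @param y numeric vector.
#' @return list with numeric vectors \code{rho} and \code{p}.
#' @export
spearmanRows <- function(mat, y) {
  n <- ncol(mat)
  if (n <= 9) {
    res <- apply(mat, 1, function(v) {
      ct <- suppressWarnings(cor.test(v, y, method = "spearman"))
      c(ct$estimate, ct$p.value)
    })
    return(list(rho = unname(res[1, ]), p = unname(res[2, ])))
  }
  ry <- rank(y)
  rm <- t(apply(mat, 1, rank))
  rho <- as.numeric(cor(t(rm), ry))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = pmin(p, 1))
}

#' Cluster samples on the most variable genes
#'
#' Genes are ranked by the standard deviation of log2(TPM + 1) across
#' samples; samples are clustered hierarchically with Ward linkage
#' (ward.D2) on Euclidean distances over the top \code{topN} genes.
#'
#' @param expr numeric gene x sample TPM matrix (>= 3 samples).
#' @param topN number of variable genes (default 500; all genes with a
#'   warning when fewer exist).
#' @param k optional number of sample clusters to cut.
#' @return list: \code{genes} (selected, by descending sd), \code{hclust},
#'   \code{clusters} (if k given).
#' @export
variableGeneClustering <- function(expr, topN = 500L, k = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  lex <- log2(expr + 1)
  sds <- apply(lex, 1, sd)
  if (nrow(expr) < topN) {
    warning("fewer genes (", nrow(expr), ") than topN; using all")
    topN <- nrow(expr)
  }
  ord <- order(-sds, seq_along(sds))
  sel <- ord[seq_len(topN)]
  hc <- hclust(dist(t(lex[sel, , drop = FALSE])), method = "ward.D2")
  out <- list(genes = rownames(expr)[sel], hclust = hc)
  if (!is.null(k)) out$clusters <- cutree(hc, k = k)
  out
}
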