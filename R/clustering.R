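## cgi_clustering: variable-CGI selection, PCA with projection, Monti-style
## consensus clustering (PAM, Euclidean), methylation-based sample grouping,
## cluster characterisation and covariate tests.

#' Select variably methylated CGIs
#'
#' Drops CGIs whose mean methylation is below \code{low} in \emph{all}
#' samples (constitutively unmethylated) or above \code{high} in all
#' samples (constitutively methylated); the rest are the variable CGIs on
#' which clustering and PCA operate. Idempotent.
#'
#' @param mat numeric matrix, CGIs x samples, complete on the considered
#'   samples (commonly covered CGIs).
#' @param low,high exclusion bounds (defaults 0.2 and 0.8, strict).
#' @return the row-subset matrix.
#' @export
selectVariableCGIs <- function(mat, low = 0.2, high = 0.8) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  allLow <- rowSums(mat < low) == ncol(mat)
  allHigh <- rowSums(mat > high) == ncol(mat)
  out <- mat[!allLow & !allHigh, , drop = FALSE]
  if (!nrow(out)) stop("no variable CGIs remain after filtering")
  out
}

#' Binarize methylation status
#'
#' Entry 1 iff the mean methylation is strictly greater than
#' \code{threshold} (methylated), else 0.
#'
#' @param mat numeric matrix in [0,1].
#' @param threshold methylated cutoff (default 0.2, strict >).
#' @return integer 0/1 matrix of the same shape.
#' @export
binarizeStatus <- function(mat, threshold = 0.2) {
  stopifnot(all(mat >= 0 & mat <= 1, na.rm = TRUE))
  out <- (mat > threshold) + 0L
  dimnames(out) <- dimnames(mat)
  out
}

#' Centered PCA with projection of held-out samples
#'
#' PCA (centered, not scaled) of a training matrix of samples x features;
#' additional samples (e.g. cell lines) are projected onto the trained
#' components using the training centering and loadings, so they do not
#' influence the decomposition.
#'
#' @param train numeric matrix, samples x features, complete.
#' @param project optional matrix of samples x the same features.
#' @return list with \code{scores} (train), \code{projected} (or NULL),
#'   \code{loadings}, \code{explained} (variance fractions), \code{center}.
#' @export
pcaWithProjection <- function(train, project = NULL) {
  stopifnot(is.matrix(train), nrow(train) >= 2, !anyNA(train))
  pc <- prcomp(train, center = TRUE, scale. = FALSE)
  projected <- NULL
  if (!is.null(project)) {
    stopifnot(ncol(project) == ncol(train))
    projected <- scale(project, center = pc$center, scale = FALSE) %*%
      pc$rotation
  }
  list(scores = pc$x, projected = projected, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2), center = pc$center)
}

#' Monti-style consensus clustering of items (PAM, Euclidean)
#'
#' For each k in 2..\code{maxK}: \code{reps} subsamples of
#' \code{ceiling(pItem * n)} items (all features retained) are each
#' partitioned with PAM (Euclidean distance, deterministic BUILD+SWAP);
#' consensus(i, j) is the number of times i and j co-clustered divided by
#' the number of times both were subsampled. The final assignment at each k
#' is hierarchical clustering (average linkage) of 1 - consensus cut at k,
#' with clusters relabelled 1..k by ascending mean methylation. k is not
#' chosen automatically: consensus-CDF area and delta-area diagnostics are
#' returned for the caller to judge (the workflow default downstream is 4).
#'
#' @param mat numeric matrix, items (e.g. CGIs) x samples.
#' @param maxK largest k examined (default 12).
#' @param reps subsampling replicates (default 100).
#' @param pItem item subsampling proportion (default 0.8).
#' @param seed integer RNG seed; fixes the whole subsample sequence.
#' @return a \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(mat, maxK = 12L, reps = 100L, pItem = 0.8,
                             seed = 1L) {
  stopifnot(is.matrix(mat), nrow(mat) >= maxK, !anyNA(mat))
  n <- nrow(mat)
  m <- ceiling(pItem * n)
  ks <- 2:maxK
  subs <- withr::with_seed(seed, {
    lapply(seq_len(reps), function(r) sort(sample.int(n, m)))
  })
  coSampled <- matrix(0, n, n)
  for (idx in subs) coSampled[idx, idx] <- coSampled[idx, idx] + 1
  if (any(coSampled[upper.tri(coSampled)] == 0))
    stop("some item pairs were never co-subsampled; increase reps")
  dists <- lapply(subs, function(idx) dist(mat[idx, , drop = FALSE]))
  consensus <- list(); assignments <- list()
  itemMeans <- rowMeans(mat)
  for (k in ks) {
    co <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- subs[[r]]
      cl <- cluster::pam(dists[[r]], k = k, cluster.only = TRUE,
                         pamonce = 5)
      for (g in seq_len(k)) {
        members <- idx[cl == g]
        co[members, members] <- co[members, members] + 1
      }
    }
    cm <- co / coSampled
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(mat), rownames(mat))
    hc <- hclust(stats::as.dist(1 - cm), method = "average")
    raw <- cutree(hc, k = k)
    assignments[[as.character(k)]] <- .relabelByMean(raw, itemMeans)
    consensus[[as.character(k)]] <- cm
  }
  diagnostics <- .consensusCDF(consensus, ks)
  new("ConsensusResult", consensus = consensus, assignments = assignments,
      diagnostics = diagnostics, itemMeans = itemMeans)
}

## relabel clusters 1..k by ascending mean methylation of their items
.relabelByMean <- function(assign, itemMeans) {
  mk <- tapply(itemMeans, assign, mean)
  rank <- setNames(order(order(mk)), names(mk))
  out <- rank[as.character(assign)]
  names(out) <- names(assign)
  as.integer(out) |> setNames(names(assign))
}

## area under the consensus CDF per k and the relative delta-area
.consensusCDF <- function(consensus, ks) {
  auc <- vapply(consensus, function(cm) {
    v <- sort(cm[upper.tri(cm)])
    cdf <- seq_along(v) / length(v)
    sum(diff(c(0, v)) * c(0, cdf[-length(cdf)]))
  }, 0)
  delta <- c(auc[1], diff(auc) / auc[-length(auc)])
  data.frame(k = ks, auc = unname(auc), delta_auc = unname(delta))
}

#' Group samples by CGI methylation into LM/IM/HM
#'
#' Hierarchical clustering of samples (Euclidean distance, average linkage)
#' on the variable-CGI matrix, cut at the top-level three clusters; groups
#' are named LM, IM and HM by ascending mean CGI methylation (low,
#' intermediate, high methylation). The labels depend only on the matrix
#' values, not on sample order.
#'
#' @param mat numeric matrix, samples x variable CGIs, complete; >= 3
#'   samples.
#' @param linkage hclust linkage (default "average").
#' @return named character vector sample -> "LM"/"IM"/"HM".
#' @export
groupSamples <- function(mat, linkage = "average") {
  stopifnot(is.matrix(mat), !anyNA(mat), !is.null(rownames(mat)),
            !anyDuplicated(rownames(mat)))
  if (nrow(mat) < 3) stop("need at least 3 samples to form three groups")
  d <- dist(mat)
  if (all(d < 1e-12))
    stop("all samples identical; dendrogram degenerate, cannot form groups")
  ord <- order(rownames(mat))           # order-invariance of the tree
  hc <- hclust(dist(mat[ord, , drop = FALSE]), method = linkage)
  cl <- cutree(hc, k = 3)[rownames(mat)]
  gm <- tapply(rowMeans(mat), cl, mean)
  lab <- setNames(c("LM", "IM", "HM")[order(order(gm))], names(gm))
  setNames(unname(lab[as.character(cl)]), rownames(mat))
}

#' Characterise CGI clusters against genomic features and chromatin states
#'
#' Per cluster: the fraction of CGIs overlapping each feature set under the
#' conjunctive-free 20\% rule (either 20\% of the CGI or 20\% of the
#' feature); CGIs overlapping neither promoters nor gene bodies are termed
#' intergenic; active promoters are promoters of genes with average control
#' TPM >= \code{minTPM}. Chromatin-state composition (largest overlap) is
#' compared between the two supplied cell states per cluster with a
#' chi-squared test and a Cramer's V effect size.
#'
#' @param cgis GRanges of the clustered CGIs (in matrix row order).
#' @param clusters integer cluster assignment per CGI.
#' @param featureSets named list of GRanges (e.g. promoter, DMV, PMD,
#'   gene_body).
#' @param states list of two GRanges with \code{label} columns: chromatin
#'   states of two cell states.
#' @param promoterGenes optional character vector aligned to
#'   \code{featureSets$promoter} giving the gene of each promoter.
#' @param expr optional ExpressionMatrix-like gene x sample TPM matrix for
#'   the control cell state (defines active promoters).
#' @param minTPM active-promoter expression cutoff (default 1).
#' @return list with \code{fractions} (cluster x class data.frame) and
#'   \code{stateTests} (per-cluster chi-squared p and Cramer's V).
#' @export
characterizeClusters <- function(cgis, clusters, featureSets,
                                 states = NULL, promoterGenes = NULL,
                                 expr = NULL, minTPM = 1) {
  stopifnot(length(clusters) == length(cgis))
  sets <- featureSets
  if (!is.null(expr) && !is.null(promoterGenes) &&
      "promoter" %in% names(sets)) {
    avg <- rowMeans(expr)
    active <- names(avg)[avg >= minTPM]
    sets$active_promoter <- sets$promoter[promoterGenes %in% active]
  }
  hitMat <- vapply(sets, function(fs) .qualOverlapFlag(cgis, fs, 0.2),
                   logical(length(cgis)))
  if (all(c("promoter", "gene_body") %in% colnames(hitMat)))
    hitMat <- cbind(hitMat,
                    intergenic = !hitMat[, "promoter"] &
                                 !hitMat[, "gene_body"])
  fr <- apply(hitMat, 2, function(col) tapply(col, clusters, mean))
  fractions <- data.frame(cluster = sort(unique(clusters)),
                          as.data.frame(fr), row.names = NULL)
  stateTests <- NULL
  if (!is.null(states)) {
    stopifnot(length(states) == 2)
    a1 <- assignLargestOverlap(cgis, states[[1]])
    a2 <- assignLargestOverlap(cgis, states[[2]])
    lev <- sort(unique(c(a1, a2)))
    stateTests <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
      t1 <- table(factor(a1[clusters == cl], levels = lev))
      t2 <- table(factor(a2[clusters == cl], levels = lev))
      tab <- rbind(t1, t2)
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2 || identical(unname(t1), unname(t2))) {
        data.frame(cluster = cl, statistic = 0, p = 1, cramers_v = 0)
      } else {
        ct <- suppressWarnings(chisq.test(tab))
        v <- sqrt(unname(ct$statistic) /
                  (sum(tab) * (min(dim(tab)) - 1)))
        data.frame(cluster = cl, statistic = unname(ct$statistic),
                   p = ct$p.value, cramers_v = v)
      }
    }))
  }
  list(fractions = fractions, stateTests = stateTests)
}

## per-query flag: any overlap passing the 20%-either rule
.qualOverlapFlag <- function(query, features, frac) {
  out <- logical(length(query))
  if (!length(features)) return(out)
  hits <- findOverlaps(query, features, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- query[queryHits(hits)]; f <- features[subjectHits(hits)]
  ov <- width(pintersect(q, f, ignore.strand = TRUE))
  pass <- ov >= frac * width(q) | ov >= frac * width(f)
  out[unique(queryHits(hits)[pass])] <- TRUE
  out
}

#' Test covariates against sample groups
#'
#' Categorical covariates are tested against the group factor with a
#' two-sided Fisher's exact test (exact for small tables, seeded
#' Monte-Carlo p for larger ones); continuous covariates with a two-sided
#' Wilcoxon rank-sum test on a binary group split. Covariates with a single
#' level are skipped with a note.
#'
#' @param groups named character vector (e.g. from
#'   \code{\link{groupSamples}}).
#' @param covariates data.frame, rows = samples (matched by name), columns
#'   = covariates (factors/characters tested as categorical, numerics as
#'   continuous).
#' @param continuousSplit for continuous covariates, the two group labels
#'   to compare (default the first two observed).
#' @param mcCells table-size cap above which the Fisher p is Monte-Carlo
#'   (default 10 cells).
#' @param seed RNG seed for Monte-Carlo p values.
#' @return data.frame: covariate, type, test, p, note.
#' @export
covariateTests <- function(groups, covariates, continuousSplit = NULL,
                           mcCells = 10L, seed = 1L) {
  stopifnot(!is.null(rownames(covariates)) || is.data.frame(covariates))
  covariates <- covariates[names(groups), , drop = FALSE]
  rows <- lapply(colnames(covariates), function(cv) {
    x <- covariates[[cv]]
    if (is.numeric(x)) {
      gl <- continuousSplit
      if (is.null(gl)) gl <- head(sort(unique(groups)), 2)
      a <- x[groups == gl[1]]; b <- x[groups == gl[2]]
      if (length(a) < 1 || length(b) < 1)
        return(data.frame(covariate = cv, type = "continuous",
                          test = "wilcoxon", p = NA_real_,
                          note = "group empty"))
      p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      data.frame(covariate = cv, type = "continuous", test = "wilcoxon",
                 p = p, note = "")
    } else {
      x <- as.factor(as.character(x))
      if (nlevels(droplevels(x)) < 2)
        return(data.frame(covariate = cv, type = "categorical",
                          test = "fisher", p = NA_real_,
                          note = "single level; skipped"))
      tab <- table(x, groups)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      p <- if (length(tab) > mcCells)
        withr::with_seed(seed,
          fisher.test(tab, simulate.p.value = TRUE, B = 10000)$p.value)
      else fisher.test(tab)$p.value
      data.frame(covariate = cv, type = "categorical", test = "fisher",
                 p = p, note = "")
    }
  })
  do.call(rbind, rows)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of planted cluster structure.
#'
#' @param a,b integer/character assignment vectors of equal length.
#' @return numeric ARI.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
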