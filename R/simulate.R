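## synthetic_methylome: fully seeded generator of small methylome cohorts
## with planted ground truth (PMD/HMD loss, CGI-gain gradients, CGI cluster
## structure, epiallele disorder, regulator-expression coupling) so every
## analysis stage can be exercised and its recovery quantified.

#' Configuration of the synthetic methylome generator
#'
#' All sizes in bp, all methylation parameters on the beta-value scale
#' [0,1]. Defaults describe the reference study conditions used throughout
#' the tests: a 2 x 1 Mb genome, ~1 CpG per 100 bp outside CGIs, 40\% PMD,
#' 5 control + 10 tumor samples, a PMD loss of 0.15 and an HMD loss of
#' 0.03 in tumors, and a per-tumor CGI-gain gradient gamma in [0.05,
#' 0.95].
#'
#' @slot seed integer RNG seed; identical seed + config gives identical
#'   output.
#' @slot nChroms,chromLength genome geometry.
#' @slot cpgRate expected CpGs per bp outside CGIs (Poisson).
#' @slot nCGIsPerChrom,cgiLength,cgiCpGSpacing CGI number, width and
#'   regular CpG spacing inside CGIs.
#' @slot pmdFraction fraction of segments assigned PMD; \code{segmentLength}
#'   is the PMD/HMD segment grain.
#' @slot segmentLength PMD/HMD segment length.
#' @slot nControl,nTumor cohort sizes.
#' @slot deltaPMD,deltaHMD mean methylation loss planted in tumor PMD/HMD
#'   CpGs.
#' @slot gammaRange endpoints of the per-tumor CGI-gain gradient
#'   (monotone).
#' @slot clusterWeights proportions of variable CGIs over the four planted
#'   cluster profiles (sporadic, gradient-heterogeneous,
#'   gradient-homogeneous, constitutively methylated) and the unmethylated
#'   remainder; length 5, sums to 1.
#' @slot baselineHigh,baselineLow control methylation outside/inside
#'   unmethylated CGIs.
#' @slot coverageMean expected read depth (shifted Poisson, minimum 1).
#' @slot noiseSD beta-value noise standard deviation (truncated normal via
#'   clipping to [0,1]).
#' @slot soloWindow neighbour-exclusion window for solo-WCGW CpGs.
#' @slot nGenesPerChrom,geneLength gene-model geometry.
#' @slot stateSegment chromatin-state segment length for the two pseudo
#'   cell states.
#' @export
setClass("SimConfig", representation(
    seed = "integer", nChroms = "integer", chromLength = "integer",
    cpgRate = "numeric", nCGIsPerChrom = "integer", cgiLength = "integer",
    cgiCpGSpacing = "integer", pmdFraction = "numeric",
    segmentLength = "integer", nControl = "integer", nTumor = "integer",
    deltaPMD = "numeric", deltaHMD = "numeric", gammaRange = "numeric",
    clusterWeights = "numeric", baselineHigh = "numeric",
    baselineLow = "numeric", coverageMean = "numeric", noiseSD = "numeric",
    soloWindow = "integer", nGenesPerChrom = "integer",
    geneLength = "integer", stateSegment = "integer"),
  prototype(
    seed = 1L, nChroms = 2L, chromLength = 1000000L, cpgRate = 0.01,
    nCGIsPerChrom = 30L, cgiLength = 1000L, cgiCpGSpacing = 10L,
    pmdFraction = 0.4, segmentLength = 50000L, nControl = 5L,
    nTumor = 10L, deltaPMD = 0.15, deltaHMD = 0.03,
    gammaRange = c(0.05, 0.95),
    clusterWeights = c(0.15, 0.15, 0.15, 0.15, 0.40),
    baselineHigh = 0.85, baselineLow = 0.05, coverageMean = 30,
    noiseSD = 0.05, soloWindow = 35L, nGenesPerChrom = 40L,
    geneLength = 10000L, stateSegment = 2000L))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nChroms < 1 || object@chromLength < 1000)
    msg <- c(msg, "degenerate genome: need >= 1 chromosome of >= 1 kb")
  if (object@cpgRate <= 0) msg <- c(msg, "cpgRate must be positive")
  probs <- c(object@pmdFraction, object@baselineHigh, object@baselineLow,
             object@deltaPMD, object@deltaHMD, object@gammaRange,
             object@clusterWeights)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities and beta-scale parameters must lie in [0,1]")
  if (length(object@gammaRange) != 2 || diff(object@gammaRange) < 0)
    msg <- c(msg, "gammaRange must be monotone non-decreasing endpoints")
  if (length(object@clusterWeights) != 5 ||
      abs(sum(object@clusterWeights) - 1) > 1e-8)
    msg <- c(msg, "clusterWeights must be length 5 and sum to 1")
  if (object@coverageMean < 1) msg <- c(msg, "coverageMean must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param ... slot overrides of \linkS4class{SimConfig}; integers are
#'   coerced.
#' @return validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(...) {
  args <- list(...)
  proto <- new("SimConfig")
  for (nm in names(args)) {
    cls <- class(slot(proto, nm))
    slot(proto, nm) <- if (cls == "integer") as.integer(args[[nm]])
                       else as.numeric(args[[nm]])
  }
  validObject(proto)
  proto
}

## per-CGI cluster profile codes
CGI_CLUSTERS <- c("sporadic", "grad_het", "grad_hom", "constitutive",
                  "unmethylated")

#' Simulate genome annotations and planted truth
#'
#' Builds chromosomes chr1..chrN with: regularly spaced CpGs inside CGIs
#' and a Poisson process of CpGs outside; a PMD/HMD segmentation covering
#' every chromosome; CGIs assigned to one of four planted variable-cluster
#' profiles or the unmethylated remainder; flanking-base context (so a
#' subset of non-CGI CpGs is solo-WCGW); stranded gene models with
#' promoters; and chromatin-state tracks for two pseudo cell states.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list ("SimTruth") with elements \code{config},
#'   \code{chromLengths}, \code{cpgs} (GRanges with context and labels),
#'   \code{cgis}, \code{hmdPmd}, \code{genes}, \code{promoters},
#'   \code{states} (list of 2), \code{soloSites} and \code{gamma} /
#'   \code{groups} per planned sample.
#' @export
simulateGenome <- function(config) {
  validObject(config)
  chromLengths <- setNames(rep(config@chromLength, config@nChroms),
                           paste0("chr", seq_len(config@nChroms)))
  withr::with_seed(config@seed, {
    cgis <- .simCGIs(config, chromLengths)
    hmdPmd <- .simDomains(config, chromLengths)
    cpgs <- .simCpGs(config, chromLengths, cgis)
    genes <- .simGenes(config, chromLengths)
    states <- .simStates(config, chromLengths)
    nVar <- length(cgis)
    pool <- rep(seq_len(5), times = round(config@clusterWeights * nVar))
    pool <- c(pool, rep(5L, max(0, nVar - length(pool))))  # pad rounding gap
    cl <- sample(pool[seq_len(nVar)])
    mcols(cgis)$cluster <- CGI_CLUSTERS[cl]
    mcols(cgis)$susceptibility <- runif(nVar, 0.85, 1.0)
  })
  if (!length(cpgs)) stop("degenerate config: zero CpGs emitted")
  dom <- assignLargestOverlap(cpgs, hmdPmd)
  mcols(cpgs)$domain <- dom
  cgiIdx <- findOverlaps(cpgs, cgis, ignore.strand = TRUE, select = "first")
  mcols(cpgs)$cgi <- cgiIdx
  mcols(cpgs)$solo <- classifySoloWCGW(cpgs, mcols(cpgs)$flank5,
                                       mcols(cpgs)$flank3,
                                       window = config@soloWindow) &
                      is.na(cgiIdx)
  promoters <- definePromoters(genes)
  gamma <- c(rep(0, config@nControl),
             seq(config@gammaRange[1], config@gammaRange[2],
                 length.out = config@nTumor))
  groups <- c(rep("control", config@nControl),
              rep("tumor", config@nTumor))
  ids <- c(sprintf("control_%02d", seq_len(config@nControl)),
           sprintf("tumor_%02d", seq_len(config@nTumor)))
  list(config = config, chromLengths = chromLengths, cpgs = cpgs,
       cgis = cgis, hmdPmd = hmdPmd, genes = genes, promoters = promoters,
       states = states, soloSites = granges(cpgs[mcols(cpgs)$solo]),
       sampleIds = ids, groups = setNames(groups, ids),
       gamma = setNames(gamma, ids))
}

.simCGIs <- function(config, chromLengths) {
  out <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    n <- config@nCGIsPerChrom
    binW <- len %/% n
    if (binW <= config@cgiLength + 2L)
      stop("degenerate config: CGIs do not fit the chromosome")
    st <- (seq_len(n) - 1L) * binW +
      sample.int(binW - config@cgiLength - 1L, n, replace = TRUE)
    GRanges(chr, IRanges(st + 1L, width = config@cgiLength),
            seqlengths = chromLengths)
  })
  gr <- do.call(c, out)
  names(gr) <- sprintf("CGI_%04d", seq_along(gr))
  gr
}

.simDomains <- function(config, chromLengths) {
  out <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    starts <- seq.int(0L, len - 1L, by = config@segmentLength)
    lab <- ifelse(runif(length(starts)) < config@pmdFraction, "PMD", "HMD")
    GRanges(chr, IRanges(starts + 1L, pmin(starts + config@segmentLength,
                                           len)), label = lab,
            seqlengths = chromLengths)
  })
  gr <- do.call(c, out)
  ## merge adjacent same-label segments into maximal domains
  merged <- lapply(c("PMD", "HMD"), function(l) {
    m <- reduce(gr[mcols(gr)$label == l])
    mcols(m)$label <- rep(l, length(m))
    m
  })
  gr <- GenomicRanges::sort(do.call(c, merged))
  names(gr) <- sprintf("%s_%03d", mcols(gr)$label, seq_along(gr))
  gr
}

.simCpGs <- function(config, chromLengths, cgis) {
  bases <- c("A", "C", "G", "T")
  out <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    nOut <- rpois(1, config@cpgRate * len)
    posOut <- sort(unique(sample.int(len - 2L, nOut)))
    cg <- cgis[seqnames(cgis) == chr]
    posIn <- unlist(lapply(seq_along(cg), function(i)
      seq.int(start(cg)[i], end(cg)[i] - 1L, by = config@cgiCpGSpacing)))
    inCgi <- overlapsAny(GRanges(chr, IRanges(posOut, width = 1L)), cg)
    pos <- sort(unique(c(posOut[!inCgi], posIn)))
    GRanges(chr, IRanges(pos, width = 1L),
            flank5 = sample(bases, length(pos), replace = TRUE,
                            prob = c(0.35, 0.15, 0.15, 0.35)),
            flank3 = sample(bases, length(pos), replace = TRUE,
                            prob = c(0.35, 0.15, 0.15, 0.35)),
            seqlengths = chromLengths)
  })
  GenomicRanges::sort(do.call(c, out))
}

.simGenes <- function(config, chromLengths) {
  out <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    n <- config@nGenesPerChrom
    binW <- len %/% n
    if (binW <= config@geneLength + 2L)
      stop("degenerate config: genes do not fit the chromosome")
    st <- (seq_len(n) - 1L) * binW +
      sample.int(binW - config@geneLength - 1L, n, replace = TRUE)
    GRanges(chr, IRanges(st + 1L, width = config@geneLength),
            strand = sample(c("+", "-"), n, replace = TRUE),
            seqlengths = chromLengths)
  })
  gr <- do.call(c, out)
  names(gr) <- sprintf("GENE_%04d", seq_along(gr))
  gr
}

.simStates <- function(config, chromLengths) {
  stateNames <- names(chromStateGroups)
  one <- function() {
    out <- lapply(names(chromLengths), function(chr) {
      len <- chromLengths[[chr]]
      starts <- seq.int(0L, len - 1L, by = config@stateSegment)
      GRanges(chr, IRanges(starts + 1L,
                           pmin(starts + config@stateSegment, len)),
              label = sample(stateNames, length(starts), replace = TRUE),
              seqlengths = chromLengths)
    })
    do.call(c, out)
  }
  s1 <- one()
  s2 <- s1
  flip <- runif(length(s2)) < 0.3   # second cell state differs at 30% of segments
  mcols(s2)$label[flip] <- sample(stateNames, sum(flip), replace = TRUE)
  list(state1 = s1, state2 = s2)
}

#' Simulate one sample's methylome from planted truth
#'
#' Control samples: CpGs outside CGIs around \code{baselineHigh} (0.85) and
#' inside unmethylated CGIs around \code{baselineLow} (0.05). Tumor
#' samples additionally lose \code{deltaPMD} in PMD CpGs and
#' \code{deltaHMD} in HMD CpGs, and gain methylation in the planted CGI
#' clusters: sporadic CGIs gain 0.6 in a random 15\% of (CGI, sample)
#' pairs; gradient-heterogeneous CGIs gain gamma x susceptibility only in
#' samples with gamma > 0.45; gradient-homogeneous CGIs gain gamma x
#' susceptibility in every tumor; constitutive CGIs sit at
#' \code{baselineHigh} in everyone. Truncated-normal noise (sd
#' \code{noiseSD}, clipped to [0,1]); coverage is 1 + Poisson(mean - 1).
#'
#' @param truth output of \code{\link{simulateGenome}}.
#' @param group "control" or "tumor".
#' @param gamma CGI-gain gradient position in [0,1] (0 for controls).
#' @param sampleId sample identifier.
#' @param seed integer seed for this sample's noise.
#' @return a \linkS4class{SampleMethylome}.
#' @export
simulateSample <- function(truth, group, gamma, sampleId,
                           seed = truth$config@seed + 1000L) {
  if (!group %in% c("control", "tumor"))
    stop("unknown group label: ", group)
  stopifnot(gamma >= 0, gamma <= 1)
  cfg <- truth$config
  cpgs <- truth$cpgs
  mu <- .expectedLevels(truth, group, gamma, seed)
  withr::with_seed(seed + 1L, {
    lev <- pmin(pmax(mu + rnorm(length(mu), 0, cfg@noiseSD), 0), 1)
    cov <- 1L + rpois(length(mu), cfg@coverageMean - 1)
  })
  gr <- granges(cpgs)
  mcols(gr)$level <- lev
  mcols(gr)$coverage <- cov
  SampleMethylome(gr, sampleId, group)
}

## noise-free expected level per CpG for a sample
.expectedLevels <- function(truth, group, gamma, seed) {
  cfg <- truth$config
  cpgs <- truth$cpgs
  cgiOf <- mcols(cpgs)$cgi
  inCgi <- !is.na(cgiOf)
  cl <- mcols(truth$cgis)$cluster
  sus <- mcols(truth$cgis)$susceptibility
  mu <- rep(cfg@baselineHigh, length(cpgs))
  ## constitutively methylated CGIs sit a notch below the non-CGI baseline
  ## so they stay inside the variable-CGI band in every sample
  cgiBase <- ifelse(cl == "constitutive", cfg@baselineHigh - 0.10,
                    cfg@baselineLow)
  mu[inCgi] <- cgiBase[cgiOf[inCgi]]
  if (group == "tumor") {
    dom <- mcols(cpgs)$domain
    mu[!inCgi & dom == "PMD"] <- mu[!inCgi & dom == "PMD"] - cfg@deltaPMD
    mu[!inCgi & dom == "HMD"] <- mu[!inCgi & dom == "HMD"] - cfg@deltaHMD
    gain <- numeric(length(cl))
    gain[cl == "grad_hom"] <- gamma * sus[cl == "grad_hom"]
    if (gamma > 0.45)
      gain[cl == "grad_het"] <- gamma * sus[cl == "grad_het"]
    spor <- withr::with_seed(seed + 2L, {
      runif(length(cl)) < 0.15
    })
    gain[cl == "sporadic" & spor] <- 0.6
    mu[inCgi] <- pmin(mu[inCgi] + gain[cgiOf[inCgi]], 0.98)
  }
  mu
}

#' Simulate a full cohort
#'
#' \code{\link{simulateGenome}} plus one \code{\link{simulateSample}} per
#' planned sample (controls at gamma 0, tumors on the configured gamma
#' gradient), each with a seed derived from the config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{truth} and \code{samples} (named list of
#'   \linkS4class{SampleMethylome}).
#' @export
simulateCohort <- function(config) {
  truth <- simulateGenome(config)
  samples <- lapply(seq_along(truth$sampleIds), function(i) {
    id <- truth$sampleIds[i]
    simulateSample(truth, truth$groups[[id]], truth$gamma[[id]], id,
                   seed = config@seed + 1000L + i * 17L)
  })
  names(samples) <- truth$sampleIds
  list(truth = truth, samples = samples)
}

#' Simulate epiallele counts for a region
#'
#' For each non-overlapping consecutive 4-CpG locus in the region,
#' \code{depth} reads are drawn from a mixture: with probability
#' \code{1 - disorder} the locus's modal pattern (fully methylated outside
#' CGIs, fully unmethylated inside) and with probability \code{disorder} a
#' pattern uniform over the 16. Disorder 0 gives a single pattern; disorder
#' 1 gives the uniform distribution.
#'
#' @param truth output of \code{\link{simulateGenome}}.
#' @param region GRanges of length 1 containing >= 4 CpGs.
#' @param disorder mixture weight in [0,1].
#' @param depth reads per locus (>= 1).
#' @param seed RNG seed.
#' @return data.frame in the \code{\link{readEpialleles}} schema: chrom,
#'   pos1..pos4 (0-based), 16 pattern-count columns.
#' @export
simulateEpialleles <- function(truth, region, disorder, depth,
                               seed = truth$config@seed + 5000L) {
  stopifnot(disorder >= 0, disorder <= 1)
  if (depth < 1) stop("depth must be >= 1")
  cp <- truth$cpgs[overlapsAny(truth$cpgs, region, ignore.strand = TRUE)]
  if (length(cp) < 4) stop("region contains fewer than 4 CpGs")
  nLoci <- length(cp) %/% 4L
  pos <- start(cp)
  inCgi <- !is.na(mcols(cp)$cgi)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nLoci), function(i) {
      idx <- (i - 1L) * 4L + 1:4
      modal <- if (all(inCgi[idx])) "0000" else "1111"
      uni <- rbinom(1, depth, disorder)
      counts <- setNames(integer(16), epialleles4)
      if (uni > 0)
        counts <- counts + as.integer(rmultinom(1, uni, rep(1 / 16, 16)))
      counts[modal] <- counts[modal] + (depth - uni)
      c(list(chrom = as.character(seqnames(cp))[idx[1]],
             pos1 = pos[idx[1]] - 1L, pos2 = pos[idx[2]] - 1L,
             pos3 = pos[idx[3]] - 1L, pos4 = pos[idx[4]] - 1L),
        as.list(counts))
    })
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  colnames(out)[6:21] <- epialleles4
  out
}

#' Simulate an expression matrix with planted regulator coupling
#'
#' Regulator genes get log2 TPM = a + b x (per-sample methylation summary)
#' + noise with the stated slope b; background genes are independent
#' noise around a; silenced genes get TPM uniform below 0.5 so the screen's
#' expression floor removes them.
#'
#' @param summaries named numeric per-sample methylation summary (e.g.
#'   global or CGI means).
#' @param regulators named numeric vector of slopes b per regulator gene.
#' @param nBackground number of null genes (default 200).
#' @param nSilenced number of silenced genes (default 5).
#' @param a baseline log2 TPM (default 4).
#' @param noiseSD log2-scale noise sd (default 0.5).
#' @param seed RNG seed.
#' @return numeric gene x sample TPM matrix.
#' @export
simulateExpression <- function(summaries, regulators, nBackground = 200L,
                               nSilenced = 5L, a = 4, noiseSD = 0.5,
                               seed = 1L) {
  ns <- length(summaries)
  withr::with_seed(seed, {
    reg <- t(vapply(regulators, function(b)
      2^(a + b * summaries + rnorm(ns, 0, noiseSD)), numeric(ns)))
    bg <- matrix(2^(a + rnorm(nBackground * ns, 0, noiseSD)),
                 nBackground, ns)
    sil <- matrix(runif(nSilenced * ns, 0, 0.4), nSilenced, ns)
  })
  out <- rbind(reg, bg, sil)
  rownames(out) <- c(names(regulators),
                     sprintf("NULL_%04d", seq_len(nBackground)),
                     sprintf("SILENCED_%02d", seq_len(nSilenced)))
  colnames(out) <- names(summaries)
  out
}

#' Write a simulated cohort to disk
#'
#' Per-sample bedGraph-like methylation TSVs, BED files for all annotation
#' sets, and a JSON file of the planted truth (gamma, groups, CGI
#' clusters).
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort$truth
  paths <- c()
  for (s in cohort$samples) {
    p <- file.path(outdir, paste0(sampleId(s), ".meth.tsv"))
    writeMethylome(s, p); paths <- c(paths, p)
  }
  beds <- list(cgi = truth$cgis, hmd_pmd = truth$hmdPmd,
               genes = truth$genes, promoters = truth$promoters,
               solo_wcgw = truth$soloSites,
               state1 = truth$states$state1, state2 = truth$states$state2)
  for (nm in names(beds)) {
    gr <- beds[[nm]]
    if (is.null(mcols(gr)$label))
      mcols(gr)$label <- if (!is.null(names(gr))) names(gr) else "."
    p <- file.path(outdir, paste0(nm, ".bed"))
    writeIntervals(gr, p); paths <- c(paths, p)
  }
  tj <- list(gamma = as.list(truth$gamma), groups = as.list(truth$groups),
             cgi_clusters = setNames(as.list(mcols(truth$cgis)$cluster),
                                     names(truth$cgis)))
  p <- file.path(outdir, "truth.json")
  jsonlite::write_json(tj, p, auto_unbox = TRUE)
  invisible(c(paths, p))
}
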