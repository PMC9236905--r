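test_that("genome simulation is deterministic and rejects degenerate configs", {
  cfg <- simConfig(seed = 5, nChroms = 2, chromLength = 2e5,
                   nCGIsPerChrom = 10, nGenesPerChrom = 8,
                   geneLength = 5000)
  t1 <- simulateGenome(cfg)
  t2 <- simulateGenome(cfg)
  expect_identical(start(t1$cpgs), start(t2$cpgs))
  expect_identical(mcols(t1$cgis)$cluster, mcols(t2$cgis)$cluster)
  expect_identical(start(t1$hmdPmd), start(t2$hmdPmd))
  expect_error(simConfig(chromLength = 100), "degenerate")
  expect_error(simConfig(cpgRate = 0), "positive")
  expect_error(simConfig(gammaRange = c(0.9, 0.1)), "monotone")
})

test_that("CpG counts match the Poisson expectation and PMD/HMD partition the genome", {
  cfg <- simConfig(seed = 6, nChroms = 2, chromLength = 1e6,
                   cpgRate = 0.01, nCGIsPerChrom = 30)
  tr <- simulateGenome(cfg)
  ## outside-CGI CpGs follow Poisson(rate x length); CGI CpGs are regular
  nCgiCpGs <- sum(!is.na(mcols(tr$cpgs)$cgi))
  nOutside <- length(tr$cpgs) - nCgiCpGs
  lambda <- cfg@cpgRate * cfg@nChroms * as.numeric(cfg@chromLength)
  expect_lt(abs(nOutside - lambda), 5 * sqrt(lambda) + 700)
  ## roughly 100 CpGs per CGI at 10-bp spacing
  expect_equal(nCgiCpGs, 2 * 30 * 100, tolerance = 0.05)
  ## PMD + HMD cover each chromosome exactly once
  cov <- GenomicRanges::reduce(tr$hmdPmd)
  expect_equal(sum(width(cov)), 2 * 1e6)
  ## non-overlapping: total width equals covered width
  expect_equal(sum(width(tr$hmdPmd)), sum(width(cov)))
  ## pmdFraction 0: everything HMD
  tr0 <- simulateGenome(simConfig(seed = 6, pmdFraction = 0))
  expect_true(all(mcols(tr0$hmdPmd)$label == "HMD"))
  expect_true(all(mcols(tr0$cpgs)$domain == "HMD"))
  ## cluster labels partition the CGIs
  expect_true(all(mcols(tr$cgis)$cluster %in%
                    c("sporadic", "grad_het", "grad_hom", "constitutive",
                      "unmethylated")))
})

test_that("solo-WCGW sites have W flanks and isolated positions", {
  tr <- simulateGenome(simConfig(seed = 11, nChroms = 1,
                                 chromLength = 5e5, nGenesPerChrom = 10,
                                 geneLength = 5000))
  solo <- mcols(tr$cpgs)$solo
  expect_gt(sum(solo), 100)
  expect_true(all(mcols(tr$cpgs)$flank5[solo] %in% c("A", "T")))
  expect_true(all(mcols(tr$cpgs)$flank3[solo] %in% c("A", "T")))
  pos <- start(tr$cpgs)
  d <- pmin(c(Inf, diff(pos)), c(diff(pos), Inf))
  expect_true(all(d[solo] > tr$config@soloWindow))
  expect_false(any(solo & !is.na(mcols(tr$cpgs)$cgi)))
})

test_that("sample simulation plants the configured losses and keeps contracts", {
  cfg <- simConfig(seed = 20, nChroms = 2, chromLength = 4e5,
                   nCGIsPerChrom = 15, nGenesPerChrom = 8,
                   geneLength = 5000, deltaPMD = 0.3, deltaHMD = 0.05)
  tr <- simulateGenome(cfg)
  ctrl <- simulateSample(tr, "control", 0, "c1", seed = 1)
  tum <- simulateSample(tr, "tumor", 0.5, "t1", seed = 2)
  expect_error(simulateSample(tr, "relapse", 0, "x"), "unknown group")
  expect_true(all(methCoverage(ctrl) >= 1))
  expect_true(all(methLevel(ctrl) >= 0 & methLevel(ctrl) <= 1))
  ## planted PMD loss recovered as a mean difference
  pmdIdx <- mcols(tr$cpgs)$domain == "PMD" & is.na(mcols(tr$cpgs)$cgi)
  d <- mean(methLevel(tum)[pmdIdx]) - mean(methLevel(ctrl)[pmdIdx])
  expect_equal(d, -0.3, tolerance = 0.02)
  hmdIdx <- mcols(tr$cpgs)$domain == "HMD" & is.na(mcols(tr$cpgs)$cgi)
  d2 <- mean(methLevel(tum)[hmdIdx]) - mean(methLevel(ctrl)[hmdIdx])
  expect_equal(d2, -0.05, tolerance = 0.02)
  ## determinism
  tumB <- simulateSample(tr, "tumor", 0.5, "t1", seed = 2)
  expect_identical(methLevel(tum), methLevel(tumB))
})

test_that("a zero-effect tumor is indistinguishable from a control", {
  cfg <- simConfig(seed = 21, nChroms = 1, chromLength = 6e5,
                   nCGIsPerChrom = 10, nGenesPerChrom = 8,
                   geneLength = 5000, deltaPMD = 0, deltaHMD = 0,
                   clusterWeights = c(0, 0, 0, 0.2, 0.8))
  tr <- simulateGenome(cfg)
  ctrl <- simulateSample(tr, "control", 0, "c1", seed = 31)
  tum <- simulateSample(tr, "tumor", 0, "t1", seed = 32)
  set.seed(1)
  idx <- sample(length(tr$cpgs), 5000)
  ks <- suppressWarnings(ks.test(methLevel(ctrl)[idx],
                                 methLevel(tum)[idx]))
  expect_gt(ks$p.value, 0.01)
})

test_that("epiallele simulation honours disorder limits and input contracts", {
  tr <- simulateGenome(simConfig(seed = 30, nChroms = 1,
                                 chromLength = 2e5, nGenesPerChrom = 8,
                                 geneLength = 5000))
  region <- GRanges("chr1", IRanges(1, 50000))
  ep0 <- simulateEpialleles(tr, region, 0, depth = 20, seed = 1)
  counts <- as.matrix(ep0[, 6:21])
  expect_true(all(apply(counts, 1, max) == 20))
  expect_true(all(rowSums(counts) == 20))
  ## disorder 1 at high depth: near-uniform counts
  smallRegion <- GRanges("chr1", IRanges(start(tr$cpgs)[1],
                                         start(tr$cpgs)[4]))
  ep1 <- simulateEpialleles(tr, smallRegion, 1, depth = 16000, seed = 2)
  expect_equal(nrow(ep1), 1L)
  expect_true(all(abs(as.numeric(ep1[1, 6:21]) - 1000) <= 120))
  ## fewer than 4 CpGs in the region
  tiny <- GRanges("chr1", IRanges(start(tr$cpgs)[1],
                                  start(tr$cpgs)[3]))
  expect_error(simulateEpialleles(tr, tiny, 0.5, depth = 10), "fewer than 4")
  expect_error(simulateEpialleles(tr, region, 0.5, depth = 0), "depth")
})

test_that("expression simulation plants slopes, silenced genes and a clean null", {
  meth <- setNames(seq(0.2, 0.8, length.out = 20), sprintf("s%02d", 1:20))
  ex <- simulateExpression(meth, regulators = c(POS = 8), nBackground = 50,
                           nSilenced = 3, noiseSD = 1e-6, seed = 3)
  expect_equal(cor(log2(ex["POS", ] + 1), meth, method = "spearman"), 1)
  expect_true(all(ex[grepl("SILENCED", rownames(ex)), ] < 0.5))
  ## b = 0: rho distribution centred at zero
  exN <- simulateExpression(meth, regulators = c(N = 0), nBackground = 400,
                            seed = 4)
  rhos <- apply(log2(exN + 1), 1, cor, y = meth, method = "spearman")
  expect_lt(abs(median(rhos, na.rm = TRUE)), 0.15)
})

test_that("cohorts write to disk deterministically and round-trip", {
  cfg <- simConfig(seed = 40, nChroms = 1, chromLength = 1e5,
                   nCGIsPerChrom = 5, nControl = 2, nTumor = 2,
                   nGenesPerChrom = 5, geneLength = 3000)
  co <- simulateCohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeCohort(co, d1)
  writeCohort(simulateCohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  back <- suppressMessages(readMethylome(
    file.path(d1, "control_01.meth.tsv"), minCov = 1, maxCov = 1e4))
  expect_equal(length(back), length(co$samples[[1]]))
})
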