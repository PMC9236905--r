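test_that("makeWindows reproduces bedtools makewindows semantics", {
  w <- makeWindows(c(chr1 = 1500L), width = 1000L, step = 250L)
  expect_equal(start(w) - 1L, c(0L, 250L, 500L, 750L, 1000L, 1250L))
  expect_equal(end(w), c(1000L, 1250L, 1500L, 1500L, 1500L, 1500L))
  ## width == step tiles without overlap
  t <- makeWindows(c(chr1 = 3000L), width = 1000L, step = 1000L)
  expect_equal(sum(width(t)), 3000L)
  expect_true(all(width(GenomicRanges::reduce(t)) == 3000L))
  ## chromosome shorter than width: single truncated window set
  s <- makeWindows(c(chr1 = 400L), width = 1000L, step = 250L)
  expect_equal(start(s) - 1L, c(0L, 250L))
  expect_equal(end(s), c(400L, 400L))
  expect_error(makeWindows(c(chr1 = 1000L), width = 0), "width")
  ## random lengths vs the loop oracle
  set.seed(3)
  for (i in 1:100) {
    len <- sample(500:100000, 1)
    wd <- sample(c(500L, 1000L, 5000L), 1)
    st <- sample(c(250L, 1000L), 1)
    got <- makeWindows(setNames(len, "chrN"), wd, st)
    want <- bfMakeWindows(len, wd, st)
    expect_equal(start(got) - 1L, unname(want[, "start"]))
    expect_equal(end(got), unname(want[, "end"]))
  }
})

test_that("window deltas are zero/unchanged when tumor equals control and the 0.1 bound is strict", {
  pos <- seq(10, 4990, by = 20)
  avg <- GRanges("chr1", IRanges(pos, width = 1), mean = rep(0.8, length(pos)))
  win <- makeWindows(c(chr1 = 5000L))
  dom <- mkIv(0, 5000, label = "HMD")
  wd <- windowDeltas(avg, avg, win, GRanges(), dom)
  expect_true(all(wd$delta == 0))
  expect_true(all(wd$class == "unchanged"))
  ## delta exactly at -threshold stays unchanged (strict inequality);
  ## dyadic levels keep the window means exact in floating point
  avgHi <- avg; mcols(avgHi)$mean <- rep(0.5, length(pos))
  avgLo <- avg; mcols(avgLo)$mean <- rep(0.375, length(pos))
  wd2 <- windowDeltas(avgLo, avgHi, win, GRanges(), dom, threshold = 0.125)
  expect_true(all(wd2$delta == -0.125))
  expect_true(all(wd2$class == "unchanged"))
  mcols(avgLo)$mean <- rep(0.34375, length(pos))
  wd3 <- windowDeltas(avgLo, avgHi, win, GRanges(), dom, threshold = 0.125)
  expect_true(all(wd3$class == "hypo"))
  ## disjoint CpG universes are rejected
  avgB <- GRanges("chr1", IRanges(pos + 7L, width = 1),
                  mean = rep(0.8, length(pos)))
  expect_error(windowDeltas(avgB, avg, win, GRanges(), dom), "no CpGs")
})

test_that("windows recover planted PMD and HMD losses from a synthetic cohort", {
  co <- smallCohortCache()
  tr <- co$truth
  tumorAvg <- subtypeAverage(co$samples[tr$groups == "tumor"])
  controlAvg <- subtypeAverage(co$samples[tr$groups == "control"])
  win <- makeWindows(tr$chromLengths)
  wd <- windowDeltas(tumorAvg, controlAvg, win, tr$cgis, tr$hmdPmd)
  med <- tapply(wd$delta, wd$domain, median)
  expect_equal(unname(med["PMD"]), -tr$config@deltaPMD, tolerance = 0.02)
  expect_equal(unname(med["HMD"]), -tr$config@deltaHMD, tolerance = 0.02)
})

test_that("DMV calling merges canyons with window support and drops bare CGIs", {
  ## uniformly high methylome: no DMVs
  pos <- seq(5, 99995, by = 50)
  hi <- GRanges("chr1", IRanges(pos, width = 1),
                mean = rep(0.85, length(pos)))
  expect_length(callDMVs(hi, GRanges(), c(chr1 = 100000L)), 0)
  ## a dense 20-kb canyon at 0.05 gives one merged DMV
  lev <- rep(0.85, length(pos))
  lev[pos >= 40000 & pos < 60000] <- 0.05
  canyon <- GRanges("chr1", IRanges(pos, width = 1), mean = lev)
  dmv <- callDMVs(canyon, GRanges(), c(chr1 = 100000L))
  expect_length(dmv, 1)
  expect_lt(mcols(dmv)$mean, 0.15)
  ## matches the brute-force enumeration + union oracle
  want <- bfCallDMVs(pos - 1L, lev, numeric(0), numeric(0), 100000L)
  expect_equal(start(dmv) - 1L, want[, 1])
  expect_equal(end(dmv), want[, 2])
  ## an isolated unmethylated CGI in a high background yields nothing
  lev2 <- rep(0.85, length(pos))
  cgi <- mkIv(50000, 51000)
  lev2[pos > 50000 & pos <= 51000] <- 0.02
  iso <- GRanges("chr1", IRanges(pos, width = 1), mean = lev2)
  ## make the CGI CpGs dense enough to qualify on its own
  dense <- sort(c(pos, seq(50010, 50990, by = 30)))
  lev3 <- ifelse(dense > 50000 & dense <= 51000, 0.02, 0.85)
  iso2 <- GRanges("chr1", IRanges(dense, width = 1), mean = lev3)
  expect_length(callDMVs(iso2, cgi, c(chr1 = 100000L)), 0)
})

test_that("DMV calling equals the brute-force oracle on random low-methylation genomes", {
  set.seed(909)
  for (rep in 1:20) {
    len <- 60000L
    pos0 <- sort(sample.int(len - 1L, 1500))
    lev <- runif(length(pos0), 0, 0.4)   # plenty of qualifying windows
    cgiS <- sort(sample.int(len - 2000L, 2))
    cgiE <- cgiS + 1000L
    avg <- GRanges("chr1", IRanges(pos0 + 1L, width = 1), mean = lev)
    cgis <- mkIv(cgiS, cgiE)
    got <- callDMVs(avg, cgis, c(chr1 = len))
    want <- bfCallDMVs(pos0, lev, cgiS, cgiE, len)
    if (is.null(want)) {
      expect_length(got, 0)
    } else {
      expect_equal(start(got) - 1L, unname(want[, 1]))
      expect_equal(end(got), unname(want[, 2]))
    }
    expect_true(all(width(GenomicRanges::reduce(got)) == width(got)))
  }
})

test_that("solo-WCGW classification needs W flanks and no neighbour within the window", {
  cp <- GRanges("chr1", IRanges(c(100, 200, 210, 400), width = 1))
  f5 <- c("A", "A", "T", "C")
  f3 <- c("T", "T", "A", "G")
  solo <- classifySoloWCGW(cp, f5, f3)
  expect_equal(solo, c(TRUE, FALSE, FALSE, FALSE))
  ## neighbour at 36 bp is allowed, at 35 it is not
  cp2 <- GRanges("chr1", IRanges(c(100, 136), width = 1))
  expect_equal(classifySoloWCGW(cp2, c("A", "A"), c("T", "T")),
               c(TRUE, TRUE))
  cp3 <- GRanges("chr1", IRanges(c(100, 135), width = 1))
  expect_equal(classifySoloWCGW(cp3, c("A", "A"), c("T", "T")),
               c(FALSE, FALSE))
})

test_that("solo-WCGW domain means drop regions missing in any sample and recover planted loss", {
  co <- smallCohortCache()
  tr <- co$truth
  sm <- soloWCGWDomainMeans(co$samples, tr$soloSites, tr$hmdPmd)
  expect_true(all(!is.na(as.matrix(sm[, -(1:5)]))))
  ## trivial example: two solo CpGs at 0.9/0.7 average to 0.8
  solo <- GRanges("chr1", IRanges(c(100, 200), width = 1))
  dom <- mkIv(0, 1000, label = "HMD")
  m <- mkMeth(c(100, 200), c(0.9, 0.7))
  one <- soloWCGWDomainMeans(list(m), solo, dom)
  expect_equal(one$s1, 0.8)
  ## region uncovered in one of three samples is dropped
  m2 <- mkMeth(c(100, 200), c(0.5, 0.5), id = "s2")
  m3 <- mkMeth(5000, 0.5, id = "s3")     # no solo CpG in the region
  none <- soloWCGWDomainMeans(list(m, m2, m3), solo, dom)
  expect_equal(nrow(none), 0L)
  ## planted PMD loss visible in solo means, HMD nearly unshifted
  ctrl <- rowMeans(as.matrix(sm[, 5L + which(tr$groups == "control")]))
  tum <- rowMeans(as.matrix(sm[, 5L + which(tr$groups == "tumor")]))
  d <- tapply(tum - ctrl, sm$domain, median)
  expect_equal(unname(d["PMD"]), -tr$config@deltaPMD, tolerance = 0.02)
  expect_equal(unname(d["HMD"]), -tr$config@deltaHMD, tolerance = 0.02)
})
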