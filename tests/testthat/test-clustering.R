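test_that("variable-CGI selection drops constitutively un/methylated islands and is idempotent", {
  mat <- rbind(allLow = c(0.05, 0.10, 0.15),
               varied = c(0.10, 0.50, 0.90),
               allHigh = c(0.85, 0.90, 0.95),
               mid = c(0.30, 0.40, 0.50))
  colnames(mat) <- paste0("s", 1:3)
  v <- selectVariableCGIs(mat)
  expect_setequal(rownames(v), c("varied", "mid"))
  expect_identical(selectVariableCGIs(v), v)
  expect_error(selectVariableCGIs(mat[1, , drop = FALSE]), "no variable")
})

test_that("status binarisation is strict at the 0.2 cutoff", {
  m <- matrix(c(0.25, 0.2, 0, 1), 2)
  b <- binarizeStatus(m)
  expect_equal(as.vector(b), c(1L, 0L, 0L, 1L))
})

test_that("PCA reconstructs centered data and projects held-out samples consistently", {
  set.seed(5)
  x <- matrix(rnorm(20 * 8), 20, 8)
  p <- pcaWithProjection(x)
  recon <- p$scores %*% t(p$loadings)
  centered <- scale(x, center = p$center, scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-8)
  expect_lte(sum(p$explained), 1 + 1e-12)
  ## duplicate rows land on identical scores
  x2 <- rbind(x, x[1, ])
  p2 <- pcaWithProjection(x2)
  expect_equal(p2$scores[1, ], p2$scores[21, ], tolerance = 1e-10)
  ## projecting the training data reproduces the training scores
  p3 <- pcaWithProjection(x, project = x)
  expect_equal(unname(p3$projected), unname(p3$scores), tolerance = 1e-10)
})

test_that("consensus clustering recovers a planted two-group structure with a clean block matrix", {
  set.seed(99)
  n <- 40
  truthLab <- rep(1:2, each = n / 2)
  mat <- matrix(rnorm(n * 10, mean = rep(c(0.2, 0.7), each = n / 2),
                      sd = 0.03), n, 10)
  rownames(mat) <- sprintf("i%02d", 1:n)
  cr <- consensusCluster(mat, maxK = 4, reps = 40, seed = 17)
  cm <- consensusMatrix(cr, 2)
  within <- cm[truthLab == 1, truthLab == 1]
  between <- cm[truthLab == 1, truthLab == 2]
  expect_gt(min(within), 0.95)
  expect_lt(max(between), 0.05)
  asg <- clusterAssignments(cr, 2)
  expect_equal(adjustedRandIndex(asg, truthLab), 1)
  ## relabelling: cluster 1 has the lower mean methylation
  expect_lt(mean(mat[asg == 1, ]), mean(mat[asg == 2, ]))
  ## determinism under the same seed
  cr2 <- consensusCluster(mat, maxK = 4, reps = 40, seed = 17)
  expect_identical(consensusMatrix(cr2, 2), cm)
  ## consensus matrices are valid: symmetric, unit diagonal, in [0,1]
  for (k in 2:4) {
    m <- consensusMatrix(cr, k)
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 1))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("stronger planted separation never reduces within-cluster consensus", {
  set.seed(123)
  n <- 30
  lab <- rep(1:2, each = n / 2)
  withinMean <- vapply(c(0.05, 0.2, 0.4), function(sep) {
    mat <- matrix(rnorm(n * 8, mean = rep(c(0.4, 0.4 + sep), each = n / 2),
                        sd = 0.05), n, 8)
    cr <- consensusCluster(mat, maxK = 3, reps = 30, seed = 5)
    cm <- consensusMatrix(cr, 2)
    mean(c(cm[lab == 1, lab == 1], cm[lab == 2, lab == 2]))
  }, 0)
  expect_true(all(diff(withinMean) >= -0.02))
})

test_that("sample grouping names LM/IM/HM tiers by ascending methylation, order-invariantly", {
  set.seed(42)
  gains <- rep(c(0.1, 0.5, 0.9), each = 4)
  mat <- matrix(0.05 + gains + rnorm(12 * 30, 0, 0.02), 12, 30)
  mat <- pmin(pmax(mat, 0), 1)
  rownames(mat) <- sprintf("s%02d", 1:12)
  g <- groupSamples(mat)
  truth <- rep(c("LM", "IM", "HM"), each = 4)
  expect_equal(adjustedRandIndex(g, truth), 1)
  expect_equal(unname(g[1:4]), rep("LM", 4))
  expect_equal(unname(g[9:12]), rep("HM", 4))
  ## permuting the input rows permutes, but does not change, the labels
  perm <- sample(12)
  g2 <- groupSamples(mat[perm, ])
  expect_equal(g2[rownames(mat)], g[rownames(mat)])
  ## identical samples give a degenerate dendrogram
  same <- matrix(0.5, 5, 10, dimnames = list(paste0("x", 1:5), NULL))
  expect_error(groupSamples(same), "identical")
})

test_that("cluster characterisation fractions match per-CGI classification and state tests degenerate correctly", {
  cgis <- mkIv(c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500),
               seqlen = 10000)
  clusters <- c(1L, 1L, 2L, 2L)
  promoters <- mkIv(c(0, 1000), c(500, 1500))   # cluster 1 fully promoter
  bodies <- mkIv(2000, 2500)
  states <- mkIv(c(0, 2000), c(2000, 4000), label = c("1_TssA", "15_Quies"))
  res <- characterizeClusters(cgis, clusters,
                              list(promoter = promoters,
                                   gene_body = bodies),
                              states = list(states, states))
  fr <- res$fractions
  expect_equal(fr$promoter[fr$cluster == 1], 1.0)
  expect_equal(fr$promoter[fr$cluster == 2], 0.0)
  expect_equal(fr$intergenic[fr$cluster == 2], 0.5)
  ## identical state tracks: statistic 0, p 1, V 0
  expect_true(all(res$stateTests$p == 1))
  expect_true(all(res$stateTests$cramers_v == 0))
})

test_that("covariate tests detect aligned factors and respect skip rules", {
  groups <- setNames(rep(c("LM", "IM", "HM"), each = 5),
                     sprintf("s%02d", 1:15))
  aligned <- data.frame(
    sub = rep(c("a", "b", "c"), each = 5),
    flat = rep(c("x", "y"), length.out = 15),
    single = rep("only", 15),
    age = seq(30, 58, by = 2),
    row.names = names(groups))
  res <- covariateTests(groups, aligned,
                        continuousSplit = c("LM", "HM"))
  expect_lt(res$p[res$covariate == "sub"], 0.01)
  expect_gt(res$p[res$covariate == "flat"], 0.05)
  expect_true(is.na(res$p[res$covariate == "single"]))
  expect_match(res$note[res$covariate == "single"], "skipped")
  expect_equal(res$test[res$covariate == "age"], "wilcoxon")
  ## perfectly aligned 2x2-style design matches fisher.test directly
  g2 <- setNames(rep(c("LM", "HM"), each = 5), sprintf("t%02d", 1:10))
  cv2 <- data.frame(mut = rep(c("wt", "mut"), each = 5),
                    row.names = names(g2))
  res2 <- covariateTests(g2, cv2)
  expect_equal(res2$p, fisher.test(table(cv2$mut, g2))$p.value)
  expect_lt(res2$p, 0.01)
})

test_that("wilcoxon and fisher nulls are calibrated", {
  set.seed(31)
  pw <- replicate(200, {
    a <- rnorm(10); b <- rnorm(10)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  })
  expect_gte(mean(pw > 0.05), 0.90)
  ## group-independent covariate: p-values roughly uniform
  pf <- replicate(200, {
    g <- setNames(sample(rep(c("A", "B"), each = 8)), sprintf("s%d", 1:16))
    cv <- data.frame(c1 = sample(rep(c("x", "y"), each = 8)),
                     row.names = names(g))
    covariateTests(g, cv)$p
  })
  ## fisher p is discrete and conservative: type-I error at or below nominal
  expect_lte(mean(pf <= 0.05), 0.075)
  expect_gte(mean(pf > 0.05), 0.85)
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjustedRandIndex(1:5, c(2L, 3L, 4L, 5L, 1L)), 1)
})
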