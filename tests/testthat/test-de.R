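test_that("size factors follow the median-of-ratios definition", {
  k <- cbind(s1 = c(10, 100, 1), s2 = c(20, 200, 2))
  expect_equal(unname(estimateSizeFactors(k)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  k2 <- matrix(rep(c(5L, 9L, 30L), 4), 3, 4)
  expect_equal(unname(estimateSizeFactors(k2)), rep(1, 4))
  set.seed(101)
  for (i in 1:20) {
    k3 <- matrix(rpois(20, 50) + 1L, 5, 4)
    expect_equal(unname(estimateSizeFactors(k3)), bruteSizeFactors(k3),
                 tolerance = 1e-12)
  }
  expect_error(estimateSizeFactors(matrix(c(0L, 1L, 1L, 0L), 2, 2)),
               "positive counts")
})

test_that("size factors agree with the established reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(202)
  k <- matrix(rnbinom(600, mu = 100, size = 10), 100, 6)
  expect_equal(unname(estimateSizeFactors(k)),
               unname(DESeq2::estimateSizeFactorsForMatrix(k)),
               tolerance = 1e-3)
})

test_that("moment dispersion floors constants and recovers simulations", {
  grp <- rep(c("A", "B"), each = 4)
  k <- matrix(rep(c(10L, 20L), each = 12), 3, 8)  # constant within group
  d <- estimateDispersions(k, sizeFactors = rep(1, 8), group = grp)
  expect_true(all(d == 1e-8))
  set.seed(7)
  kp <- matrix(rpois(300 * 100, 200), 300, 100)
  dp <- estimateDispersions(kp, sizeFactors = rep(1, 100),
                            group = rep(c("A", "B"), each = 50))
  expect_lte(median(dp), 0.01)
  kn <- matrix(rnbinom(300 * 400, mu = 150, size = 2), 300, 400)
  dn <- estimateDispersions(kn, sizeFactors = rep(1, 400),
                            group = rep(c("A", "B"), each = 200))
  expect_gt(median(dn), 0.4)
  expect_lt(median(dn), 0.6)
  expect_error(estimateDispersions(kp[, 1:3], group = c("A", "A", "B")),
               ">= 2 samples")
})

test_that("Wald test is null at identical group means and recovers effects", {
  k <- matrix(rep(c(30L, 80L, 200L), 6), 3, 6)
  res <- waldTest(k, c("B", "A"), sizeFactors = rep(1, 6),
                  group = rep(c("A", "B"), 3))
  expect_equal(res$log2FoldChange, rep(0, 3))
  expect_equal(res$stat, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))
  # all-zero genes are flagged, not significant
  kz <- rbind(k, gene0 = 0L)
  resz <- waldTest(kz, c("B", "A"), sizeFactors = rep(1, 6),
                   group = rep(c("A", "B"), 3))
  expect_true(resz$allZero[4])
  expect_equal(resz$pvalue[4], 1)
  # planted DMT-vs-SHAM effect of 1.5 log2 units is recovered on average
  cfg <- syntheticStudyConfig(seed = 31)
  study <- simulateCountStudy(cfg, "ZDF")
  de <- waldTest(study, c("DMT", "SHAM"))
  fao <- de$gene %in% cfg$faoGenes
  expect_equal(mean(de$log2FoldChange[fao]), 1.5, tolerance = 0.1)
  expect_error(waldTest(k, c("B", "C"), group = rep(c("A", "B"), 3)),
               "absent")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjustBH(0.03), 0.03)
  expect_equal(adjustBH(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(adjustBH(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  for (i in seq_len(1000)) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- adjustBH(p)
    expect_equal(adj, bruteBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))       # padj >= p component-wise
    expect_identical(order(adj[order(p)]),
                     seq_along(p))           # order-preserving
  }
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
  expect_error(adjustBH(c(-0.1)), "0, 1")
})

test_that("DEG calling applies an inclusive FC gate and strict alpha", {
  de <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    log2FoldChange = c(0.5, log2(1.2), log2(1.3), -log2(1.5), log2(2)),
    padj = c(0.01, 0.001, 0.049, 0.02, 0.05),
    allZero = FALSE)
  degs <- callDEGs(de)
  expect_setequal(degGenes(degs), c("a", "c", "d"))
  dirs <- degDirections(degs)
  expect_identical(unname(dirs[c("a", "c", "d")]), c("up", "up", "down"))
})

test_that("concordance is symmetric, idempotent and direction-aware", {
  a <- DEGSet(c("g1", "g2", "g3"), c("up", "down", "up"), "c1")
  b <- DEGSet(c("g2", "g3", "g4"), c("down", "down", "up"), "c2")
  ab <- concordantDEGs(a, b)
  expect_setequal(degGenes(ab), "g2")          # g3 flips direction
  ba <- concordantDEGs(b, a)
  expect_setequal(degGenes(ab), degGenes(ba))
  aa <- concordantDEGs(a, a)
  expect_setequal(degGenes(aa), degGenes(a))
  expect_identical(degDirections(aa)[degGenes(a)],
                   degDirections(a)[degGenes(a)])
})

test_that("corrected fractions reproduce the printed study percentages", {
  dis <- makeDEGs(379, "up", contrast = "SHAM vs healthy")
  trt <- DEGSet(c(paste0("g", 1:206), paste0("x", 1:50)),
                rep("down", 256), "DMT vs SHAM")
  cf <- correctedFraction(dis, trt)
  expect_identical(cf$count, 206L)
  expect_identical(cf$percentage, 54.4)
  dis2 <- makeDEGs(3089, "up")
  trt2 <- DEGSet(paste0("g", 1:804), rep("down", 804))
  expect_identical(correctedFraction(dis2, trt2)$percentage, 26.0)
  # same-direction overlap is not "corrected" under the default mode
  trtSame <- DEGSet(paste0("g", 1:206), rep("up", 206))
  expect_identical(correctedFraction(dis, trtSame)$count, 0L)
  expect_identical(correctedFraction(dis, trtSame, mode = "any")$count,
                   206L)
  expect_identical(correctedFraction(dis, makeDEGs(5, prefix = "z"))$percentage,
                   0)
  expect_error(correctedFraction(DEGSet(character(), character()), trt),
               "empty")
})

test_that("the rlog-style transform is anchored and monotone", {
  k <- matrix(c(0L, 2L, 10L, 50L), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  tr <- rlogLikeTransform(k, sizeFactors = c(s1 = 2))
  expect_equal(tr["g1", 1], 0)
  expect_equal(tr["g2", 1], 1)     # count equal to the size factor maps to 1
  expect_true(all(diff(tr[, 1]) > 0))
})

test_that("PCA respects mirror symmetry, ordering and reconstruction", {
  x <- rbind(c(1, 3, 5), c(3, 1, 1))   # two samples mirrored about the mean
  p <- pcaScores(x)
  expect_equal(p$scores[1, 1], -p$scores[2, 1])
  set.seed(5)
  y <- matrix(rnorm(80), 8, 10)
  py <- pcaScores(y)
  expect_true(all(diff(py$varianceExplained) <= 1e-12))
  recon <- py$scores %*% t(py$loadings)
  expect_equal(recon, scale(y, center = TRUE, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_warning(pc <- pcaScores(matrix(1, 4, 3)), "constant")
  expect_true(pc$constant)
})
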