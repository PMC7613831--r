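test_that("baseline correction recovers offsets, ramps and is idempotent", {
  n <- 4000
  expect_equal(baselineCorrect(rep(0, n)), rep(0, n))
  # sparse peaks on a constant offset: offset recovered away from peaks
  x <- seq_len(n)
  peaks <- 8 * exp(-(x - 1000)^2 / 50) + 6 * exp(-(x - 3000)^2 / 50)
  v <- peaks + 5
  corr <- baselineCorrect(v)
  away <- abs(x - 1000) > 100 & abs(x - 3000) > 100
  expect_lt(max(abs(corr[away])), 0.05)      # within 1% of the offset
  # linear ramp, no peaks: residual below 2% of the ramp range
  ramp <- seq(0, 100, length.out = n)
  expect_lt(max(abs(baselineCorrect(ramp))), 2)
  # idempotence on noiseless input
  expect_lt(max(abs(baselineCorrect(corr) - corr)), 0.05)
  expect_error(baselineCorrect(v, window = 0), "positive")
  expect_error(baselineCorrect(v, window = 100, step = 200), "exceed")
  expect_error(baselineCorrect(rep(1, 50), window = 100, step = 50),
               "length")
})

test_that("wavelet detection finds isolated peaks and rejects noise", {
  ppm <- seq(10, 0, length.out = 6000)
  step <- abs(ppm[2] - ppm[1])
  sig <- 10 * exp(-(ppm - 3)^2 / (2 * 0.01^2))
  pk <- detectPeaksCWT(sig, ppm = ppm)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$ppm - 3), step + 1e-12)
  expect_equal(pk$intensity, 10, tolerance = 0.01)
  # two Gaussians >= 6 sigma apart resolve into exactly two peaks
  sig2 <- sig + 7 * exp(-(ppm - 3.12)^2 / (2 * 0.01^2))
  pk2 <- detectPeaksCWT(sig2, ppm = ppm)
  expect_identical(nrow(pk2), 2L)
  expect_equal(sort(pk2$ppm), c(3, 3.12), tolerance = 0.005)
  # white noise alone yields well under one detection per spectrum
  set.seed(61)
  hits <- vapply(seq_len(100), function(i)
    nrow(detectPeaksCWT(rnorm(4000), ppm = seq_len(4000), minSNR = 5)),
    integer(1))
  expect_lt(mean(hits), 0.5)
  expect_error(detectPeaksCWT(sig, ppm = ppm, scales = 2), "2 scales")
  expect_error(detectPeaksCWT(sig[1:100], ppm = ppm[1:100],
                              scales = c(16, 32)), "too large")
})

test_that("peak grouping clusters by tolerance and deduplicates samples", {
  pk <- data.frame(sample = c("s1", "s2", "s3", "s1"),
                   ppm = c(2.999, 3.000, 3.001, 5.0),
                   intensity = c(5, 6, 7, 3))
  gt <- groupPeaks(pk, tolerance = 0.01)
  expect_identical(nrow(gt$groups), 2L)
  expect_equal(gt$groups$ppm, c(3.0, 5.0))
  expect_identical(gt$groups$n, c(3L, 1L))
  # a sample contributing two peaks keeps only its most intense
  pk2 <- data.frame(sample = c("s1", "s1", "s2"),
                    ppm = c(3.000, 3.002, 3.001),
                    intensity = c(2, 9, 5))
  gt2 <- groupPeaks(pk2, tolerance = 0.01)
  expect_identical(nrow(gt2$members), 2L)
  expect_equal(gt2$members$intensity[gt2$members$sample == "s1"], 9)
  expect_identical(nrow(gt2$unassigned), 1L)
  expect_equal(gt2$unassigned$intensity, 2)
  expect_error(groupPeaks(pk, tolerance = 0), "positive")
})

test_that("silhouette widths match the definition and the cluster oracle", {
  pos <- c(1.0, 1.1, 5.0, 5.1)
  lab <- c(1, 1, 2, 2)
  s <- silhouetteWidths(pos, lab)
  expect_equal(s[1], 3.95 / 4.05, tolerance = 1e-12)
  expect_true(all(s > 0.97))
  # singleton clusters score 1; a single cluster scores 1 throughout
  expect_equal(silhouetteWidths(c(1, 2, 9), c(1, 1, 2))[3], 1)
  expect_equal(silhouetteWidths(c(1, 2, 3), c(1, 1, 1)), rep(1, 3))
  skip_if_not_installed("cluster")
  set.seed(67)
  for (i in 1:20) {
    p <- c(rnorm(6, 1, 0.2), rnorm(5, 5, 0.2), rnorm(4, 9, 0.2))
    l <- rep(1:3, c(6, 5, 4))
    mine <- silhouetteWidths(p, l)
    ref <- cluster::silhouette(l, dist(p))[, "sil_width"]
    expect_equal(mine, unname(ref), tolerance = 1e-12)
  }
})

test_that("silhouette gating dissolves merged groups and converges", {
  # one merged group spanning two true clusters fails the gate and is
  # re-split into two clean groups
  pk <- data.frame(sample = paste0("s", 1:4),
                   ppm = c(1.0, 5.0, 1.1, 5.1),
                   intensity = c(4, 4, 5, 5))
  merged <- groupPeaks(pk, tolerance = 10)     # everything in one group
  expect_identical(nrow(merged$groups), 1L)
  filt <- silhouetteFilter(merged, tolerance = 0.5)
  expect_identical(nrow(filt$groups), 2L)
  expect_true(all(filt$groups$silhouette >= 0.6))
  expect_equal(filt$groups$ppm, c(1.05, 5.05))
  # a tight lone group is retained with silhouette 1
  one <- groupPeaks(pk[c(1, 3), ], tolerance = 0.5)
  f1 <- silhouetteFilter(one, tolerance = 0.5)
  expect_identical(nrow(f1$groups), 1L)
  expect_equal(f1$groups$silhouette, 1)
})

test_that("peak filling completes the matrix from the spectra", {
  ppm <- seq(10, 0, length.out = 6000)
  apex <- 6
  sig <- apex * exp(-(ppm - 4)^2 / (2 * 0.01^2))
  sp <- NMRSpectra(ppm, cbind(s1 = sig, s2 = rep(0, 6000)),
                   group = c("a", "b"))
  mat <- matrix(c(NA, NA), 2, 1, dimnames = list(c("s1", "s2"), "4.0000"))
  filled <- fillPeaks(mat, sp, halfWidth = 0.01)
  expect_equal(filled["s1", 1], apex, tolerance = 0.05 * apex)
  expect_identical(filled["s2", 1], 0)          # zero spectrum fills 0
  # complete matrices pass through unchanged
  m2 <- matrix(c(1.5, 2.5), 2, 1, dimnames = dimnames(mat))
  expect_equal(unname(fillPeaks(m2, sp)[, 1]), c(1.5, 2.5))
  expect_error(fillPeaks(mat, sp, halfWidth = 0), "positive")
})

test_that("probabilistic quotient normalization rescales to the reference", {
  ref <- c(4, 8, 2, 6, 10)
  mat <- rbind(a = ref, b = 3 * ref, c = 0.5 * ref)
  colnames(mat) <- sprintf("%.4f", 1:5)
  pq <- pqnNormalize(mat)
  expect_equal(unname(pq$factors), c(1, 3, 0.5))
  expect_equal(unname(pq$normalized["b", ]), ref)
  same <- rbind(a = ref, b = ref)
  expect_equal(unname(pqnNormalize(same)$factors), c(1, 1))
  expect_error(pqnNormalize(rbind(a = ref, b = rep(0, 5))), "all-zero")
  expect_error(pqnNormalize(rbind(a = c(NA, ref[-1]), b = ref)), "complete")
})

test_that("PQN is scale-equivariant", {
  set.seed(71)
  mat <- matrix(rexp(60, 0.2), 6, 10,
                dimnames = list(paste0("s", 1:6), sprintf("%.4f", 1:10)))
  ref <- apply(mat, 2, median)
  base <- pqnNormalize(mat, reference = ref)
  for (c0 in c(0.25, 4)) {
    m2 <- mat
    m2[3, ] <- c0 * m2[3, ]
    sc <- pqnNormalize(m2, reference = ref)
    expect_equal(unname(sc$factors[3]), unname(c0 * base$factors[3]),
                 tolerance = 1e-12)
    expect_equal(sc$normalized[3, ], base$normalized[3, ],
                 tolerance = 1e-12)
    expect_equal(sc$normalized[-3, ], base$normalized[-3, ],
                 tolerance = 1e-12)
  }
})

test_that("the composed spectral chain yields a complete gated matrix", {
  cfg <- smallStudyConfig(seed = 73)
  sp <- simulateNMRCohort(cfg)
  out <- processSpectra(sp)
  expect_false(any(is.na(out$matrix)))
  expect_true(all(out$groupTable$groups$silhouette >= 0.6))
  expect_identical(rownames(out$normalized),
                   colnames(spectraIntensity(sp)))
  # most planted peaks are recovered even on this reduced cohort
  planted <- plantedTruth(sp)$peaks$ppm
  rec <- vapply(planted, function(p)
    any(abs(out$groupTable$groups$ppm - p) <= 0.01), logical(1))
  expect_gt(mean(rec), 0.9)
})
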