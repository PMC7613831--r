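test_that("all generators are deterministic under a fixed seed", {
  cfg <- smallStudyConfig(seed = 11)
  expect_identical(assay(simulateCountStudy(cfg, "ZDF"), "counts"),
                   assay(simulateCountStudy(cfg, "ZDF"), "counts"))
  expect_identical(simulateAtlas(cfg), simulateAtlas(cfg))
  expect_identical(simulateDrugNetworks(cfg)$edges,
                   simulateDrugNetworks(cfg)$edges)
  expect_identical(spectraIntensity(simulateNMRCohort(cfg)),
                   spectraIntensity(simulateNMRCohort(cfg)))
  expect_identical(simulateMorphometry(cfg)$measurements,
                   simulateMorphometry(cfg)$measurements)
  # different models give different cohorts
  expect_false(identical(assay(simulateCountStudy(cfg, "ZDF"), "counts"),
                         assay(simulateCountStudy(cfg, "ZDSD"), "counts")))
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticStudyConfig(nGenes = -5), "positive")
  expect_error(syntheticStudyConfig(dispersion = 0), "positive")
  expect_error(syntheticStudyConfig(
    nGenes = 100, faoGenes = c("gene00001", "gene00002"),
    fibrosisGenes = c("gene00002", "gene00003")), "disjoint")
  expect_error(syntheticStudyConfig(faoLog2FC = Inf), "finite")
  expect_error(syntheticStudyConfig(nmr = list(dilutionRange = c(-1, 2))),
               "positive")
  expect_error(simulateNMRCohort(syntheticStudyConfig(
    nmr = list(peaks = data.frame(ppm = 12, family = "stable")))),
    "outside")
  expect_error(simulateMorphometry(syntheticStudyConfig(
    morphometry = list(params = utils::modifyList(
      renomix:::.defaultMorphoParams(),
      list(gbm_nm = list(mean = c(healthy = 180, SHAM = 260, DMT = 210),
                         sd = c(healthy = -1, SHAM = 2, DMT = 2))))))),
    "negative scale")
})

test_that("generated counts match the negative-binomial moments", {
  # constant mean, unit library sizes, no effects: 600 genes x 18 samples
  # pools 10,800 NB draws at mu = 100, alpha = 0.05
  cfg <- syntheticStudyConfig(
    seed = 5, nGenes = 600, nFaoGenes = 2, nFibrosisGenes = 2,
    faoLog2FC = 0, faoDiseaseLog2FC = 0, fibrosisLog2FC = 0,
    baseMeanRange = c(100, 100), librarySizeRange = c(1, 1))
  k <- assay(simulateCountStudy(cfg, "ZDF"), "counts")
  expect_equal(mean(k), 100, tolerance = 0.02)
  expect_equal(var(as.vector(k)), 100 + 0.05 * 100^2, tolerance = 0.1)
})

test_that("planted truth is exhaustive and consistent", {
  cfg <- smallStudyConfig(seed = 13)
  study <- simulateCountStudy(cfg, "ZDSD")
  tr <- plantedTruth(study)
  expect_setequal(tr$genes$gene, rownames(study))
  expect_false(anyDuplicated(tr$genes$gene) > 0)
  expect_setequal(names(tr$librarySizes), colnames(study))
  fao <- tr$genes[tr$genes$module == "fao", ]
  expect_true(all(fao$log2FC_DMTvsSHAM == cfg$faoLog2FC))
  sp <- simulateNMRCohort(cfg)
  expect_setequal(names(plantedTruth(sp)$dilution),
                  colnames(spectraIntensity(sp)))
})

test_that("atlas plants argmax cell types exactly as recorded", {
  cfg <- smallStudyConfig(seed = 17)
  atl <- simulateAtlas(cfg)
  expect_true(all(atl$atlas >= 0))
  expect_true(all(rowSums(atl$atlas) > 0))
  expect_identical(colnames(atl$atlas), tubuleCellTypes())
  argmax <- colnames(atl$atlas)[apply(atl$atlas, 1, which.max)]
  expect_identical(argmax, atl$truth$cellType)
  pt <- atl$truth$compartment == "proximal_tubule"
  expect_true(all(atl$truth$cellType[pt] %in% proximalTubuleCellTypes()))
  expect_true(all(!atl$truth$cellType[!pt] %in% proximalTubuleCellTypes()))
  # planted PT genes are dominated by the FAO module at the configured rate
  faoRows <- atl$truth$feature %in% cfg$faoGenes
  expect_gt(mean(pt[faoRows]), 0.55)
})

test_that("drug networks honour sizes, disjointness and exact overlaps", {
  zeroSpec <- list(
    sizes = c(fenofibrate = 50, liraglutide = 40, metformin = 30,
              ramipril = 20, rosuvastatin = 25,
              PPARA = 45, PPARD = 30, PPARG = 35),
    moduleHitFraction = c(fenofibrate = 0, liraglutide = 0, metformin = 0,
                          ramipril = 0, rosuvastatin = 0,
                          PPARA = 0, PPARD = 0, PPARG = 0),
    sharedCoreFraction = 0, fenoPparaOverlap = 12)
  cfg <- syntheticStudyConfig(seed = 19, drugSpecs = zeroSpec)
  net <- simulateDrugNetworks(cfg)
  expect_identical(lengths(net$targetSets)[names(zeroSpec$sizes)],
                   setNames(as.integer(zeroSpec$sizes),
                            names(zeroSpec$sizes)))
  drugs <- c("fenofibrate", "liraglutide", "metformin", "ramipril",
             "rosuvastatin")
  for (pair in utils::combn(drugs, 2, simplify = FALSE))
    expect_length(intersect(net$targetSets[[pair[1]]],
                            net$targetSets[[pair[2]]]), 0)
  expect_length(intersect(net$targetSets$fenofibrate,
                          net$targetSets$PPARA), 12)
  zeroSpec$fenoPparaOverlap <- 60  # exceeds both set sizes
  expect_error(simulateDrugNetworks(
    syntheticStudyConfig(seed = 19, drugSpecs = zeroSpec)),
    "exceeds")
})

test_that("noise-free spectra place apexes and scale with dilution", {
  sp <- simulateNMRCohort(onePeakConfig(ppm = 3.0))
  ints <- spectraIntensity(sp)
  axis <- ppmAxis(sp)
  step <- abs(axis[2] - axis[1])
  for (j in seq_len(ncol(ints)))
    expect_lt(abs(axis[which.max(ints[, j])] - 3.0), step + 1e-12)
  # integrated intensity scales exactly with the planted dilution
  sp2 <- simulateNMRCohort(onePeakConfig(seed = 4,
                                         dilutionRange = c(0.5, 2)))
  d <- plantedTruth(sp2)$dilution
  ratio <- integrateSpectra(sp2) / d
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("morphometry draws are positive and recover planted shifts", {
  cfg <- smallStudyConfig(seed = 23)
  m <- simulateMorphometry(cfg)$measurements
  expect_true(all(m[, -(1:2)] > 0))
  # roundness formula holds exactly on the generated geometry
  expect_equal(roundness(m$mito_area_um2, m$mito_major_um),
               m$mito_roundness, tolerance = 1e-12)
  # planted SHAM > healthy glomerular-area shift is recovered
  expect_lt(t.test(m$glom_area_um2[m$group == "SHAM"],
                   m$glom_area_um2[m$group == "healthy"],
                   alternative = "greater")$p.value, 0.01)
})

test_that("null morphometry shows no spurious group differences", {
  eq <- list(mean = c(healthy = 100, SHAM = 100, DMT = 100),
             sd = c(healthy = 10, SHAM = 10, DMT = 10))
  pvals <- vapply(seq_len(300), function(i) {
    cfg <- syntheticStudyConfig(
      seed = 1000 + i,
      morphometry = list(groups = c(healthy = 8, SHAM = 8, DMT = 8),
                         params = utils::modifyList(
                           renomix:::.defaultMorphoParams(),
                           list(glom_area_um2 = eq))))
    m <- simulateMorphometry(cfg)$measurements
    t.test(m$glom_area_um2[m$group == "SHAM"],
           m$glom_area_um2[m$group == "healthy"])$p.value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.01)
  expect_lte(mean(pvals < 0.05), 0.10)
})
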