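test_that("per-type averaging equals brute-force group means", {
  m1 <- matrix(c(1, 3), 2, 1, dimnames = list(NULL, "f1"))
  expect_equal(unname(averageExpressionByType(m1, c("S1", "S1"))[1, 1]), 2)
  # single cell per type: identity
  m2 <- matrix(1:6, 2, 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  a2 <- averageExpressionByType(m2, c("S1", "DCT"))
  expect_equal(a2["f2", "S1"], 3)
  expect_equal(a2["f2", "DCT"], 4)
  set.seed(41)
  cells <- matrix(rnorm(100), 20, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  lab <- sample(c("S1", "mTAL", "CNT"), 20, replace = TRUE)
  atlas <- averageExpressionByType(cells, lab)
  for (ty in unique(lab))
    expect_equal(atlas[, ty], colMeans(cells[lab == ty, , drop = FALSE]),
                 tolerance = 1e-12)
  expect_error(averageExpressionByType(cells, lab[-1]), "one label")
  expect_error(averageExpressionByType(cells, c(lab[-1], NA)), "unlabelled")
})

test_that("argmax localization assigns compartments and flags ties", {
  atlas <- matrix(1, 3, 14, dimnames = list(c("a", "b", "c"),
                                            tubuleCellTypes()))
  atlas["a", "S2"] <- 5
  atlas["b", "CNT"] <- 5
  atlas["c", c("S3", "mTAL")] <- 5   # tie: first in ontology order wins
  loc <- localizeFeatures(c("a", "b", "c", "absent"), atlas)
  expect_identical(loc$cellType[1:3], c("S2", "CNT", "S3"))
  expect_identical(loc$compartment[1:3],
                   c("proximal_tubule", "rest_of_tubule",
                     "proximal_tubule"))
  expect_identical(loc$tie[1:3], c(FALSE, FALSE, TRUE))
  expect_false(loc$inAtlas[4])
  expect_true(is.na(loc$cellType[4]))
})

test_that("localization equals a brute-force row-max scan", {
  set.seed(43)
  for (i in 1:5) {
    atlas <- matrix(rexp(200 * 14), 200, 14,
                    dimnames = list(sprintf("f%03d", 1:200),
                                    tubuleCellTypes()))
    loc <- localizeFeatures(rownames(atlas), atlas)
    expect_identical(loc$cellType, bruteLocalize(atlas))
  }
})

test_that("stratification reproduces the printed responsive-gene shares", {
  # 165 of 200 concordant DEGs respond to >= 1 medication, 125 of them to
  # fenofibrate: the printed 75.8% share
  conc <- makeDEGs(200)
  drugSets <- list(
    fenofibrate = paste0("g", 1:125),
    liraglutide = paste0("g", 120:140),
    metformin = paste0("g", 135:155),
    ramipril = paste0("g", 150:160),
    rosuvastatin = paste0("g", 156:165))
  s <- stratifyByResponsiveness(conc, drugSets, atlas = NULL,
                                focalEntity = "fenofibrate")
  expect_identical(s$responsiveAny, 165L)
  expect_identical(s$focal$count, 125L)
  expect_identical(s$focal$pctOfResponsive, 75.8)
  # 147 responsive to >= 1 isotype, 96 PPAR-alpha-responsive: 65.3%
  isoSets <- list(PPARA = paste0("g", 1:96),
                  PPARD = paste0("g", 90:130),
                  PPARG = paste0("g", 125:147))
  s2 <- stratifyByResponsiveness(conc, isoSets, atlas = NULL,
                                 focalEntity = "PPARA")
  expect_identical(s2$responsiveAny, 147L)
  expect_identical(s2$focal$count, 96L)
  expect_identical(s2$focal$pctOfResponsive, 65.3)
  # empty concordant set: all zero
  s0 <- stratifyByResponsiveness(DEGSet(character(), character()),
                                 drugSets, NULL, "fenofibrate")
  expect_identical(s0$responsiveAny, 0L)
  expect_identical(s0$focal$pctOfResponsive, 0)
  expect_error(stratifyByResponsiveness(conc, drugSets, NULL, "aspirin"),
               "not among")
})

test_that("stratification counts are conserved across levels", {
  set.seed(47)
  atlas <- matrix(rexp(150 * 14), 150, 14,
                  dimnames = list(sprintf("g%03d", 1:150),
                                  tubuleCellTypes()))
  for (i in 1:10) {
    genes <- sprintf("g%03d", sample(1:300, 120))  # half outside the atlas
    conc <- DEGSet(genes, sample(c("up", "down"), 120, replace = TRUE))
    sets <- lapply(1:4, function(j) sample(genes, sample(10:60, 1)))
    names(sets) <- paste0("drug", 1:4)
    s <- stratifyByResponsiveness(conc, sets, atlas, "drug1")
    expect_identical(s$focal$count + s$other$count, s$responsiveAny)
    expect_identical(s$focalAtlas$present + s$focalAtlas$absent,
                     s$focal$count)
    expect_identical(s$otherAtlas$present + s$otherAtlas$absent,
                     s$other$count)
    expect_identical(s$focalAtlas$proximalTubule + s$focalAtlas$restOfTubule,
                     s$focalAtlas$present)
  }
})

test_that("multi-way overlaps match brute-force pattern counts", {
  v <- multiwayOverlap(list(A = c("a", "b"), B = c("b", "c")))
  expect_identical(v$count[v$pattern == "A"], 1L)
  expect_identical(v$count[v$pattern == "B"], 1L)
  expect_identical(v$count[v$pattern == "A&B"], 1L)
  vd <- multiwayOverlap(list(A = c("a", "b"), B = c("c", "d")))
  expect_identical(vd$count[vd$pattern == "A&B"], 0L)
  set.seed(53)
  for (i in 1:20) {
    ns <- sample(2:4, 1)
    sets <- lapply(seq_len(ns), function(j)
      sample(letters, sample(3:15, 1)))
    names(sets) <- LETTERS[seq_len(ns)]
    v <- multiwayOverlap(sets)
    expect_identical(sum(v$count), length(unique(unlist(sets))))
    br <- bruteVenn(sets)
    for (pat in names(br))
      expect_identical(v$count[v$pattern == pat], as.integer(br[[pat]]))
  }
  expect_error(multiwayOverlap(list(A = "a")), "2 and 8")
})

test_that("fraction of known targets hit is a plain percentage", {
  expect_identical(fractionOfKnownTargets(c("a", "b"), letters[1:10]), 20.0)
  expect_identical(fractionOfKnownTargets("zz", letters[1:10]), 0.0)
  expect_identical(fractionOfKnownTargets(letters, letters[1:10]), 100.0)
  # the printed study value: 125 DEGs of 880 fenofibrate targets = 14.2%
  expect_identical(
    fractionOfKnownTargets(paste0("t", 1:125), paste0("t", 1:880)), 14.2)
  expect_error(fractionOfKnownTargets("a", character()), "empty")
})
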