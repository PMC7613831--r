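test_that("rank-statistic AUC matches the all-pairs oracle", {
  expect_equal(aucScore(c(FALSE, FALSE, TRUE, TRUE), 1:4), 1)
  expect_equal(aucScore(c(FALSE, FALSE, TRUE, TRUE), 4:1), 0)
  expect_equal(aucScore(c(FALSE, TRUE, FALSE, TRUE), rep(2, 4)), 0.5)
  set.seed(81)
  for (i in seq_len(100)) {
    n <- sample(4:50, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c(TRUE, FALSE)
    sc <- sample(round(rnorm(n), 1))    # rounded scores force ties
    expect_equal(aucScore(lab, sc), bruteAUC(lab, sc), tolerance = 1e-12)
  }
  expect_error(aucScore(rep(TRUE, 4), 1:4), "both classes")
})

test_that("AUC agrees with the established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  for (i in 1:5) {
    lab <- rep(c(FALSE, TRUE), each = 15)
    sc <- rnorm(30) + lab
    expect_equal(aucScore(lab, sc),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
                 tolerance = 1e-9)
  }
})

test_that("confusion metrics satisfy their defining identities", {
  act <- c(rep("pos", 10), rep("neg", 10))
  prd <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
  cm <- confusionMetrics(act, prd, positive = "pos")
  expect_identical(c(cm$TP, cm$FN, cm$TN, cm$FP), c(9L, 1L, 8L, 2L))
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.8)
  perfect <- confusionMetrics(act, act, positive = "pos")
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  allPos <- confusionMetrics(act, rep("pos", 20), positive = "pos")
  expect_equal(allPos$specificity, 0)
  expect_error(confusionMetrics(act, prd[-1]), "mismatch")
})

test_that("rdCV separates separable classes and is seed-deterministic", {
  set.seed(91)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("V%02d", 1:p)))
  y <- rep(c("A", "B"), each = n / 2)
  # two informative variables with an 8-sigma class separation
  X[, 1:2] <- 0.5 * X[, 1:2] + 4 * (y == "B")
  fit <- fitRDCV(X, y, nOuter = 5, nRep = 3, nTree = 60, seed = 1)
  expect_identical(fit@misclassifications, 0L)
  expect_equal(fit@auc, 1)
  expect_true(all(fit@probabilities >= 0 & fit@probabilities <= 1))
  fc <- fit@flavorCounts
  expect_true(fc["min"] <= fc["mid"] && fc["mid"] <= fc["max"])
  expect_true(all(is.finite(fit@errorCurve$meanError)))
  fit2 <- fitRDCV(X, y, nOuter = 5, nRep = 3, nTree = 60, seed = 1)
  expect_identical(fit@probabilities, fit2@probabilities)
  expect_identical(fit@giniImportance, fit2@giniImportance)
  expect_error(fitRDCV(X, rep("A", n)), "two classes")
  expect_error(fitRDCV(X[1:4, ], y[c(1, 2, 21, 22)], nOuter = 6),
               "more outer segments")
})

test_that("rdCV is uninformative under permuted labels", {
  set.seed(92)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("V%02d", 1:p)))
  y <- sample(rep(c("A", "B"), each = n / 2))
  fit <- fitRDCV(X, y, nOuter = 5, nRep = 3, nTree = 60, seed = 4)
  expect_gt(fit@auc, 0.25)
  expect_lt(fit@auc, 0.75)
})

test_that("informative variables rise to the top of the Gini ranking", {
  set.seed(93)
  n <- 40; p <- 30
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("V%02d", 1:p)))
  y <- rep(c("A", "B"), each = n / 2)
  X[y == "B", 1:3] <- X[y == "B", 1:3] + 2.5
  fit <- fitRDCV(X, y, nOuter = 5, nRep = 3, nTree = 80, seed = 5)
  top5 <- rankVariables(fit, "all")$variable[1:5]
  expect_true(all(sprintf("V%02d", 1:3) %in% top5))
})

test_that("variable ranking is ordered, deterministic and tie-flagged", {
  res <- new("RDCVResult",
             config = list(nOuter = 2, nRep = 1, flavor = "max"),
             errorCurve = data.frame(nVar = 3:2, meanError = c(0.1, 0.2)),
             flavorCounts = c(min = 2, mid = 2, max = 3),
             selectedVars = list(min = c("a", "b"), mid = c("a", "b"),
                                 max = c("a", "b", "c")),
             probabilities = c(s1 = 0.9), predicted = c(s1 = "B"),
             yTrue = c(s1 = "B"), positiveClass = "B",
             misclassifications = 0L, auc = 1,
             giniImportance = c(a = 0.8, b = 0.2, c = 0.2))
  rk <- rankVariables(res, "max")
  expect_identical(rk$variable, c("a", "b", "c"))  # lexicographic tie-break
  expect_identical(rk$tie, c(FALSE, TRUE, TRUE))
  expect_setequal(rk$variable, res@selectedVars$max)
})
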