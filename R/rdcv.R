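#' Repeated double cross-validation random-forest classifier
#'
#' Two-class random-forest classification with recursive elimination of the
#' least informative variables inside a repeated double cross-validation:
#' each repetition splits the samples into `nOuter` stratified outer
#' segments; for each held-out segment the remaining samples are again split
#' into inner folds that drive the elimination (train a forest, rank
#' variables by mean decrease in Gini, retain a `varRatio` fraction, record
#' the inner validation misclassification rate at every variable count).
#' The averaged inner error curve selects the variable count per model
#' flavor (`min` = count minimizing the error; `max` = largest count whose
#' error stays within a tolerance band above the minimum; `mid` = rounded
#' geometric mean of the two); the forest is refit at the selected count on
#' the outer-training samples and predicts the held-out segment. Held-out
#' class probabilities are averaged over repetitions, classified at the 50%
#' threshold and summarized by the misclassification count and AUC;
#' variable importance is the mean decrease in Gini averaged over the
#' per-repetition refits.
#'
#' @param X Numeric matrix, samples x variables (column names required).
#' @param y Two-level factor (or coercible) of class labels; the second
#'   level is treated as the positive class.
#' @param nOuter Outer cross-validation segments (default 5).
#' @param nRep Model repetitions (default 100).
#' @param varRatio Fraction of variables retained per elimination step
#'   (default 0.85).
#' @param flavor Model flavor used for the reported fit: "min", "mid" or
#'   "max" (default "max").
#' @param nTree Trees per forest (default 500).
#' @param maxTolerance Fraction of the inner error-curve range that the
#'   `max` flavor may sit above the minimal error (default 0.05).
#' @param seed Seed for the whole procedure (default 1).
#' @return An [RDCVResult-class].
#' @export
fitRDCV <- function(X, y, nOuter = 5, nRep = 100, varRatio = 0.85,
                    flavor = c("max", "mid", "min"), nTree = 500,
                    maxTolerance = 0.05, seed = 1) {
  flavor <- match.arg(flavor)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("sample_", seq_len(nrow(X)))
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (nOuter < 2) stop("nOuter must be >= 2")
  if (nOuter > nrow(X)) stop("more outer segments than samples")
  if (varRatio <= 0 || varRatio >= 1) stop("varRatio must be in (0,1)")
  if (min(table(y)) < nOuter)
    warning("a class has fewer samples than outer segments; ",
            "segments are still stratified but may be unbalanced")
  pos <- levels(y)[2]
  p <- ncol(X)

  ## deterministic elimination ladder of variable counts
  counts <- p
  while (counts[length(counts)] > 2) {
    nxt <- min(counts[length(counts)] - 1L,
               ceiling(varRatio * counts[length(counts)]))
    counts <- c(counts, max(2L, nxt))
  }

  withSeed(seed, {
    probSum <- setNames(rep(0, nrow(X)), rownames(X))
    probN <- setNames(rep(0, nrow(X)), rownames(X))
    giniSum <- setNames(rep(0, p), colnames(X))
    giniN <- 0
    errSum <- rep(0, length(counts)); errN <- 0
    flavorTally <- matrix(0, nRep, 3,
                          dimnames = list(NULL, c("min", "mid", "max")))

    for (rep_i in seq_len(nRep)) {
      outerFold <- .stratifiedFolds(y, nOuter)
      repErr <- rep(0, length(counts)); repErrN <- 0

      innerStates <- vector("list", nOuter)
      for (o in seq_len(nOuter)) {
        testIdx <- which(outerFold == o)
        trainIdx <- which(outerFold != o)
        yTr <- droplevels(y[trainIdx])
        if (nlevels(yTr) < 2) next
        nInner <- max(2L, nOuter - 1L)
        innerFold <- .stratifiedFolds(yTr, nInner)

        foldErr <- matrix(NA_real_, nInner, length(counts))
        foldGini <- matrix(0, nInner, p,
                           dimnames = list(NULL, colnames(X)))
        for (f in seq_len(nInner)) {
          valIdx <- trainIdx[innerFold == f]
          fitIdx <- trainIdx[innerFold != f]
          if (nlevels(droplevels(y[fitIdx])) < 2) next
          vars <- colnames(X)
          for (ci in seq_along(counts)) {
            rf <- randomForest::randomForest(
              X[fitIdx, vars, drop = FALSE], y[fitIdx],
              ntree = nTree, importance = FALSE)
            pred <- stats::predict(rf, X[valIdx, vars, drop = FALSE])
            foldErr[f, ci] <- mean(pred != y[valIdx])
            imp <- rf$importance[, "MeanDecreaseGini"]
            if (ci == 1L) foldGini[f, vars] <- imp
            if (ci < length(counts)) {
              keep <- names(sort(imp, decreasing = TRUE))[
                seq_len(counts[ci + 1L])]
              vars <- keep
            }
          }
        }
        innerStates[[o]] <- list(testIdx = testIdx, trainIdx = trainIdx,
                                 gini = colMeans(foldGini))
        fe <- colMeans(foldErr, na.rm = TRUE)
        repErr <- repErr + fe; repErrN <- repErrN + 1
      }

      avgCurve <- repErr / max(repErrN, 1)
      sel <- .selectFlavorCounts(counts, avgCurve, maxTolerance)
      flavorTally[rep_i, ] <- sel
      errSum <- errSum + avgCurve; errN <- errN + 1

      nSel <- sel[[flavor]]
      for (o in seq_len(nOuter)) {
        st <- innerStates[[o]]
        if (is.null(st)) next
        rank <- names(sort(st$gini, decreasing = TRUE))
        vars <- rank[seq_len(min(nSel, length(rank)))]
        rf <- randomForest::randomForest(
          X[st$trainIdx, vars, drop = FALSE], y[st$trainIdx],
          ntree = nTree, importance = FALSE)
        pr <- stats::predict(rf, X[st$testIdx, vars, drop = FALSE],
                             type = "prob")[, pos]
        probSum[st$testIdx] <- probSum[st$testIdx] + pr
        probN[st$testIdx] <- probN[st$testIdx] + 1
        giniSum[vars] <- giniSum[vars] + rf$importance[, "MeanDecreaseGini"]
        giniN <- giniN + 1
      }
    }

    prob <- probSum / pmax(probN, 1)
    predicted <- ifelse(prob >= 0.5, pos, levels(y)[1])
    gini <- giniSum / max(giniN, 1)
    flavorCounts <- round(colMeans(flavorTally))
    flavorCounts <- pmin(pmax(flavorCounts, 2), p)
    rankAll <- names(sort(gini, decreasing = TRUE))
    selectedVars <- lapply(flavorCounts, function(k)
      rankAll[seq_len(min(k, length(rankAll)))])

    new("RDCVResult",
        config = list(nOuter = nOuter, nRep = nRep, varRatio = varRatio,
                      flavor = flavor, nTree = nTree,
                      maxTolerance = maxTolerance, seed = seed,
                      counts = counts),
        errorCurve = data.frame(nVar = counts,
                                meanError = errSum / max(errN, 1)),
        flavorCounts = flavorCounts,
        selectedVars = selectedVars,
        probabilities = prob,
        predicted = setNames(as.character(predicted), rownames(X)),
        yTrue = setNames(as.character(y), rownames(X)),
        positiveClass = pos,
        misclassifications = sum(predicted != as.character(y)),
        auc = aucScore(y == pos, prob),
        giniImportance = gini)
  })
}

## stratified assignment of samples to k folds
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

## flavor selection on the averaged inner error curve
.selectFlavorCounts <- function(counts, curve, maxTolerance) {
  ok <- is.finite(curve)
  cts <- counts[ok]; cv <- curve[ok]
  minErr <- min(cv)
  nMin <- min(cts[cv == minErr])           # fewest variables at the minimum
  band <- minErr + maxTolerance * (max(cv) - minErr)
  nMax <- max(cts[cv <= band])
  nMid <- round(exp(mean(log(c(nMin, nMax)))))
  c(min = nMin, mid = nMid, max = nMax)
}

#' Rank variables by mean decrease in Gini
#'
#' @param result An [RDCVResult-class].
#' @param flavor Which flavor's selected set to rank (default the fitted
#'   one); "all" ranks every variable.
#' @return data.frame `variable`, `meanDecreaseGini`, `rank`, `tie`,
#'   descending by importance with lexicographic tie-break.
#' @export
rankVariables <- function(result, flavor = NULL) {
  stopifnot(is(result, "RDCVResult"))
  flavor <- flavor %||% result@config$flavor
  g <- result@giniImportance
  if (!identical(flavor, "all"))
    g <- g[result@selectedVars[[flavor]]]
  o <- order(-g, names(g))
  g <- g[o]
  data.frame(variable = names(g), meanDecreaseGini = unname(g),
             rank = seq_along(g),
             tie = duplicated(unname(g)) | duplicated(unname(g),
                                                      fromLast = TRUE),
             row.names = NULL)
}

#' Confusion-matrix summary at a fixed classification
#'
#' @param actual,predicted Equal-length label vectors on the same alphabet.
#' @param positive The positive class (default: last sorted level).
#' @return List: `TP`, `FP`, `TN`, `FN`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
confusionMetrics <- function(actual, predicted, positive = NULL) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  actual <- as.character(actual); predicted <- as.character(predicted)
  lv <- sort(unique(c(actual, predicted)))
  if (length(lv) > 2) stop("two-class labels expected")
  positive <- positive %||% lv[length(lv)]
  tp <- sum(actual == positive & predicted == positive)
  fn <- sum(actual == positive & predicted != positive)
  tn <- sum(actual != positive & predicted != positive)
  fp <- sum(actual != positive & predicted == positive)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(actual))
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties contributing one half.
#'
#' @param labels Logical (or two-level) vector; TRUE / second level =
#'   positive.
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(labels, scores) {
  if (!is.logical(labels)) {
    f <- factor(labels)
    if (nlevels(f) != 2) stop("labels must have two classes")
    labels <- f == levels(f)[2]
  }
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
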