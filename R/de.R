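#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes (restricted
#' to genes with a positive geometric mean across samples) of
#' k_ij / (prod_j k_ij)^(1/n).
#'
#' @param counts A [CountStudy-class] or a non-negative integer matrix
#'   (genes x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
#' @examples
#' k <- cbind(s1 = c(10, 100, 1), s2 = c(20, 200, 2))
#' estimateSizeFactors(k)  # 1/sqrt(2), sqrt(2)
estimateSizeFactors <- function(counts) {
  k <- if (is(counts, "CountStudy")) assay(counts, "counts") else
    as.matrix(counts)
  if (any(k < 0)) stop("counts must be non-negative")
  logGeo <- rowMeans(log(k))          # -Inf where any count is zero
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no gene has positive counts in all samples")
  geo <- exp(logGeo[use])
  sf <- apply(k[use, , drop = FALSE] / geo, 2, stats::median)
  setNames(sf, colnames(k))
}

#' Per-gene method-of-moments dispersion
#'
#' Normalizes counts by size factors, pools the within-group variance across
#' groups, and returns alpha_i = max(floor, (s^2 - mu)/mu^2) per gene, where
#' mu is the mean normalized count. Genes with constant normalized counts hit
#' the floor.
#'
#' @param counts A [CountStudy-class] or count matrix.
#' @param sizeFactors Per-sample positive factors
#'   (default [estimateSizeFactors()]).
#' @param group Per-sample group labels; taken from the CountStudy when
#'   omitted.
#' @param floor Lower bound for the dispersion (default 1e-8).
#' @return Named non-negative numeric vector, one dispersion per gene.
#' @export
estimateDispersions <- function(counts, sizeFactors = NULL, group = NULL,
                                floor = 1e-8) {
  if (is(counts, "CountStudy")) {
    group <- group %||% sampleGroups(counts)
    k <- assay(counts, "counts")
  } else k <- as.matrix(counts)
  if (is.null(group)) stop("'group' is required for a plain matrix")
  if (any(table(group) < 2)) stop("every group needs >= 2 samples")
  sizeFactors <- sizeFactors %||% estimateSizeFactors(k)
  q <- sweep(k, 2, sizeFactors, "/")

  groups <- unique(group)
  ssq <- 0; df <- 0
  for (g in groups) {
    qg <- q[, group == g, drop = FALSE]
    ng <- ncol(qg)
    ssq <- ssq + rowSums((qg - rowMeans(qg))^2)
    df <- df + (ng - 1)
  }
  s2 <- ssq / df
  mu <- rowMeans(q)
  alpha <- ifelse(mu > 0, pmax(floor, (s2 - mu) / mu^2), floor)
  setNames(alpha, rownames(k))
}

#' Two-group negative-binomial Wald test
#'
#' Fits the simplified two-group NB model per gene: the log2 fold-change is
#' the log2 ratio of group means of size-factor-normalized counts, its
#' standard error follows from the NB variance mu + alpha*mu^2 by the delta
#' method, the Wald z is their ratio with a two-sided normal p-value, and p
#' is Benjamini-Hochberg adjusted across genes. By default the per-gene
#' moment dispersions are moderated to their across-gene mean before
#' entering the standard error; `moderation = "none"` uses the raw per-gene
#' values.
#'
#' @param counts A [CountStudy-class] or count matrix.
#' @param contrast Character pair `c(numerator, denominator)` of group
#'   labels; the reported log2FC is numerator vs denominator.
#' @param sizeFactors,dispersions Optional precomputed values.
#' @param group Per-sample labels when `counts` is a plain matrix.
#' @param moderation "common" (default) or "none".
#' @return data.frame with one row per gene: `gene`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `allZero`, and the
#'   contrast as an attribute. All-zero genes are flagged and given
#'   log2FC = 0, p = 1.
#' @export
waldTest <- function(counts, contrast, sizeFactors = NULL,
                     dispersions = NULL, group = NULL,
                     moderation = c("common", "none")) {
  moderation <- match.arg(moderation)
  if (is(counts, "CountStudy")) {
    group <- group %||% sampleGroups(counts)
    k <- assay(counts, "counts")
  } else k <- as.matrix(counts)
  if (is.null(group)) stop("'group' is required for a plain matrix")
  if (!all(contrast %in% group)) stop("contrast group absent from samples")
  if (any(table(group[group %in% contrast]) < 2))
    stop("both contrast groups need >= 2 samples")

  if (is.null(rownames(k)))
    rownames(k) <- sprintf("gene%05d", seq_len(nrow(k)))
  sizeFactors <- sizeFactors %||% estimateSizeFactors(k)
  dispersions <- dispersions %||%
    estimateDispersions(k, sizeFactors, group = group)
  alpha <- if (moderation == "common")
    rep(mean(dispersions), nrow(k)) else dispersions

  q <- sweep(k, 2, sizeFactors, "/")
  qN <- q[, group == contrast[1], drop = FALSE]   # numerator group
  qD <- q[, group == contrast[2], drop = FALSE]
  nN <- ncol(qN); nD <- ncol(qD)
  mN <- rowMeans(qN); mD <- rowMeans(qD)

  allZero <- mN == 0 & mD == 0
  ## pseudo-mean guard for one-sided zeros; keeps lfc and SE finite
  eps <- 0.5
  mNg <- ifelse(mN > 0, mN, eps)
  mDg <- ifelse(mD > 0, mD, eps)
  lfc <- ifelse(allZero, 0, log2(mNg / mDg))
  varN <- (mNg + alpha * mNg^2) / nN
  varD <- (mDg + alpha * mDg^2) / nD
  se <- sqrt(varN / mNg^2 + varD / mDg^2) / log(2)
  stat <- ifelse(allZero, 0, lfc / se)
  p <- ifelse(allZero, 1, 2 * stats::pnorm(-abs(stat)))
  res <- data.frame(gene = rownames(k), baseMean = rowMeans(q),
                    log2FoldChange = lfc, lfcSE = se, stat = stat,
                    pvalue = p, padj = adjustBH(p), allZero = allZero,
                    row.names = NULL)
  attr(res, "contrast") <- paste(contrast[1], "vs", contrast[2])
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, clipped at 1.
#' @export
adjustBH <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at the study thresholds
#'
#' A gene is differentially expressed iff its absolute fold-change is at
#' least `fcThreshold` (inclusive) and its adjusted p is strictly below
#' `alpha`; direction is the sign of the log2 fold-change.
#'
#' @param de A [waldTest()] result.
#' @param fcThreshold Linear fold-change gate (default 1.3).
#' @param alpha Adjusted-p gate (default 0.05).
#' @return A [DEGSet-class].
#' @export
callDEGs <- function(de, fcThreshold = 1.3, alpha = 0.05) {
  sel <- abs(de$log2FoldChange) >= log2(fcThreshold) & de$padj < alpha &
    !de$allZero
  DEGSet(gene = de$gene[sel],
         direction = ifelse(de$log2FoldChange[sel] > 0, "up", "down"),
         contrast = attr(de, "contrast") %||% "unspecified",
         fcThreshold = fcThreshold, alpha = alpha)
}

#' Cross-model concordant DEGs
#'
#' Genes present in both sets with the same direction of regulation.
#'
#' @param a,b [DEGSet-class] objects for the same contrast in two models.
#' @return A [DEGSet-class] of the direction-matched intersection.
#' @export
concordantDEGs <- function(a, b) {
  da <- degDirections(a); db <- degDirections(b)
  common <- intersect(names(da), names(db))
  keep <- common[da[common] == db[common]]
  DEGSet(gene = keep, direction = unname(da[keep]),
         contrast = paste(a@contrast, "&", b@contrast),
         fcThreshold = a@fcThreshold, alpha = a@alpha)
}

#' Fraction of disease-altered transcripts corrected by treatment
#'
#' A disease DEG (SHAM vs healthy) counts as corrected when it reappears in
#' the treatment contrast (DMT vs SHAM) with the opposite direction
#' (`mode = "opposite"`, default) or in any direction (`mode = "any"`).
#' The percentage is reported to one decimal, half away from zero.
#'
#' @param diseaseDegs,treatmentDegs [DEGSet-class] objects.
#' @param mode "opposite" or "any".
#' @return List: `count`, `total`, `percentage`.
#' @export
#' @examples
#' dis <- DEGSet(paste0("g", 1:379), rep("up", 379), "SHAM vs healthy")
#' trt <- DEGSet(paste0("g", 1:206), rep("down", 206), "DMT vs SHAM")
#' correctedFraction(dis, trt)$percentage  # 54.4
correctedFraction <- function(diseaseDegs, treatmentDegs,
                              mode = c("opposite", "any")) {
  mode <- match.arg(mode)
  if (length(diseaseDegs) == 0)
    stop("empty disease DEG set: percentage undefined")
  dd <- degDirections(diseaseDegs)
  td <- degDirections(treatmentDegs)
  common <- intersect(names(dd), names(td))
  corrected <- if (mode == "opposite")
    common[dd[common] != td[common]] else common
  list(count = length(corrected), total = length(dd),
       percentage = roundHalfUp(100 * length(corrected) / length(dd), 1),
       genes = corrected)
}

#' Regularized-log-style transform
#'
#' A monotone variance-stabilizing transform of normalized counts,
#' log2(k/s + 1), standing in for the regularized log transform for
#' downstream PCA and correlation work.
#'
#' @param counts A [CountStudy-class] or count matrix.
#' @param sizeFactors Optional per-sample factors.
#' @return Real matrix of the same dimensions.
#' @export
rlogLikeTransform <- function(counts, sizeFactors = NULL) {
  k <- if (is(counts, "CountStudy")) assay(counts, "counts") else
    as.matrix(counts)
  sizeFactors <- sizeFactors %||% estimateSizeFactors(k)
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  log2(sweep(k, 2, sizeFactors, "/") + 1)
}

#' Principal component scores of a samples x features matrix
#'
#' Singular value decomposition of the column-centered matrix. The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param x Numeric matrix, samples in rows.
#' @param nComponents Number of components to return (default
#'   `min(dim) - ` as available).
#' @return List: `scores` (samples x PCs), `loadings` (features x PCs),
#'   `varianceExplained` (fraction per PC), `constant` (TRUE when the input
#'   had no variance, flagged with a warning).
#' @export
pcaScores <- function(x, nComponents = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  totVar <- sum(xc^2)
  if (totVar == 0) {
    warning("constant matrix: zero-variance components")
    k <- nComponents %||% 1L
    return(list(scores = matrix(0, nrow(x), k),
                loadings = matrix(0, ncol(x), k),
                varianceExplained = rep(0, k), constant = TRUE))
  }
  s <- svd(xc)
  k <- min(nComponents %||% length(s$d), length(s$d))
  ## sign convention: largest |loading| positive per component
  for (i in seq_len(k)) {
    v <- s$v[, i]
    if (v[which.max(abs(v))] < 0) {
      s$v[, i] <- -s$v[, i]; s$u[, i] <- -s$u[, i]
    }
  }
  scores <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  loadings <- s$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       varianceExplained = s$d[seq_len(k)]^2 / totVar, constant = FALSE)
}
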