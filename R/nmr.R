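#' Running-quantile baseline correction
#'
#' Estimates a smooth baseline per spectrum as a running low quantile:
#' windows of `window` points are anchored every `step` points, the
#' `quantile` of each window is taken as a baseline sample (assigned to the
#' quantile's expected position within the window, which makes the estimate
#' exact on locally linear backgrounds), the samples are linearly
#' interpolated (with linear extrapolation at the edges) and subtracted.
#'
#' @param spectra An [NMRSpectra-class], or a numeric intensity vector.
#' @param window Window size in axis points (default 1000).
#' @param quantile Quantile taken as the baseline level (default 0.1).
#' @param step Anchor spacing in points (default 500).
#' @param noiseRecenter Recenters the estimate by the expected noise
#'   quantile offset (the running q-quantile of baseline-plus-noise sits
#'   qnorm(q) noise-SDs below the true baseline), using a robust
#'   first-difference noise-scale estimate; exactly zero for noiseless
#'   input (default TRUE).
#' @return Same type as the input, baseline-subtracted.
#' @export
baselineCorrect <- function(spectra, window = 1000, quantile = 0.1,
                            step = 500, noiseRecenter = TRUE) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  if (step > window) stop("step must not exceed window")
  correct1 <- function(v) {
    n <- length(v)
    if (window > n) stop("window exceeds the spectrum length")
    centers <- unique(c(seq(1, n, by = step), n))
    half <- floor(window / 2)
    lo <- pmax(1, centers - half)
    hi <- pmin(n, centers + half)
    y <- mapply(function(l, h) stats::quantile(v[l:h], quantile,
                                               names = FALSE), lo, hi)
    x <- lo + quantile * (hi - lo)   # expected quantile position
    o <- order(x); x <- x[o]; y <- y[o]
    keep <- !duplicated(x); x <- x[keep]; y <- y[keep]
    base <- if (length(x) == 1L) rep(y, n) else {
      b <- stats::approx(x, y, xout = seq_len(n), rule = 2)$y
      ## linear extrapolation beyond the outermost anchors
      s1 <- (y[2] - y[1]) / (x[2] - x[1])
      m <- length(x)
      s2 <- (y[m] - y[m - 1]) / (x[m] - x[m - 1])
      i <- seq_len(n)
      b[i < x[1]] <- y[1] + s1 * (i[i < x[1]] - x[1])
      b[i > x[m]] <- y[m] + s2 * (i[i > x[m]] - x[m])
      b
    }
    if (noiseRecenter) {
      sigma <- stats::mad(diff(v)) / sqrt(2)
      base <- base - stats::qnorm(quantile) * sigma
    }
    v - base
  }
  if (is(spectra, "NMRSpectra")) {
    out <- spectra
    out@intensity <- apply(spectra@intensity, 2, correct1)
    return(out)
  }
  correct1(as.numeric(spectra))
}

## Ricker (Mexican-hat) kernel at scale `a`, unit L2 norm
.ricker <- function(a) {
  t <- seq(-ceiling(5 * a), ceiling(5 * a))
  (2 / (sqrt(3 * a) * pi^0.25)) * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

## same-length convolution with zero padding
.convSame <- function(x, k) {
  n <- length(x); m <- length(k); half <- (m - 1L) %/% 2L
  full <- stats::convolve(x, rev(k), type = "open")
  full[(half + 1L):(half + n)]
}

## indices of local maxima of v (strict neighbours, dominant in +-w window)
.localMaxima <- function(v, w) {
  n <- length(v)
  if (n < 3) return(integer())
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (w > 1 && length(cand)) {
    keep <- vapply(cand, function(i) {
      lo <- max(1, i - w); hi <- min(n, i + w)
      v[i] >= max(v[lo:hi])
    }, logical(1))
    cand <- cand[keep]
  }
  cand
}

#' Mexican-hat continuous-wavelet peak detection
#'
#' Computes the continuous wavelet transform of each spectrum with a Ricker
#' (Mexican-hat) kernel over a ladder of scales, links local maxima of the
#' coefficients into ridge lines across scales, and reports a peak for each
#' ridge long and strong enough: position from the smallest scale on the
#' ridge, signal-to-noise as the ridge's maximal coefficient over a robust
#' (MAD-based) noise level taken from the smallest-scale coefficients.
#'
#' @param spectra [NMRSpectra-class] or numeric intensity vector.
#' @param scales Integer vector of wavelet scales in axis points
#'   (default roughly 2..32, log-spaced); at least 2 required.
#' @param minSNR Minimal signal-to-noise ratio (default 3).
#' @param minRidgeLength Minimal number of scales a ridge must span
#'   (default one third of the ladder, at least 2).
#' @param ppm Axis for a plain-vector input.
#' @return data.frame peak list: `sample`, `index`, `ppm`, `intensity`
#'   (value of the input spectrum at the apex), `scale` (best scale), `snr`.
#' @export
detectPeaksCWT <- function(spectra, scales = NULL, minSNR = 3,
                           minRidgeLength = NULL, ppm = NULL) {
  if (is(spectra, "NMRSpectra")) {
    axis <- ppmAxis(spectra)
    ints <- spectraIntensity(spectra)
  } else {
    axis <- ppm
    ints <- matrix(as.numeric(spectra), ncol = 1,
                   dimnames = list(NULL, "sample_1"))
  }
  n <- nrow(ints)
  scales <- sort(unique(round(scales %||% 2^seq(1, 5, by = 0.5))))
  if (length(scales) < 2) stop("need >= 2 scales")
  if (max(scales) * 10 >= n) stop("scales too large for the axis")
  if (minSNR <= 0) stop("minSNR must be positive")
  minRidgeLength <- minRidgeLength %||% max(2L, floor(length(scales) / 3))

  kernels <- lapply(scales, .ricker)
  out <- lapply(colnames(ints), function(sm) {
    v <- ints[, sm]
    cwt <- vapply(kernels, function(k) .convSame(v, k), numeric(n))
    ## robust noise level with a numerical floor so that noiseless input
    ## does not promote convolution round-off to spurious ridges
    noise <- max(1.4826 * stats::median(abs(cwt[, 1])),
                 1e-6 * max(abs(cwt)), .Machine$double.eps)

    ## ridge linking, largest scale downward
    ns <- length(scales)
    maxima <- lapply(seq_len(ns), function(i)
      .localMaxima(cwt[, i], w = max(1L, scales[i] %/% 2L)))
    ridges <- list()
    open <- list()   # each: pos, coefs, scaleIdx, gap
    for (i in rev(seq_len(ns))) {
      mx <- maxima[[i]]
      used <- logical(length(mx))
      tol <- max(3, scales[i])
      if (length(open)) {
        for (r in seq_along(open)) {
          if (!length(mx)) { open[[r]]$gap <- open[[r]]$gap + 1L; next }
          d <- abs(mx - open[[r]]$pos)
          j <- which.min(d)
          if (d[j] <= tol && !used[j]) {
            used[j] <- TRUE
            open[[r]]$pos <- mx[j]
            open[[r]]$coefs <- c(open[[r]]$coefs, cwt[mx[j], i])
            open[[r]]$scaleIdx <- c(open[[r]]$scaleIdx, i)
            open[[r]]$gap <- 0L
          } else open[[r]]$gap <- open[[r]]$gap + 1L
        }
      }
      closed <- vapply(open, function(r) r$gap > 2L, logical(1))
      ridges <- c(ridges, open[closed])
      open <- open[!closed]
      for (j in which(!used))   # new ridges born at this scale
        open <- c(open, list(list(pos = mx[j], coefs = cwt[mx[j], i],
                                  scaleIdx = i, gap = 0L)))
    }
    ridges <- c(ridges, open)
    if (!length(ridges)) return(NULL)

    peaks <- do.call(rbind, lapply(ridges, function(r) {
      if (length(r$scaleIdx) < minRidgeLength) return(NULL)
      best <- which.max(r$coefs)
      snr <- r$coefs[best] / noise
      if (!is.finite(snr) || snr < minSNR) return(NULL)
      data.frame(index = r$pos, scale = scales[r$scaleIdx[best]],
                 snr = snr)
    }))
    if (is.null(peaks) || !nrow(peaks)) return(NULL)
    ## merge near-duplicate apices, keeping the stronger
    peaks <- peaks[order(peaks$index, -peaks$snr), , drop = FALSE]
    keep <- rep(TRUE, nrow(peaks))
    last <- 1L
    if (nrow(peaks) > 1) for (i in 2:nrow(peaks)) {
      if (peaks$index[i] - peaks$index[last] <= 3) {
        if (peaks$snr[i] > peaks$snr[last]) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
      } else last <- i
    }
    peaks <- peaks[keep, , drop = FALSE]
    ## parabolic apex refinement removes the sampling-grid bias of v[index]
    apex <- vapply(peaks$index, function(i) {
      if (i <= 1 || i >= n) return(v[i])
      den <- v[i - 1] - 2 * v[i] + v[i + 1]
      if (den >= 0) return(v[i])
      v[i] - (v[i - 1] - v[i + 1])^2 / (8 * den)
    }, numeric(1))
    data.frame(sample = sm, index = peaks$index,
               ppm = if (is.null(axis)) NA_real_ else axis[peaks$index],
               intensity = apex, scale = peaks$scale,
               snr = peaks$snr, row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample = character(), index = integer(),
                      ppm = numeric(), intensity = numeric(),
                      scale = numeric(), snr = numeric())
  res
}

#' Group detected peaks across samples by chemical shift
#'
#' Single-linkage clustering of peak positions with the given ppm
#' tolerance; each cluster becomes a peak group whose consensus position is
#' the median of its members. When a sample contributes more than one peak
#' to a group, only its most intense peak is retained and the rest are
#' returned to the unassigned pool.
#'
#' @param peaks Peak list from [detectPeaksCWT()] (needs `sample`, `ppm`,
#'   `intensity`).
#' @param tolerance Single-linkage cut height in ppm (default 0.005).
#' @return List of class `PeakGroupTable`: `groups` (group, ppm, n),
#'   `members` (group, sample, ppm, intensity), `unassigned`.
#' @export
groupPeaks <- function(peaks, tolerance = 0.005) {
  if (tolerance <= 0) stop("tolerance must be positive")
  stopifnot(all(c("sample", "ppm", "intensity") %in% names(peaks)))
  if (!nrow(peaks)) {
    return(structure(list(groups = data.frame(group = integer(),
                                              ppm = numeric(),
                                              n = integer()),
                          members = cbind(peaks[0, ], group = integer()),
                          unassigned = peaks[0, ]),
                     class = "PeakGroupTable"))
  }
  cl <- if (nrow(peaks) == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(peaks$ppm), "single"),
                  h = tolerance)
  peaks$group <- cl
  keep <- unlist(lapply(split(seq_len(nrow(peaks)),
                              list(peaks$group, peaks$sample), drop = TRUE),
                        function(i) i[which.max(peaks$intensity[i])]))
  members <- peaks[sort(keep), c("group", "sample", "ppm", "intensity")]
  unassigned <- peaks[setdiff(seq_len(nrow(peaks)), keep),
                      c("sample", "ppm", "intensity")]
  grp <- do.call(rbind, lapply(split(members, members$group), function(g)
    data.frame(group = g$group[1], ppm = stats::median(g$ppm),
               n = nrow(g))))
  ## relabel groups by consensus ppm for determinism
  o <- order(grp$ppm)
  relabel <- setNames(seq_along(o), grp$group[o])
  grp <- grp[o, ]; grp$group <- seq_along(o)
  members$group <- relabel[as.character(members$group)]
  members <- members[order(members$group, members$sample), ]
  rownames(grp) <- rownames(members) <- rownames(unassigned) <- NULL
  structure(list(groups = grp, members = members, unassigned = unassigned),
            class = "PeakGroupTable")
}

#' @export
print.PeakGroupTable <- function(x, ...) {
  cat("PeakGroupTable:", nrow(x$groups), "groups,", nrow(x$members),
      "retained peaks,", nrow(x$unassigned), "unassigned\n")
  invisible(x)
}

#' One-dimensional silhouette widths
#'
#' s(i) = (b - a) / max(a, b) on absolute position differences, where a is
#' the mean distance to the other members of i's cluster and b the smallest
#' mean distance to another cluster. Members of singleton clusters get
#' s = 1; when only one cluster exists every width is 1.
#'
#' @param positions Numeric vector.
#' @param labels Cluster labels, parallel to `positions`.
#' @return Numeric vector of silhouette widths.
#' @export
silhouetteWidths <- function(positions, labels) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  if (length(uniq) == 1L) return(rep(1, length(positions)))
  vapply(seq_along(positions), function(i) {
    own <- positions[setdiff(which(labels == labels[i]), i)]
    if (!length(own)) return(1)
    a <- mean(abs(positions[i] - own))
    b <- min(vapply(setdiff(uniq, labels[i]), function(l)
      mean(abs(positions[i] - positions[labels == l])), numeric(1)))
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Silhouette-gated iterative regrouping of peak groups
#'
#' Computes the mean silhouette of every peak group on member ppm
#' positions; groups below the threshold are dissolved and their members
#' regrouped with a tightened tolerance, iterating until every retained
#' group reaches the threshold or `maxIter` is hit (in which case the
#' still-failing groups are dropped with a warning).
#'
#' @param groupTable A `PeakGroupTable` from [groupPeaks()].
#' @param threshold Minimal acceptable mean silhouette (default 0.6).
#' @param maxIter Maximal regrouping iterations (default 20).
#' @param tolerance Initial regrouping tolerance; defaults to the median
#'   within-group ppm spread or 0.005.
#' @param shrink Multiplier applied to the tolerance at each iteration
#'   (default 0.6), guaranteeing progress towards singletons.
#' @return A `PeakGroupTable` whose retained groups all have mean
#'   silhouette >= `threshold`; per-group silhouettes in `groups$silhouette`.
#' @export
silhouetteFilter <- function(groupTable, threshold = 0.6, maxIter = 20,
                             tolerance = 0.005, shrink = 0.6) {
  members <- groupTable$members
  unassigned <- groupTable$unassigned
  if (!nrow(members)) return(groupTable)
  tol <- tolerance
  ## a lone multi-member group has no between-cluster distance to judge it
  ## by: when its largest internal gap exceeds the grouping tolerance it
  ## plainly spans several peaks, so dissolve and regroup it; a tight lone
  ## group is retained (silhouette 1 by convention)
  if (length(unique(members$group)) == 1L && nrow(members) > 1L &&
      max(diff(sort(members$ppm))) > tol) {
    re <- groupPeaks(members[, c("sample", "ppm", "intensity")], tol)
    members <- re$members
    if (nrow(re$unassigned)) unassigned <- rbind(unassigned, re$unassigned)
  }
  for (iter in seq_len(maxIter)) {
    s <- silhouetteWidths(members$ppm, members$group)
    gs <- tapply(s, members$group, mean)
    bad <- names(gs)[gs < threshold]
    if (!length(bad)) break
    tol <- tol * shrink
    pool <- members[members$group %in% bad, ]
    members <- members[!members$group %in% bad, ]
    ## regroup the dissolved members at the tightened tolerance
    re <- groupPeaks(pool[, c("sample", "ppm", "intensity")], tol)
    if (nrow(re$members)) {
      off <- if (nrow(members)) max(members$group) else 0L
      re$members$group <- re$members$group + off
      members <- rbind(members, re$members)
    }
    if (nrow(re$unassigned)) unassigned <- rbind(unassigned, re$unassigned)
    if (iter == maxIter) {
      s <- silhouetteWidths(members$ppm, members$group)
      gs <- tapply(s, members$group, mean)
      bad <- names(gs)[gs < threshold]
      if (length(bad)) {
        warning(length(bad),
                " peak group(s) failed the silhouette gate at maxIter ",
                "and were dropped")
        drop <- members$group %in% bad
        unassigned <- rbind(unassigned,
                            members[drop, c("sample", "ppm", "intensity")])
        members <- members[!drop, ]
      }
    }
  }
  ## rebuild the group table with consensus positions and silhouettes
  if (!nrow(members)) {
    gt <- groupPeaks(members[, c("sample", "ppm", "intensity")], tolerance)
    gt$unassigned <- unassigned
    return(gt)
  }
  s <- silhouetteWidths(members$ppm, members$group)
  gs <- tapply(s, members$group, mean)
  grp <- do.call(rbind, lapply(split(members, members$group), function(g)
    data.frame(group = g$group[1], ppm = stats::median(g$ppm),
               n = nrow(g), silhouette = unname(gs[as.character(g$group[1])]))))
  o <- order(grp$ppm)
  relabel <- setNames(seq_along(o), grp$group[o])
  grp <- grp[o, ]; grp$group <- seq_along(o)
  members$group <- unname(relabel[as.character(members$group)])
  members <- members[order(members$group, members$sample), ]
  rownames(grp) <- rownames(members) <- NULL
  structure(list(groups = grp, members = members, unassigned = unassigned),
            class = "PeakGroupTable")
}

#' Build the sample x peak-group intensity matrix
#'
#' @param groupTable A `PeakGroupTable`.
#' @param samples Sample ids forming the rows (defaults to those seen in the
#'   members; pass the full cohort to include samples with no detections).
#' @return Numeric matrix, samples x groups, NA where a sample contributed
#'   no peak; columns named by consensus ppm.
#' @export
buildIntensityMatrix <- function(groupTable, samples = NULL) {
  m <- groupTable$members
  samples <- samples %||% sort(unique(m$sample))
  cols <- sprintf("%.4f", groupTable$groups$ppm)
  mat <- matrix(NA_real_, length(samples), nrow(groupTable$groups),
                dimnames = list(samples, cols))
  if (nrow(m)) {
    idx <- cbind(match(m$sample, samples), match(m$group,
                                                 groupTable$groups$group))
    mat[idx] <- m$intensity
  }
  mat
}

#' Fill missed peaks from the spectra
#'
#' Each missing entry of the intensity matrix is filled with the maximal
#' (baseline-corrected) intensity within +-`halfWidth` ppm of the group's
#' consensus position in that sample's spectrum, floored at zero.
#'
#' @param mat Intensity matrix from [buildIntensityMatrix()] (columns named
#'   by ppm).
#' @param spectra The baseline-corrected [NMRSpectra-class].
#' @param halfWidth Search half-width in ppm (default 0.005).
#' @return The matrix with no missing entries; the pre-filling missingness
#'   mask is attached as attribute `"filled"`.
#' @export
fillPeaks <- function(mat, spectra, halfWidth = 0.005) {
  if (halfWidth <= 0) stop("halfWidth must be positive")
  axis <- ppmAxis(spectra)
  ints <- spectraIntensity(spectra)
  mask <- is.na(mat)
  ppmCols <- as.numeric(colnames(mat))
  for (j in which(colSums(mask) > 0)) {
    win <- which(abs(axis - ppmCols[j]) <= halfWidth)
    for (i in which(mask[, j])) {
      sm <- rownames(mat)[i]
      mat[i, j] <- if (length(win) && sm %in% colnames(ints))
        max(0, max(ints[win, sm])) else 0
    }
  }
  attr(mat, "filled") <- mask
  mat
}

#' Probabilistic quotient normalization
#'
#' Divides each sample's row by the median of its entry-wise quotients
#' against a reference spectrum (by default the column-wise median across
#' samples). Columns whose reference value is zero are excluded from the
#' quotient computation. The per-sample median quotient estimates the
#' sample's dilution.
#'
#' @param mat Non-negative intensity matrix, samples x peaks, no NAs.
#' @param reference "median" (default) or a numeric vector of length
#'   ncol(mat).
#' @return List: `normalized` (matrix), `factors` (named per-sample median
#'   quotients), `reference`.
#' @export
pqnNormalize <- function(mat, reference = "median") {
  if (any(is.na(mat))) stop("matrix must be complete (run fillPeaks first)")
  if (any(rowSums(mat) == 0)) stop("all-zero sample row")
  ref <- if (is.numeric(reference)) reference else
    apply(mat, 2, stats::median)
  use <- ref > 0
  if (!any(use)) stop("reference has no positive entries")
  q <- sweep(mat[, use, drop = FALSE], 2, ref[use], "/")
  factors <- apply(q, 1, stats::median)
  if (any(factors <= 0)) stop("non-positive quotient median")
  list(normalized = sweep(mat, 1, factors, "/"),
       factors = factors, reference = ref)
}

#' Integrate a spectrum over its axis
#'
#' Trapezoidal integral of intensity over ppm (absolute value of the axis
#' direction), per sample.
#'
#' @param spectra An [NMRSpectra-class].
#' @return Named numeric vector of integrals.
#' @export
integrateSpectra <- function(spectra) {
  x <- ppmAxis(spectra); y <- spectraIntensity(spectra)
  w <- abs(diff(x))
  apply(y, 2, function(v) sum(w * (v[-1] + v[-length(v)]) / 2))
}

#' Full spectral processing chain
#'
#' Baseline correction, wavelet peak detection, cross-sample grouping,
#' silhouette-gated regrouping, peak filling and probabilistic quotient
#' normalization, composed with the package defaults.
#'
#' @param spectra An [NMRSpectra-class].
#' @param baselineWindow,baselineQuantile,baselineStep Baseline parameters
#'   (points / quantile / points).
#' @param scales,minSNR Peak-detection parameters.
#' @param tolerance Grouping tolerance in ppm.
#' @param silhouetteThreshold Silhouette gate (default 0.6).
#' @param minGroupFraction Peak groups detected in fewer than this fraction
#'   of samples are discarded before matrix building (default 0.25);
#'   guards the quotient normalization against sporadic noise detections.
#' @param fillHalfWidth Peak-filling half-width in ppm.
#' @param baseline Apply baseline correction first (default TRUE).
#' @return List: `corrected` (NMRSpectra), `peaks`, `groupTable`,
#'   `matrixRaw` (with NAs), `matrix` (filled), `normalized`, `factors`,
#'   `reference`.
#' @export
processSpectra <- function(spectra, baselineWindow = 1000,
                           baselineQuantile = 0.1, baselineStep = 500,
                           scales = NULL, minSNR = 5, tolerance = 0.005,
                           silhouetteThreshold = 0.6,
                           minGroupFraction = 0.25,
                           fillHalfWidth = 0.005, baseline = TRUE) {
  corrected <- if (baseline)
    baselineCorrect(spectra, baselineWindow, baselineQuantile, baselineStep)
  else spectra
  peaks <- detectPeaksCWT(corrected, scales = scales, minSNR = minSNR)
  gt <- groupPeaks(peaks, tolerance)
  gt <- silhouetteFilter(gt, threshold = silhouetteThreshold,
                         tolerance = tolerance)
  samples <- colnames(spectraIntensity(spectra))
  minN <- ceiling(minGroupFraction * length(samples))
  if (minN > 1 && nrow(gt$groups)) {
    keep <- gt$groups$n >= minN
    dropped <- gt$groups$group[!keep]
    gt$unassigned <- rbind(gt$unassigned,
                           gt$members[gt$members$group %in% dropped,
                                      c("sample", "ppm", "intensity")])
    gt$members <- gt$members[!gt$members$group %in% dropped, ]
    gt$groups <- gt$groups[keep, ]
  }
  matRaw <- buildIntensityMatrix(gt, samples)
  mat <- fillPeaks(matRaw, corrected, fillHalfWidth)
  pqn <- pqnNormalize(mat)
  list(corrected = corrected, peaks = peaks, groupTable = gt,
       matrixRaw = matRaw, matrix = mat, normalized = pqn$normalized,
       factors = pqn$factors, reference = pqn$reference)
}
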