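#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' CountStudy: gene-level counts with group and model annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' `counts` assay (genes x samples, non-negative integers) together with the
#' per-sample experimental `group` (healthy / SHAM / DMT) and the rat `model`
#' (ZDF or ZDSD) in `colData`. Planted simulation truth, when present, lives
#' in `metadata(x)$truth`.
#'
#' @slot .Data inherited SummarizedExperiment internals.
#' @export
setClass("CountStudy", contains = "SummarizedExperiment")

.validCountStudy <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    k <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(k))) msg <- c(msg, "counts must not contain NA")
    else {
      if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(k != round(k))) msg <- c(msg, "counts must be integer-valued")
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) msg <- c(msg, "colData must have 'group'")
  else if (any(is.na(cd$group))) msg <- c(msg, "every sample needs a group")
  if (!"model" %in% colnames(cd)) msg <- c(msg, "colData must have 'model'")
  if (length(msg)) msg else TRUE
}
setValidity("CountStudy", .validCountStudy)

#' Construct a CountStudy
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param group Character/factor vector of per-sample groups
#'   (e.g. healthy, SHAM, DMT).
#' @param model Single string or per-sample vector naming the rat model
#'   (ZDF or ZDSD).
#' @param truth Optional list of planted simulation truth.
#' @return A [CountStudy-class] object.
#' @export
#' @examples
#' k <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cs <- CountStudy(k, group = rep(c("SHAM", "DMT"), each = 2), model = "ZDF")
#' sampleGroups(cs)
CountStudy <- function(counts, group, model, truth = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(model) == 1L) model <- rep(model, ncol(counts))
  cd <- S4Vectors::DataFrame(group = as.character(group),
                             model = as.character(model),
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  obj <- new("CountStudy", se)
  if (!is.null(truth)) metadata(obj)$truth <- truth
  validObject(obj)
  obj
}

#' DEGSet: a thresholded differentially-expressed gene set
#'
#' Genes passing the study's differential-expression gates
#' (absolute fold-change >= `fcThreshold`, adjusted p < `alpha`),
#' each with a direction of regulation.
#'
#' @slot gene Character vector of gene ids (unique).
#' @slot direction Character vector, "up" or "down", parallel to `gene`.
#' @slot contrast Single string labelling the contrast.
#' @slot fcThreshold Fold-change gate (linear scale).
#' @slot alpha Adjusted-p gate.
#' @export
setClass("DEGSet",
         representation(gene = "character", direction = "character",
                        contrast = "character", fcThreshold = "numeric",
                        alpha = "numeric"))

setValidity("DEGSet", function(object) {
  msg <- character()
  if (length(object@gene) != length(object@direction))
    msg <- c(msg, "gene and direction lengths differ")
  if (anyDuplicated(object@gene)) msg <- c(msg, "duplicate genes")
  if (length(object@direction) &&
      !all(object@direction %in% c("up", "down")))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' Construct a DEGSet
#'
#' @param gene Character vector of gene ids.
#' @param direction Parallel character vector, "up"/"down".
#' @param contrast Contrast label.
#' @param fcThreshold,alpha Thresholds the set was called at.
#' @return A [DEGSet-class].
#' @export
DEGSet <- function(gene, direction, contrast = "unspecified",
                   fcThreshold = 1.3, alpha = 0.05) {
  new("DEGSet", gene = as.character(gene), direction = as.character(direction),
      contrast = contrast, fcThreshold = fcThreshold, alpha = alpha)
}

#' NMRSpectra: a cohort of 1D NMR spectra on a shared ppm axis
#'
#' @slot ppm Strictly monotone numeric chemical-shift axis (ppm).
#' @slot intensity Numeric matrix, length(ppm) x n samples.
#' @slot sampleData DataFrame with at least `group`, rownames = sample ids.
#' @slot truth Planted simulation truth or NULL.
#' @export
setClass("NMRSpectra",
         representation(ppm = "numeric", intensity = "matrix",
                        sampleData = "DataFrame", truth = "listOrNULL"))

setValidity("NMRSpectra", function(object) {
  msg <- character()
  d <- diff(object@ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msg <- c(msg, "ppm axis must be strictly monotone")
  if (nrow(object@intensity) != length(object@ppm))
    msg <- c(msg, "intensity rows must match ppm length")
  if (any(is.na(object@intensity))) msg <- c(msg, "missing intensities")
  if (ncol(object@intensity) != nrow(object@sampleData))
    msg <- c(msg, "sampleData rows must match samples")
  if (!"group" %in% colnames(object@sampleData))
    msg <- c(msg, "sampleData must have 'group'")
  if (length(msg)) msg else TRUE
})

#' Construct an NMRSpectra object
#'
#' @param ppm Strictly monotone numeric axis.
#' @param intensity Matrix, points x samples (columns named by sample).
#' @param group Per-sample group labels.
#' @param truth Optional planted-truth list.
#' @return An [NMRSpectra-class].
#' @export
NMRSpectra <- function(ppm, intensity, group, truth = NULL) {
  intensity <- as.matrix(intensity)
  sd <- S4Vectors::DataFrame(group = as.character(group),
                             row.names = colnames(intensity))
  new("NMRSpectra", ppm = as.numeric(ppm), intensity = intensity,
      sampleData = sd, truth = truth)
}

#' RDCVResult: repeated double cross-validation classifier output
#'
#' @slot config List of the rdCV settings used.
#' @slot errorCurve data.frame: nVar, meanError (averaged inner curve).
#' @slot flavorCounts Named numeric: selected variable counts (min, mid, max).
#' @slot selectedVars Named list of selected variable ids per flavor.
#' @slot probabilities Named numeric: aggregated held-out probability of the
#'   positive class per sample (mean over repetitions).
#' @slot predicted Named character: class calls at the 50% threshold.
#' @slot yTrue Named character: actual classes.
#' @slot positiveClass Single string.
#' @slot misclassifications Integer count at the 50% threshold.
#' @slot auc Numeric AUC of aggregated probabilities.
#' @slot giniImportance Named numeric: mean decrease in Gini, averaged over
#'   repetitions (0 for never-selected variables).
#' @export
setClass("RDCVResult",
         representation(config = "list", errorCurve = "data.frame",
                        flavorCounts = "numeric", selectedVars = "list",
                        probabilities = "numeric", predicted = "character",
                        yTrue = "character", positiveClass = "character",
                        misclassifications = "integer", auc = "numeric",
                        giniImportance = "numeric"))

setValidity("RDCVResult", function(object) {
  msg <- character()
  p <- object@probabilities
  if (length(p) && (any(p < 0) || any(p > 1)))
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (length(object@giniImportance) && any(object@giniImportance < 0))
    msg <- c(msg, "Gini importances must be non-negative")
  if (object@misclassifications > length(object@yTrue))
    msg <- c(msg, "more misclassifications than samples")
  if (length(msg)) msg else TRUE
})

## ---- generics ----

#' @rdname CountStudy
#' @param x A CountStudy.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname CountStudy
#' @export
setMethod("sampleGroups", "CountStudy",
          function(x) setNames(colData(x)$group, colnames(x)))

#' @rdname CountStudy
#' @export
setGeneric("studyModel", function(x) standardGeneric("studyModel"))
#' @rdname CountStudy
#' @export
setMethod("studyModel", "CountStudy",
          function(x) unique(colData(x)$model))

#' Planted simulation truth stored on a simulated object
#'
#' @param x A CountStudy or NMRSpectra produced by a simulator.
#' @return The recorded truth list, or NULL for real data.
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "CountStudy", function(x) metadata(x)$truth)
#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "NMRSpectra", function(x) x@truth)

#' Gene ids in a DEGSet
#' @param x A DEGSet.
#' @export
setGeneric("degGenes", function(x) standardGeneric("degGenes"))
#' @rdname degGenes
#' @export
setMethod("degGenes", "DEGSet", function(x) x@gene)

#' Directions of a DEGSet, named by gene
#' @param x A DEGSet.
#' @export
setGeneric("degDirections", function(x) standardGeneric("degDirections"))
#' @rdname degDirections
#' @export
setMethod("degDirections", "DEGSet",
          function(x) setNames(x@direction, x@gene))

#' @export
setMethod("length", "DEGSet", function(x) length(x@gene))

#' ppm axis of an NMRSpectra object
#' @param x An NMRSpectra.
#' @export
setGeneric("ppmAxis", function(x) standardGeneric("ppmAxis"))
#' @rdname ppmAxis
#' @export
setMethod("ppmAxis", "NMRSpectra", function(x) x@ppm)

#' Intensity matrix (points x samples) of an NMRSpectra object
#' @param x An NMRSpectra.
#' @export
setGeneric("spectraIntensity", function(x) standardGeneric("spectraIntensity"))
#' @rdname spectraIntensity
#' @export
setMethod("spectraIntensity", "NMRSpectra", function(x) x@intensity)

#' Per-sample annotation of an NMRSpectra object
#' @param x An NMRSpectra.
#' @export
setGeneric("spectraSampleData", function(x) standardGeneric("spectraSampleData"))
#' @rdname spectraSampleData
#' @export
setMethod("spectraSampleData", "NMRSpectra", function(x) x@sampleData)

## ---- show methods ----

setMethod("show", "DEGSet", function(object) {
  cat("DEGSet:", length(object@gene), "genes (",
      sum(object@direction == "up"), "up /",
      sum(object@direction == "down"), "down )\n")
  cat("  contrast:", object@contrast, "\n")
  cat("  gates: |FC| >=", object@fcThreshold, ", padj <", object@alpha, "\n")
})

setMethod("show", "NMRSpectra", function(object) {
  cat("NMRSpectra:", ncol(object@intensity), "spectra,",
      length(object@ppm), "points, ppm",
      sprintf("%.2f..%.2f", object@ppm[1], object@ppm[length(object@ppm)]), "\n")
  print(table(object@sampleData$group))
})

setMethod("show", "RDCVResult", function(object) {
  cat("RDCVResult (", object@config$nRep, "repetitions x",
      object@config$nOuter, "outer segments )\n")
  cat("  selected variable counts:",
      paste(names(object@flavorCounts), object@flavorCounts,
            sep = "=", collapse = ", "), "\n")
  cat("  misclassifications:", object@misclassifications, "/",
      length(object@yTrue), "  AUC:", round(object@auc, 3), "\n")
})
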