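#' Average a cell x feature matrix by cell type
#'
#' Collapses a single-cell (or single-sample) expression matrix to an atlas
#' of per-type arithmetic means, with columns placed in the fixed tubule
#' ontology order where the labels match it.
#'
#' @param cellMatrix Numeric matrix, cells x features.
#' @param cellLabels Per-cell type labels (no NAs).
#' @return Matrix, features x cell types.
#' @export
averageExpressionByType <- function(cellMatrix, cellLabels) {
  cellMatrix <- as.matrix(cellMatrix)
  if (length(cellLabels) != nrow(cellMatrix))
    stop("one label per cell is required")
  if (any(is.na(cellLabels))) stop("unlabelled cells")
  sums <- rowsum(cellMatrix, group = cellLabels)
  means <- sums / as.vector(table(cellLabels)[rownames(sums)])
  atlas <- t(means)
  known <- intersect(tubuleCellTypes(), colnames(atlas))
  atlas[, c(known, setdiff(colnames(atlas), known)), drop = FALSE]
}

#' Localize features to tubule cell types by maximal abundance
#'
#' Assigns each feature present in the atlas to its argmax cell type and to
#' the proximal-tubule compartment iff that type is S1, S2 or S3. Ties are
#' broken by the first cell type in ontology order and flagged.
#'
#' @param features Character vector of feature ids.
#' @param atlas Matrix, features x cell types (ontology order respected).
#' @return data.frame: `feature`, `inAtlas`, `cellType`, `compartment`
#'   (proximal_tubule / rest_of_tubule), `tie`.
#' @export
localizeFeatures <- function(features, atlas) {
  ord <- intersect(tubuleCellTypes(), colnames(atlas))
  atlas <- atlas[, c(ord, setdiff(colnames(atlas), ord)), drop = FALSE]
  present <- features %in% rownames(atlas)
  out <- data.frame(feature = features, inAtlas = present,
                    cellType = NA_character_, compartment = NA_character_,
                    tie = NA)
  if (any(present)) {
    sub <- atlas[features[present], , drop = FALSE]
    rowMax <- apply(sub, 1, max)
    idx <- apply(sub, 1, which.max)          # first maximum in column order
    ties <- rowSums(sub == rowMax) > 1
    ct <- colnames(sub)[idx]
    out$cellType[present] <- ct
    out$compartment[present] <-
      ifelse(ct %in% proximalTubuleCellTypes(), "proximal_tubule",
             "rest_of_tubule")
    out$tie[present] <- ties
  }
  out
}

#' Stratify concordant DEGs by medication / PPAR responsiveness,
#' atlas presence and tubule compartment
#'
#' Reproduces the doughnut-plot logic: among a concordant DEG set, counts
#' genes responsive to at least one entity of a class (medications or PPAR
#' isotypes), the share responsive to the focal entity, the split of
#' responsive genes by presence in the cell-type atlas, and the
#' proximal-tubule vs rest-of-tubule split of atlas-present genes, reported
#' separately for focal-responsive and other-responsive genes. Percentages
#' are one-decimal, half away from zero; counts at each level sum to their
#' parent.
#'
#' @param concordant A [DEGSet-class].
#' @param network Target sets: a named list of character vectors, or the
#'   list returned by [simulateDrugNetworks()], or an edge data.frame with
#'   `entity`/`target` columns.
#' @param atlas Feature x cell-type matrix (or NULL to skip levels 2-3).
#' @param focalEntity Entity name, e.g. "fenofibrate" or "PPARA".
#' @param entities Entities forming the class; defaults to all in `network`.
#' @return Nested list of class `StratificationSummary`.
#' @export
stratifyByResponsiveness <- function(concordant, network, atlas = NULL,
                                     focalEntity, entities = NULL) {
  sets <- .asTargetSets(network)
  entities <- entities %||% names(sets)
  if (!focalEntity %in% entities)
    stop("focal entity not among the network entities")
  sets <- sets[entities]
  genes <- degGenes(concordant)

  responsive <- genes[genes %in% unique(unlist(sets))]
  focal <- responsive[responsive %in% sets[[focalEntity]]]
  other <- setdiff(responsive, focal)

  pct <- function(k, n) if (n > 0) roundHalfUp(100 * k / n, 1) else 0.0

  summarizeCompartment <- function(g) {
    if (is.null(atlas))
      return(list(present = NA_integer_, absent = NA_integer_))
    loc <- localizeFeatures(g, atlas)
    present <- loc$feature[loc$inAtlas]
    ptN <- sum(loc$compartment == "proximal_tubule", na.rm = TRUE)
    list(present = length(present), absent = sum(!loc$inAtlas),
         proximalTubule = ptN, restOfTubule = length(present) - ptN,
         proximalTubulePct = pct(ptN, length(present)))
  }

  structure(list(
    total = length(genes),
    responsiveAny = length(responsive),
    responsiveAnyPct = pct(length(responsive), length(genes)),
    focalEntity = focalEntity,
    focal = list(count = length(focal),
                 pctOfResponsive = pct(length(focal), length(responsive))),
    other = list(count = length(other),
                 pctOfResponsive = pct(length(other), length(responsive))),
    focalAtlas = summarizeCompartment(focal),
    otherAtlas = summarizeCompartment(other),
    genes = list(responsive = responsive, focal = focal, other = other)),
    class = "StratificationSummary")
}

.asTargetSets <- function(network) {
  if (is.data.frame(network)) {
    stopifnot(all(c("entity", "target") %in% names(network)))
    return(split(network$target, network$entity))
  }
  if (is.list(network) && !is.null(network$targetSets))
    return(network$targetSets)
  if (is.list(network) && !is.null(names(network))) return(network)
  stop("cannot interpret 'network' as target sets")
}

#' @export
print.StratificationSummary <- function(x, ...) {
  cat("StratificationSummary (focal:", x$focalEntity, ")\n")
  cat("  concordant DEGs:", x$total, "\n")
  cat("  responsive to >=1 entity:", x$responsiveAny,
      sprintf("(%.1f%%)", x$responsiveAnyPct), "\n")
  cat("  focal-responsive:", x$focal$count,
      sprintf("(%.1f%% of responsive)", x$focal$pctOfResponsive), "\n")
  if (!is.na(x$focalAtlas$present))
    cat("  focal in atlas:", x$focalAtlas$present, "; PT share",
        sprintf("%.1f%%", x$focalAtlas$proximalTubulePct), "\n")
  invisible(x)
}

#' Multi-way set overlap (Venn region counts)
#'
#' Enumerates every membership pattern of 2-8 named sets and counts the
#' elements falling in each exclusive region; region counts sum to the size
#' of the union.
#'
#' @param sets Named list of 2-8 character vectors.
#' @return data.frame: one row per non-empty-pattern combination with
#'   logical membership columns, a `pattern` label and `count`.
#' @export
multiwayOverlap <- function(sets) {
  m <- length(sets)
  if (m < 2 || m > 8) stop("between 2 and 8 sets are supported")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(m))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(sets)))
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  names(pat) <- names(sets)
  pat <- pat[rowSums(pat) > 0, , drop = FALSE]
  pat$pattern <- apply(pat, 1, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  key <- apply(member, 1, paste, collapse = ".")
  patKey <- apply(pat[, names(sets), drop = FALSE], 1, paste, collapse = ".")
  pat$count <- as.integer(table(factor(key, levels = patKey)))
  rownames(pat) <- NULL
  pat
}

#' Percentage of a known target set hit by a DEG list
#'
#' @param degs Character vector (or [DEGSet-class]) of differential genes.
#' @param targets Non-empty character vector of known targets.
#' @return One-decimal percentage, 100 * |degs intersect targets|/|targets|.
#' @export
fractionOfKnownTargets <- function(degs, targets) {
  if (is(degs, "DEGSet")) degs <- degGenes(degs)
  targets <- unique(targets)
  if (!length(targets)) stop("empty target set")
  roundHalfUp(100 * length(intersect(degs, targets)) / length(targets), 1)
}
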