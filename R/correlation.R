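#' Pearson correlation matrix of a per-animal feature table
#'
#' Product-moment correlations between typed features (structure,
#' transcript, metabolite) measured on the same animals. Constant columns
#' cannot be correlated and are dropped with a warning.
#'
#' @param table Numeric matrix or data.frame, animals x features.
#' @param types Optional named character vector tagging each feature
#'   (structure / transcript / metabolite); carried into the result as an
#'   attribute.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(table, types = NULL) {
  x <- as.matrix(table)
  if (nrow(x) < 3) stop("need >= 3 animals for correlation")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(x)
  if (!is.null(types)) attr(r, "types") <- types[colnames(r)]
  r
}

#' Threshold a correlation matrix into a network
#'
#' Keeps edges with |r| >= `minAbsR` (boundary inclusive); nodes are all
#' features, with those left without any retained edge flagged as isolated.
#'
#' @param r Symmetric correlation matrix, or a long data.frame with
#'   `from`, `to`, `r` columns.
#' @param minAbsR Absolute-correlation threshold (default 0.5).
#' @param types Optional named type tags for the nodes.
#' @return List of class `CorrelationNetwork`: `edges` (from, to, r),
#'   `nodes` (feature, type, isolated).
#' @export
thresholdNetwork <- function(r, minAbsR = 0.5, types = NULL) {
  if (is.data.frame(r)) {
    stopifnot(all(c("from", "to", "r") %in% names(r)))
    long <- r[r$from != r$to, ]
    feats <- unique(c(long$from, long$to))
  } else {
    feats <- colnames(r)
    idx <- which(upper.tri(r), arr.ind = TRUE)
    long <- data.frame(from = feats[idx[, 1]], to = feats[idx[, 2]],
                       r = r[idx])
  }
  edges <- long[abs(long$r) >= minAbsR, , drop = FALSE]
  rownames(edges) <- NULL
  connected <- unique(c(edges$from, edges$to))
  nodes <- data.frame(feature = feats,
                      type = if (is.null(types)) NA_character_ else
                        unname(types[feats]),
                      isolated = !feats %in% connected)
  structure(list(edges = edges, nodes = nodes, minAbsR = minAbsR),
            class = "CorrelationNetwork")
}

#' @export
print.CorrelationNetwork <- function(x, ...) {
  cat("CorrelationNetwork:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges at |r| >=", x$minAbsR,
      "(", sum(x$nodes$isolated), "isolated )\n")
  invisible(x)
}

#' Multidimensional-scaling layout and clustering of correlated features
#'
#' Classical (Torgerson) MDS of the distance d = 1 - r to two dimensions
#' (the signed distance keeps anti-correlated features apart), followed by
#' complete-linkage hierarchical clustering of the embedding cut at
#' `kClusters`.
#'
#' @param r Symmetric correlation matrix.
#' @param kClusters Number of clusters.
#' @return List: `coordinates` (features x 2), `cluster` (named integer
#'   labels).
#' @export
mdsCluster <- function(r, kClusters = 2) {
  n <- ncol(r)
  if (n < 2) stop("need >= 2 features")
  if (kClusters > n) stop("more clusters than features")
  d <- 1 - r
  coords <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(coords) < 2)
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  dimnames(coords) <- list(colnames(r), c("dim1", "dim2"))
  cl <- stats::cutree(stats::hclust(stats::dist(coords), "complete"),
                      k = kClusters)
  list(coordinates = coords, cluster = setNames(cl, colnames(r)))
}
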