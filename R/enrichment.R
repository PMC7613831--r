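#' Hypergeometric over-representation analysis
#'
#' Tests each gene set in a collection for over-representation of a query
#' set against a universe: p = P(X >= k) for X hypergeometric with the
#' universe size N, set size K and query size n, BH-adjusted across sets.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of gene ids.
#' @param collection Named list of character vectors (the gene sets).
#' @param universe Character vector; defaults to the union of the collection
#'   (the recommended choice is all genes tested for differential
#'   expression).
#' @return data.frame per set: `set`, `overlap` (k), `setSize` (K),
#'   `querySize` (n), `universeSize` (N), `pvalue`, `padj`,
#'   `genes` (comma-separated overlap), ordered by p.
#' @export
oraTest <- function(query, collection, universe = NULL) {
  if (!length(query)) stop("empty query")
  if (!length(collection) || is.null(names(collection)))
    stop("collection must be a named list of gene sets")
  universe <- universe %||% unique(unlist(collection))
  bad <- setdiff(query, universe)
  if (length(bad)) {
    warning(length(bad), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(unique(universe)); n <- length(unique(query))
  res <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    hits <- intersect(query, set)
    k <- length(hits); K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, setSize = K, querySize = n,
               universeSize = N, pvalue = p,
               genes = paste(sort(hits), collapse = ","))
  }))
  res$padj <- adjustBH(res$pvalue)
  res[order(res$pvalue, res$set),
      c("set", "overlap", "setSize", "querySize", "universeSize",
        "pvalue", "padj", "genes")]
}

#' Per-query over-representation across several gene lists
#'
#' Runs [oraTest()] for each named query and stacks the results in long
#' format with a `query` column; BH adjustment is within query.
#'
#' @param queries Named list of character vectors.
#' @param collection Named list of gene sets.
#' @param universe Optional universe shared by all queries.
#' @return Long-format data.frame of the per-query ORA results.
#' @export
compareClusters <- function(queries, collection, universe = NULL) {
  if (!length(queries)) stop("need >= 1 query")
  out <- lapply(names(queries), function(q) {
    r <- oraTest(queries[[q]], collection, universe)
    cbind(query = q, r)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Upstream-regulator activation score
#'
#' For each regulator, overlaps its signed target edges with a DEG set and
#' scores directional consistency: z = (n_consistent - n_inconsistent) /
#' sqrt(n) over the n overlapping targets, where a target is consistent when
#' its DEG direction matches the expected sign of regulation. A regulator is
#' called activated at z >= 2, inhibited at z <= -2, otherwise undetermined;
#' regulators with no overlapping targets get a missing z.
#'
#' @param edges data.frame with columns `regulator` (or `entity`), `target`,
#'   `sign` (+1 / -1 expected direction under activation).
#' @param degs A [DEGSet-class].
#' @return data.frame: `regulator`, `nTargets` (overlap size), `z`, `state`.
#' @export
#' @examples
#' e <- data.frame(regulator = "PPARA", target = paste0("g", 1:9), sign = 1)
#' d <- DEGSet(paste0("g", 1:9), rep("up", 9))
#' regulatorActivation(e, d)  # z = 3, activated
regulatorActivation <- function(edges, degs) {
  if (!"regulator" %in% names(edges) && "entity" %in% names(edges))
    names(edges)[names(edges) == "entity"] <- "regulator"
  stopifnot(all(c("regulator", "target", "sign") %in% names(edges)))
  if (!all(edges$sign %in% c(-1, 1)))
    stop("expected sign must be +1 or -1")
  dir <- degDirections(degs)
  dirSign <- ifelse(dir == "up", 1L, -1L)
  out <- lapply(split(edges, edges$regulator), function(e) {
    hit <- e$target %in% names(dirSign)
    n <- sum(hit)
    if (n == 0)
      return(data.frame(regulator = e$regulator[1], nTargets = 0L,
                        z = NA_real_, state = "undetermined"))
    consistent <- dirSign[e$target[hit]] == e$sign[hit]
    z <- (sum(consistent) - sum(!consistent)) / sqrt(n)
    state <- if (z >= 2) "activated" else if (z <= -2) "inhibited" else
      "undetermined"
    data.frame(regulator = e$regulator[1], nTargets = n, z = z,
               state = state)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
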