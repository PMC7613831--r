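#' Read / write the package's plain-text interchange formats
#'
#' Counts and atlases travel as TSV (features in rows, header of sample or
#' cell-type ids), sample metadata as TSV (sample_id, group, model), target
#' networks as 3-column TSV (source, target, expected_sign), spectra as wide
#' CSV (first column ppm, one column per sample), intensity matrices as CSV
#' (samples x ppm-labelled peaks), gene-set collections as GMT.
#'
#' @param path File path.
#' @name renomix-io
NULL

#' @rdname renomix-io
#' @param study A [CountStudy-class].
#' @export
writeCountsTSV <- function(study, path) {
  k <- assay(study, "counts")
  utils::write.table(data.frame(gene = rownames(k), k, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname renomix-io
#' @export
writeMetadataTSV <- function(study, path) {
  cd <- as.data.frame(colData(study))
  utils::write.table(data.frame(sample_id = rownames(cd),
                                group = cd$group, model = cd$model),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname renomix-io
#' @param metadataPath Metadata TSV matching the counts.
#' @export
readCountsTSV <- function(path, metadataPath) {
  d <- utils::read.delim(path, check.names = FALSE)
  k <- as.matrix(d[, -1, drop = FALSE])
  rownames(k) <- d[[1]]
  md <- utils::read.delim(metadataPath)
  md <- md[match(colnames(k), md$sample_id), ]
  CountStudy(k, group = md$group, model = md$model)
}

#' @rdname renomix-io
#' @param atlas Feature x cell-type matrix.
#' @export
writeAtlasTSV <- function(atlas, path) {
  utils::write.table(data.frame(feature = rownames(atlas), atlas,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname renomix-io
#' @export
readAtlasTSV <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  ord <- intersect(tubuleCellTypes(), colnames(m))
  m[, c(ord, setdiff(colnames(m), ord)), drop = FALSE]
}

#' @rdname renomix-io
#' @param edges data.frame entity/target/sign.
#' @export
writeEdgesTSV <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname renomix-io
#' @export
readEdgesTSV <- function(path) utils::read.delim(path)

#' @rdname renomix-io
#' @param spectra An [NMRSpectra-class].
#' @export
writeSpectraCSV <- function(spectra, path) {
  utils::write.csv(data.frame(ppm = ppmAxis(spectra),
                              spectraIntensity(spectra),
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname renomix-io
#' @param group Per-sample groups for the spectra being read.
#' @export
readSpectraCSV <- function(path, group) {
  d <- utils::read.csv(path, check.names = FALSE)
  NMRSpectra(d$ppm, as.matrix(d[, -1, drop = FALSE]), group = group)
}

#' @rdname renomix-io
#' @param mat Samples x peaks intensity matrix.
#' @export
writeIntensityCSV <- function(mat, path) {
  utils::write.csv(data.frame(sample = rownames(mat), mat,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname renomix-io
#' @export
readIntensityCSV <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' @rdname renomix-io
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' @rdname renomix-io
#' @param collection Named list of gene sets.
#' @export
writeGMT <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, nm, collection[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
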