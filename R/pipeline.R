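#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end synthetic analysis: which
#' stages run, where outputs go, and every stage parameter (thresholds,
#' spectral-processing settings, classifier settings, correlation gates).
#'
#' @param seed Global seed; forwarded to every stochastic stage.
#' @param outdir Output directory (created if absent).
#' @param stages Character vector of enabled stages, in dependency order
#'   among `simulate`, `de`, `enrich`, `deconv`, `nmr`, `classify`,
#'   `measures`, `correlate`.
#' @param study A [syntheticStudyConfig()]; defaults to one built from
#'   `seed`.
#' @param fcThreshold,alpha Differential-expression gates (1.3, 0.05).
#' @param silhouetteThreshold Peak-grouping gate (0.6).
#' @param minAbsR Correlation-network gate (0.5).
#' @param kClusters MDS cluster count (2).
#' @param baselineWindow,baselineQuantile,baselineStep Baseline parameters.
#' @param groupingTolerance Peak-grouping tolerance in ppm.
#' @param classifyNOuter,classifyNRep,classifyVarRatio,classifyNTree
#'   rdCV classifier settings; repetitions default to 5 here to keep the
#'   orchestrated run light (the classifier itself defaults to 100).
#' @param classifyGroups Character pair of NMR groups to classify.
#' @return List of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 101, outdir = tempfile("renomix_run_"),
                           stages = c("simulate", "de", "enrich", "deconv",
                                      "nmr", "classify", "measures",
                                      "correlate"),
                           study = NULL,
                           fcThreshold = 1.3, alpha = 0.05,
                           silhouetteThreshold = 0.6, minAbsR = 0.5,
                           kClusters = 2,
                           baselineWindow = 1000, baselineQuantile = 0.1,
                           baselineStep = 500, groupingTolerance = 0.005,
                           classifyNOuter = 5, classifyNRep = 5,
                           classifyVarRatio = 0.85, classifyNTree = 100,
                           classifyGroups = c("healthy",
                                              "untreated_severe")) {
  known <- c("simulate", "de", "enrich", "deconv", "nmr", "classify",
             "measures", "correlate")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(seed = seed, outdir = outdir, stages = stages,
                 study = study %||% syntheticStudyConfig(seed = seed),
                 fcThreshold = fcThreshold, alpha = alpha,
                 silhouetteThreshold = silhouetteThreshold,
                 minAbsR = minAbsR, kClusters = kClusters,
                 baselineWindow = baselineWindow,
                 baselineQuantile = baselineQuantile,
                 baselineStep = baselineStep,
                 groupingTolerance = groupingTolerance,
                 classifyNOuter = classifyNOuter,
                 classifyNRep = classifyNRep,
                 classifyVarRatio = classifyVarRatio,
                 classifyNTree = classifyNTree,
                 classifyGroups = classifyGroups),
            class = "pipelineConfig")
}

#' Run the end-to-end synthetic analysis
#'
#' Executes the enabled stages in dependency order — simulate the study
#' inputs, differential expression with cross-model concordance and
#' corrected fractions, over-representation and regulator activation,
#' cell-type / drug-network stratification, NMR spectral processing, rdCV
#' classification, morphometric endpoints, and the structure-transcript-
#' metabolite correlation network — writing stage outputs under
#' `config$outdir` and a JSON manifest (parameters, seed, per-file MD5
#' checksums). Re-running with the same config and seed reproduces
#' identical outputs.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with `manifest` and in-memory `results` per
#'   stage.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  on <- function(s) s %in% config$stages
  res <- list()
  manifest <- list(seed = config$seed, stages = list())
  outfile <- function(...) file.path(config$outdir, paste0(...))
  record <- function(stage, files, params = list()) {
    manifest$stages[[stage]] <<- list(
      status = "complete", parameters = params,
      outputs = as.list(unname(tools::md5sum(files))) |>
        setNames(basename(files)))
  }

  if (on("simulate")) {
    sc <- config$study
    res$zdf <- simulateCountStudy(sc, "ZDF")
    res$zdsd <- simulateCountStudy(sc, "ZDSD")
    res$atlas <- simulateAtlas(sc)
    res$networks <- simulateDrugNetworks(sc)
    res$spectra <- simulateNMRCohort(sc)
    res$morpho <- simulateMorphometry(sc)
    res$collection <- withSeed(sc$seed + 71L, {
      sets <- list(fatty_acid_oxidation = sc$faoGenes,
                   fibrosis_ecm = sc$fibrosisGenes)
      for (i in 1:8) sets[[sprintf("random_set_%02d", i)]] <-
          sample(sc$genes, 100)
      sets
    })
    files <- c(writeCountsTSV(res$zdf, outfile("counts_zdf.tsv")),
               writeMetadataTSV(res$zdf, outfile("metadata_zdf.tsv")),
               writeCountsTSV(res$zdsd, outfile("counts_zdsd.tsv")),
               writeMetadataTSV(res$zdsd, outfile("metadata_zdsd.tsv")),
               writeAtlasTSV(res$atlas$atlas, outfile("atlas.tsv")),
               writeEdgesTSV(res$networks$edges,
                             outfile("drug_networks.tsv")),
               writeSpectraCSV(res$spectra, outfile("spectra.csv")),
               writeGMT(res$collection, outfile("gene_sets.gmt")))
    utils::write.csv(res$morpho$measurements,
                     outfile("morphometry.csv"), row.names = FALSE)
    jsonlite::write_json(plantedTruth(res$zdsd)$genes,
                         outfile("truth_genes.json"))
    record("simulate", c(files, outfile("morphometry.csv"),
                         outfile("truth_genes.json")),
           list(seed = config$seed))
  }

  if (on("de")) {
    if (is.null(res$zdf)) stop("de stage requires simulated counts; ",
                               "enable the simulate stage")
    deOne <- function(study) {
      sf <- estimateSizeFactors(study)
      disp <- estimateDispersions(study, sf)
      list(sf = sf,
           treat = waldTest(study, c("DMT", "SHAM"), sf, disp),
           disease = waldTest(study, c("SHAM", "healthy"), sf, disp),
           rlog = rlogLikeTransform(study, sf))
    }
    res$deZdf <- deOne(res$zdf)
    res$deZdsd <- deOne(res$zdsd)
    call <- function(de) callDEGs(de, config$fcThreshold, config$alpha)
    res$degs <- list(
      zdfTreat = call(res$deZdf$treat), zdfDisease = call(res$deZdf$disease),
      zdsdTreat = call(res$deZdsd$treat),
      zdsdDisease = call(res$deZdsd$disease))
    res$concordant <- concordantDEGs(res$degs$zdfTreat,
                                     res$degs$zdsdTreat)
    res$corrected <- list(
      zdf = correctedFraction(res$degs$zdfDisease, res$degs$zdfTreat),
      zdsd = correctedFraction(res$degs$zdsdDisease, res$degs$zdsdTreat))
    f1 <- outfile("de_zdf_dmt_vs_sham.tsv")
    f2 <- outfile("de_zdsd_dmt_vs_sham.tsv")
    utils::write.table(res$deZdf$treat, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(res$deZdsd$treat, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(concordant = degGenes(res$concordant),
           corrected = res$corrected[c("zdf", "zdsd")] |>
             lapply(function(x) x[c("count", "total", "percentage")])),
      outfile("degs.json"), auto_unbox = TRUE)
    record("de", c(f1, f2, outfile("degs.json")),
           list(fcThreshold = config$fcThreshold, alpha = config$alpha))
  }

  if (on("enrich")) {
    if (is.null(res$concordant)) stop("enrich stage requires DE results; ",
                                      "enable the de stage")
    res$ora <- oraTest(degGenes(res$concordant), res$collection,
                       universe = config$study$genes)
    pparEdges <- res$networks$edges[
      res$networks$edges$entity %in% c("PPARA", "PPARD", "PPARG"), ]
    res$regulators <- regulatorActivation(pparEdges, res$concordant)
    f <- outfile("enrichment.tsv")
    utils::write.table(res$ora, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- outfile("regulators.tsv")
    utils::write.table(res$regulators, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("enrich", c(f, f2))
  }

  if (on("deconv")) {
    if (is.null(res$concordant)) stop("deconv stage requires DE results; ",
                                      "enable the de stage")
    drugs <- c("fenofibrate", "liraglutide", "metformin", "ramipril",
               "rosuvastatin")
    isotypes <- c("PPARA", "PPARD", "PPARG")
    res$stratDrug <- stratifyByResponsiveness(
      res$concordant, res$networks, res$atlas$atlas, "fenofibrate", drugs)
    res$stratIso <- stratifyByResponsiveness(
      res$concordant, res$networks, res$atlas$atlas, "PPARA", isotypes)
    res$venn <- multiwayOverlap(lapply(
      res$networks$targetSets[drugs],
      function(s) intersect(s, degGenes(res$concordant))))
    res$localization <- localizeFeatures(degGenes(res$concordant),
                                         res$atlas$atlas)
    f <- outfile("localization.tsv")
    utils::write.table(res$localization, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- outfile("stratification.json")
    jsonlite::write_json(
      lapply(list(drug = res$stratDrug, isotype = res$stratIso),
             function(s) s[setdiff(names(s), "genes")]),
      f2, auto_unbox = TRUE)
    f3 <- outfile("venn.tsv")
    utils::write.table(res$venn, f3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("deconv", c(f, f2, f3))
  }

  if (on("nmr")) {
    if (is.null(res$spectra)) stop("nmr stage requires simulated spectra; ",
                                   "enable the simulate stage")
    res$nmr <- processSpectra(
      res$spectra, baselineWindow = config$baselineWindow,
      baselineQuantile = config$baselineQuantile,
      baselineStep = config$baselineStep,
      tolerance = config$groupingTolerance,
      silhouetteThreshold = config$silhouetteThreshold)
    f <- writeIntensityCSV(res$nmr$normalized,
                           outfile("intensity_normalized.csv"))
    f2 <- outfile("pqn_factors.tsv")
    utils::write.table(
      data.frame(sample = names(res$nmr$factors),
                 factor = res$nmr$factors),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    record("nmr", c(f, f2),
           list(window = config$baselineWindow,
                quantile = config$baselineQuantile,
                step = config$baselineStep,
                silhouette = config$silhouetteThreshold))
  }

  if (on("classify")) {
    if (is.null(res$nmr))
      stop("classify stage requires the NMR intensity matrix; ",
           "enable the nmr stage")
    grp <- spectraSampleData(res$spectra)$group
    sel <- grp %in% config$classifyGroups
    res$rdcv <- fitRDCV(res$nmr$normalized[sel, , drop = FALSE],
                        factor(grp[sel], levels = config$classifyGroups),
                        nOuter = config$classifyNOuter,
                        nRep = config$classifyNRep,
                        varRatio = config$classifyVarRatio,
                        nTree = config$classifyNTree,
                        seed = config$seed)
    f <- outfile("rdcv_ranking.tsv")
    utils::write.table(rankVariables(res$rdcv), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    f2 <- outfile("rdcv_probabilities.tsv")
    utils::write.table(
      data.frame(sample = names(res$rdcv@probabilities),
                 probability = res$rdcv@probabilities,
                 actual = res$rdcv@yTrue, predicted = res$rdcv@predicted),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auc = res$rdcv@auc,
           misclassifications = res$rdcv@misclassifications,
           flavorCounts = as.list(res$rdcv@flavorCounts)),
      outfile("rdcv_summary.json"), auto_unbox = TRUE)
    record("classify", c(f, f2, outfile("rdcv_summary.json")),
           list(nOuter = config$classifyNOuter, nRep = config$classifyNRep,
                varRatio = config$classifyVarRatio))
  }

  if (on("measures")) {
    if (is.null(res$morpho)) stop("measures stage requires morphometry; ",
                                  "enable the simulate stage")
    m <- res$morpho$measurements
    m$glom_volume_um3 <- glomerularVolume(m$glom_area_um2)
    m$pfpd_nm <- pfpdFromPfpf(m$pfpf_per8um)
    m$mito_roundness_check <- roundness(m$mito_area_um2, m$mito_major_um)
    m$mito_aspect_ratio <- m$mito_major_um / m$mito_minor_um
    res$endpoints <- m
    f <- outfile("morphometric_endpoints.csv")
    utils::write.csv(m, f, row.names = FALSE)
    record("measures", f)
  }

  if (on("correlate")) {
    need <- c("deZdsd", "nmr", "endpoints")
    if (!all(need %in% names(res)))
      stop("correlate stage requires de, nmr and measures outputs")
    res$featureTable <- .buildFeatureTable(res, config)
    r <- pearsonMatrix(res$featureTable$values,
                       types = res$featureTable$types)
    res$network <- thresholdNetwork(r, config$minAbsR,
                                    res$featureTable$types)
    res$mds <- mdsCluster(r, config$kClusters)
    f <- outfile("network_edges.tsv")
    utils::write.table(res$network$edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nodes <- res$network$nodes
    nodes$dim1 <- res$mds$coordinates[nodes$feature, 1]
    nodes$dim2 <- res$mds$coordinates[nodes$feature, 2]
    nodes$cluster <- res$mds$cluster[nodes$feature]
    f2 <- outfile("network_nodes.tsv")
    utils::write.table(nodes, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("correlate", c(f, f2),
           list(minAbsR = config$minAbsR, kClusters = config$kClusters))
  }

  manifestPath <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(manifest = manifest, results = res,
                 manifestPath = manifestPath))
}

## per-animal feature table aligning transcripts (ZDSD rlog), urinary
## metabolite peaks and morphometric endpoints by group, truncated to the
## common per-group sample count across the three sources
.buildFeatureTable <- function(res, config) {
  sc <- config$study
  groupsMap <- c(healthy = "healthy", SHAM = "untreated_severe",
                 DMT = "DMT")
  rl <- res$deZdsd$rlog
  studyGroups <- sampleGroups(res$zdsd)
  nmrGroups <- spectraSampleData(res$spectra)$group
  morpho <- res$endpoints

  faoSel <- utils::head(sc$faoGenes, 8)
  fibSel <- utils::head(sc$fibrosisGenes, 4)

  ## match normalized peak columns to planted family peaks
  peaks <- plantedTruth(res$spectra)$peaks
  colsPpm <- as.numeric(colnames(res$nmr$normalized))
  matchPeak <- function(fam) {
    pp <- peaks$ppm[peaks$family == fam]
    idx <- vapply(pp, function(x) {
      j <- which.min(abs(colsPpm - x))
      if (abs(colsPpm[j] - x) <= 0.02) j else NA_integer_
    }, integer(1))
    unique(idx[!is.na(idx)])
  }
  nicoIdx <- matchPeak("nicotinamide")
  clearIdx <- matchPeak("clearance")
  tcaIdx <- matchPeak("tca")

  blocks <- lapply(names(groupsMap), function(g) {
    sIdx <- which(studyGroups == g)
    nIdx <- which(nmrGroups == groupsMap[[g]])
    mIdx <- which(morpho$group == g)
    n <- min(length(sIdx), length(nIdx), length(mIdx))
    cbind(
      t(rl[c(faoSel, fibSel), sIdx[seq_len(n)], drop = FALSE]),
      res$nmr$normalized[nIdx[seq_len(n)],
                         c(nicoIdx, clearIdx, tcaIdx), drop = FALSE],
      as.matrix(morpho[mIdx[seq_len(n)],
                       c("mito_roundness", "glom_volume_um3", "gbm_nm")]))
  })
  values <- do.call(rbind, blocks)
  metaboliteNames <- c(paste0("nico_", sprintf("%.2f", colsPpm[nicoIdx])),
                       paste0("clear_", sprintf("%.2f", colsPpm[clearIdx])),
                       paste0("tca_", sprintf("%.2f", colsPpm[tcaIdx])))
  colnames(values) <- c(faoSel, fibSel, metaboliteNames,
                        "mito_roundness", "glom_volume_um3", "gbm_nm")
  rownames(values) <- paste0("animal_", seq_len(nrow(values)))
  types <- c(rep("transcript", length(faoSel) + length(fibSel)),
             rep("metabolite", length(metaboliteNames)),
             rep("structure", 3))
  names(types) <- colnames(values)
  list(values = values, types = types,
       faoFeatures = faoSel,
       nicoFeatures = metaboliteNames[seq_along(nicoIdx)],
       roundnessFeature = "mito_roundness")
}

#' Validate declared pipeline input files
#'
#' Schema checks for the plain-text interchange files: duplicate feature or
#' sample ids, non-integer or negative counts, missing metadata groups,
#' atlas ontology columns, non-monotone ppm axes, malformed network edge
#' lists. Report-only: problems are collected, not thrown.
#'
#' @param paths Named list of file paths; recognized names are `counts`
#'   (with `metadata`), `atlas`, `edges`, `spectra`.
#' @return List: `errors`, `warnings`, `summary` (feature/sample counts per
#'   file).
#' @export
validateInputs <- function(paths) {
  errors <- character(); warnings <- character(); summary <- list()
  if (!is.null(paths$counts)) {
    d <- utils::read.delim(paths$counts, check.names = FALSE)
    ids <- d[[1]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
      errors <- c(errors, paste0("counts: duplicate gene id(s): ",
                                 paste(unique(dup), collapse = ", ")))
    k <- as.matrix(d[, -1, drop = FALSE])
    if (any(k < 0)) errors <- c(errors, "counts: negative values")
    if (any(k != round(k))) errors <- c(errors, "counts: non-integer values")
    summary$counts <- c(genes = nrow(d), samples = ncol(d) - 1L)
    if (!is.null(paths$metadata)) {
      md <- utils::read.delim(paths$metadata)
      if (!all(c("sample_id", "group") %in% names(md)))
        errors <- c(errors, "metadata: needs sample_id and group columns")
      else if (!setequal(md$sample_id, colnames(d)[-1]))
        errors <- c(errors, "metadata: sample ids do not match counts")
    }
  }
  if (!is.null(paths$atlas)) {
    a <- utils::read.delim(paths$atlas, check.names = FALSE)
    missing <- setdiff(tubuleCellTypes(), colnames(a))
    if (length(missing))
      errors <- c(errors, paste0("atlas: missing cell type column(s): ",
                                 paste(missing, collapse = ", ")))
    if (any(as.matrix(a[, -1]) < 0))
      errors <- c(errors, "atlas: negative abundances")
    summary$atlas <- c(features = nrow(a))
  }
  if (!is.null(paths$edges)) {
    e <- utils::read.delim(paths$edges)
    if (!all(c("entity", "target") %in% names(e)))
      errors <- c(errors, "edges: needs entity and target columns")
    summary$edges <- c(edges = nrow(e))
  }
  if (!is.null(paths$spectra)) {
    s <- utils::read.csv(paths$spectra, check.names = FALSE)
    d <- diff(s$ppm)
    if (!(all(d > 0) || all(d < 0)))
      errors <- c(errors, "spectra: ppm axis is not strictly monotone")
    if (any(is.na(as.matrix(s[, -1]))))
      errors <- c(errors, "spectra: missing intensities")
    summary$spectra <- c(points = nrow(s), samples = ncol(s) - 1L)
  }
  list(errors = errors, warnings = warnings, summary = summary)
}
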