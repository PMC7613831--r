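#' Configuration for the synthetic multi-omic study
#'
#' Bundles every tunable of the synthetic-data generators: two three-group
#' count studies (healthy / SHAM / DMT) with a planted treatment-induced
#' fatty-acid-oxidation (FAO) module and a disease-induced fibrosis module,
#' a 14-cell-type tubule abundance atlas with proximal-tubule-enriched
#' planted genes, drug / PPAR-isotype target networks with configurable
#' overlaps, a 1H-NMR cohort with planted metabolite families, and
#' per-animal morphometry tables. Defaults define the package's reference
#' study conditions; every generated feature carries a recorded truth.
#'
#' @param seed Integer master seed; all generators derive from it.
#' @param nPerGroup Named integer vector: samples per group for the count
#'   studies (healthy, SHAM, DMT).
#' @param nGenes Number of genes in the count studies.
#' @param nFaoGenes,faoLog2FC Size of the FAO module and its planted
#'   DMT-vs-SHAM log2 effect. The module is additionally suppressed in
#'   disease by `faoDiseaseLog2FC` (SHAM vs healthy).
#' @param faoDiseaseLog2FC Planted SHAM-vs-healthy log2 effect on FAO genes.
#' @param nFibrosisGenes,fibrosisLog2FC Size of the fibrosis module and its
#'   planted SHAM-vs-healthy log2 effect.
#' @param fibrosisReversal Fraction of the fibrosis effect removed by DMT
#'   (1 = full reversal, so DMT-vs-SHAM shows the opposite sign).
#' @param dispersion Shared negative-binomial dispersion of the counts.
#' @param librarySizeRange Positive pair; per-sample size factors are drawn
#'   log-uniformly from this interval.
#' @param baseMeanRange Positive pair; per-gene baseline means are drawn
#'   log-uniformly from this interval.
#' @param faoGenes,fibrosisGenes Optional explicit gene-id vectors for the
#'   modules (must be disjoint subsets of the gene universe).
#' @param atlas List: `coverage` (fraction of genes present in the atlas),
#'   `ptFraction` (fraction of FAO genes planted with a proximal-tubule
#'   argmax), `backgroundPtFraction` (same for non-module genes),
#'   `enrichmentRange` (fold range by which the planted maximal cell type
#'   exceeds the feature's next-highest abundance).
#' @param drugSpecs List: `sizes` (named target-set sizes for the five
#'   medications and three PPAR isotypes), `moduleHitFraction` (named,
#'   fraction of the FAO module included in each target set),
#'   `sharedCoreFraction` (fraction of the smallest drug set shared by all
#'   drugs, and likewise for isotypes), `fenoPparaOverlap` (optional exact
#'   requested size of the fenofibrate-PPARA intersection; only honoured
#'   when module and core planting are disabled), `extPoolSize` (non-study
#'   gene ids available as targets).
#' @param nmr List: `ppmRange`, `nPoints`, `groups` (named sizes for
#'   healthy / untreated_mild / untreated_severe / DMT), `peaks` (optional
#'   data.frame ppm/family/baseAmp/sigma), `groupEffects` (family x group
#'   multiplier matrix), `dilutionRange`, `noiseSD`, `baselineAmplitude`,
#'   `peakJitterSD` (lognormal sd of per-sample peak amplitudes),
#'   `shape` ("gaussian" or "lorentzian").
#' @param morphometry List: `groups` (named animal counts) and `params`
#'   (list per variable of named group `mean` and `sd`).
#' @return A list of class `syntheticStudyConfig`.
#' @export
#' @examples
#' cfg <- syntheticStudyConfig(seed = 7, nGenes = 500, nFaoGenes = 30,
#'                             nFibrosisGenes = 30)
#' study <- simulateCountStudy(cfg, "ZDF")
syntheticStudyConfig <- function(
    seed = 101,
    nPerGroup = c(healthy = 6, SHAM = 6, DMT = 6),
    nGenes = 2000,
    nFaoGenes = 120, faoLog2FC = 1.5, faoDiseaseLog2FC = -0.7,
    nFibrosisGenes = 120, fibrosisLog2FC = 1.5, fibrosisReversal = 1,
    dispersion = 0.05,
    librarySizeRange = c(0.7, 1.4),
    baseMeanRange = c(20, 2000),
    faoGenes = NULL, fibrosisGenes = NULL,
    atlas = list(), drugSpecs = list(), nmr = list(), morphometry = list()) {

  if (any(nPerGroup <= 0) || nGenes <= 0)
    stop("sample and gene counts must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(librarySizeRange <= 0) || any(baseMeanRange <= 0))
    stop("library-size and base-mean ranges must be positive")
  if (!all(c("healthy", "SHAM", "DMT") %in% names(nPerGroup)))
    stop("nPerGroup must name healthy, SHAM and DMT")
  if (!all(is.finite(c(faoLog2FC, faoDiseaseLog2FC, fibrosisLog2FC))))
    stop("module effects must be finite")

  genes <- sprintf("gene%05d", seq_len(nGenes))
  if (is.null(faoGenes)) {
    if (nFaoGenes + nFibrosisGenes > nGenes)
      stop("modules exceed the gene universe")
    faoGenes <- genes[seq_len(nFaoGenes)]
  }
  if (is.null(fibrosisGenes))
    fibrosisGenes <- genes[nFaoGenes + seq_len(nFibrosisGenes)]
  if (length(intersect(faoGenes, fibrosisGenes)))
    stop("FAO and fibrosis modules must be disjoint")
  if (!all(c(faoGenes, fibrosisGenes) %in% genes))
    stop("module genes must belong to the gene universe")

  atlas <- utils::modifyList(list(
    coverage = 0.8, ptFraction = 0.75, backgroundPtFraction = 3 / 14,
    enrichmentRange = c(2, 6)), atlas)

  drugSpecs <- utils::modifyList(list(
    sizes = c(fenofibrate = 880, liraglutide = 300, metformin = 400,
              ramipril = 250, rosuvastatin = 350,
              PPARA = 650, PPARD = 300, PPARG = 400),
    moduleHitFraction = c(fenofibrate = 0.75, liraglutide = 0.10,
                          metformin = 0.12, ramipril = 0.06,
                          rosuvastatin = 0.10,
                          PPARA = 0.62, PPARD = 0.05, PPARG = 0.08),
    sharedCoreFraction = 0.05,
    fenoPparaOverlap = NULL,
    extPoolSize = 4000), drugSpecs)

  nmr <- utils::modifyList(list(
    ppmRange = c(10, 0.2), nPoints = 12000,
    groups = c(healthy = 11, untreated_mild = 11,
               untreated_severe = 8, DMT = 6),
    peaks = NULL,
    groupEffects = NULL,
    dilutionRange = c(0.5, 2), noiseSD = 0.01,
    baselineAmplitude = 0.5, peakJitterSD = 0.02,
    shape = "gaussian"), nmr)
  if (any(nmr$dilutionRange <= 0)) stop("dilution factors must be positive")

  morphometry <- utils::modifyList(list(
    groups = c(healthy = 6, SHAM = 7, DMT = 6),
    params = .defaultMorphoParams()), morphometry)
  if (any(morphometry$groups < 1)) stop("group sizes must be >= 1")

  structure(list(
    seed = seed, nPerGroup = nPerGroup, nGenes = nGenes, genes = genes,
    faoGenes = faoGenes, faoLog2FC = faoLog2FC,
    faoDiseaseLog2FC = faoDiseaseLog2FC,
    fibrosisGenes = fibrosisGenes, fibrosisLog2FC = fibrosisLog2FC,
    fibrosisReversal = fibrosisReversal,
    dispersion = dispersion, librarySizeRange = librarySizeRange,
    baseMeanRange = baseMeanRange, atlas = atlas, drugSpecs = drugSpecs,
    nmr = nmr, morphometry = morphometry), class = "syntheticStudyConfig")
}

.defaultMorphoParams <- function() list(
  glom_area_um2 = list(mean = c(healthy = 8700, SHAM = 12500, DMT = 9800),
                       sd = c(healthy = 700, SHAM = 900, DMT = 800)),
  pfpf_per8um = list(mean = c(healthy = 16, SHAM = 10, DMT = 14),
                     sd = c(healthy = 1.2, SHAM = 1.0, DMT = 1.2)),
  gbm_nm = list(mean = c(healthy = 180, SHAM = 260, DMT = 210),
                sd = c(healthy = 15, SHAM = 20, DMT = 18)),
  mito_major_um = list(mean = c(healthy = 1.1, SHAM = 0.9, DMT = 1.2),
                       sd = c(healthy = 0.08, SHAM = 0.07, DMT = 0.09)),
  ## shape feature planted to track treatment response (disease-depressed,
  ## DMT-restored) so it co-varies positively with the FAO module
  mito_roundness = list(mean = c(healthy = 0.52, SHAM = 0.38, DMT = 0.60),
                        sd = c(healthy = 0.04, SHAM = 0.04, DMT = 0.04)))

#' Simulate a three-group renal count study with planted modules
#'
#' Draws integer counts from a negative-binomial model with shared per-gene
#' dispersion, log-uniform library sizes and planted group effects: the FAO
#' module is suppressed in disease (SHAM vs healthy) and induced by treatment
#' (DMT vs SHAM); the fibrosis module is induced in disease and reversed by
#' treatment. Identical config + seed gives byte-identical output.
#'
#' @param config A [syntheticStudyConfig()].
#' @param model "ZDF" or "ZDSD"; the two models use distinct derived seeds so
#'   they give independent but reproducible cohorts.
#' @return A [CountStudy-class]; `plantedTruth(x)` records per-gene module
#'   membership and true log2 fold-changes per contrast, plus the library
#'   sizes used.
#' @export
simulateCountStudy <- function(config, model = c("ZDF", "ZDSD")) {
  stopifnot(inherits(config, "syntheticStudyConfig"))
  model <- match.arg(model)
  seed <- config$seed + 1000L * match(model, c("ZDF", "ZDSD"))

  withSeed(seed, {
    ng <- config$nGenes
    genes <- config$genes
    mu0 <- exp(stats::runif(ng, log(config$baseMeanRange[1]),
                            log(config$baseMeanRange[2])))
    groups <- rep(names(config$nPerGroup), config$nPerGroup)
    n <- length(groups)
    sf <- exp(stats::runif(n, log(config$librarySizeRange[1]),
                           log(config$librarySizeRange[2])))

    ## per-gene log2 group effect, exponentiated into mean multipliers
    lfc <- matrix(0, ng, 3, dimnames = list(genes,
                                            c("healthy", "SHAM", "DMT")))
    iFao <- genes %in% config$faoGenes
    iFib <- genes %in% config$fibrosisGenes
    lfc[iFao, "SHAM"] <- config$faoDiseaseLog2FC
    lfc[iFao, "DMT"] <- config$faoDiseaseLog2FC + config$faoLog2FC
    lfc[iFib, "SHAM"] <- config$fibrosisLog2FC
    lfc[iFib, "DMT"] <- config$fibrosisLog2FC *
      (1 - config$fibrosisReversal)
    mult <- 2^lfc

    mu <- outer(mu0, sf) * mult[, groups]
    k <- matrix(stats::rnbinom(ng * n, mu = mu, size = 1 / config$dispersion),
                ng, n)
    dimnames(k) <- list(genes,
                        paste(model, groups, stats::ave(seq_len(n), groups,
                              FUN = seq_along), sep = "_"))

    module <- ifelse(iFao, "fao", ifelse(iFib, "fibrosis", "background"))
    truth <- list(
      genes = data.frame(
        gene = genes, module = module,
        log2FC_SHAMvsHealthy = lfc[, "SHAM"] - lfc[, "healthy"],
        log2FC_DMTvsSHAM = lfc[, "DMT"] - lfc[, "SHAM"],
        row.names = NULL),
      librarySizes = setNames(sf, colnames(k)),
      dispersion = config$dispersion, model = model)

    CountStudy(k, group = groups, model = model, truth = truth)
  })
}

#' Simulate a tubule cell-type abundance atlas
#'
#' Generates a non-negative feature x 14 cell-type abundance matrix over the
#' configured ontology (S1..IMCD). A configurable fraction of FAO-module
#' genes is planted with its maximal abundance in a proximal-tubule segment
#' (S1-S3); the maximal cell type of every feature is forced by construction
#' (planted column = next-highest abundance x a fold drawn from
#' `enrichmentRange`), so the recorded truth is exact.
#'
#' @param config A [syntheticStudyConfig()].
#' @return List with `atlas` (matrix, features x 14 ordered cell types) and
#'   `truth` (data.frame: feature, cellType, compartment).
#' @export
simulateAtlas <- function(config) {
  stopifnot(inherits(config, "syntheticStudyConfig"))
  withSeed(config$seed + 11L, {
    ct <- tubuleCellTypes()
    pt <- proximalTubuleCellTypes()
    a <- config$atlas
    present <- sort(sample(config$genes,
                           round(a$coverage * config$nGenes)))
    nf <- length(present)
    ab <- matrix(exp(stats::rnorm(nf * 14, mean = 2, sd = 0.6)), nf, 14,
                 dimnames = list(present, ct))
    isFao <- present %in% config$faoGenes
    ptProb <- ifelse(isFao, a$ptFraction, a$backgroundPtFraction)
    inPT <- stats::runif(nf) < ptProb
    maxType <- ifelse(inPT, sample(pt, nf, replace = TRUE),
                      sample(setdiff(ct, pt), nf, replace = TRUE))
    fold <- stats::runif(nf, a$enrichmentRange[1], a$enrichmentRange[2])
    for (i in seq_len(nf)) {
      others <- ab[i, setdiff(ct, maxType[i])]
      ab[i, maxType[i]] <- max(others) * fold[i]
    }
    truth <- data.frame(
      feature = present, cellType = maxType,
      compartment = ifelse(maxType %in% pt, "proximal_tubule",
                           "rest_of_tubule"), row.names = NULL)
    list(atlas = ab, truth = truth)
  })
}

#' Simulate medication and PPAR-isotype target networks
#'
#' Builds target gene sets for the five study medications (fenofibrate,
#' liraglutide, metformin, ramipril, rosuvastatin) and the three PPAR
#' isotypes (PPARA, PPARD, PPARG) over the study gene universe plus an
#' external pool. Each entity receives a configured fraction of the planted
#' FAO module (fenofibrate and PPARA dominating), an optional core shared by
#' all entities of its class, and disjoint random fill to its configured
#' size. Edge signs are +1 for planted module targets (treatment-induced)
#' and random otherwise.
#'
#' @param config A [syntheticStudyConfig()].
#' @return List with `edges` (data.frame entity/target/sign), `targetSets`
#'   (named list of character vectors) and `truth` (planted per-gene
#'   responsiveness and the planted fenofibrate / PPARA shares over module
#'   genes).
#' @export
simulateDrugNetworks <- function(config) {
  stopifnot(inherits(config, "syntheticStudyConfig"))
  ds <- config$drugSpecs
  drugs <- c("fenofibrate", "liraglutide", "metformin", "ramipril",
             "rosuvastatin")
  isotypes <- c("PPARA", "PPARD", "PPARG")
  entities <- c(drugs, isotypes)
  if (!all(entities %in% names(ds$sizes)))
    stop("drugSpecs$sizes must name all five drugs and three isotypes")

  withSeed(config$seed + 23L, {
    pool <- c(config$genes, sprintf("ext%05d", seq_len(ds$extPoolSize)))
    fao <- config$faoGenes

    buildClass <- function(members) {
      sizes <- ds$sizes[members]
      core <- character()
      if (ds$sharedCoreFraction > 0) {
        nCore <- round(ds$sharedCoreFraction * min(sizes))
        core <- sample(setdiff(pool, fao), nCore)
      }
      sets <- list(); used <- core
      for (e in members) {
        hits <- character()
        f <- ds$moduleHitFraction[[e]] %||% 0
        if (f > 0) hits <- sample(fao, round(f * length(fao)))
        s <- unique(c(core, hits))
        if (length(s) > sizes[[e]])
          stop("requested overlap exceeds set size for ", e)
        fill <- sample(setdiff(pool, c(used, s, fao)),
                       sizes[[e]] - length(s))
        s <- c(s, fill)
        used <- union(used, s)
        sets[[e]] <- s
      }
      sets
    }

    sets <- c(buildClass(drugs), buildClass(isotypes))

    ## honour an exact requested fenofibrate-PPARA intersection when the
    ## planted-module route is disabled
    if (!is.null(ds$fenoPparaOverlap)) {
      k <- ds$fenoPparaOverlap
      feno <- sets$fenofibrate
      ppara <- sets$PPARA
      if (k > min(length(feno), length(ppara)))
        stop("requested overlap exceeds set sizes")
      cur <- intersect(ppara, feno)
      if (length(cur) > k)
        ppara <- c(setdiff(ppara, feno), sample(cur, k))
      if (length(cur) < k) {
        add <- sample(setdiff(feno, ppara), k - length(cur))
        drop <- sample(setdiff(ppara, feno), k - length(cur))
        ppara <- c(setdiff(ppara, drop), add)
      }
      sets$PPARA <- ppara
    }

    edges <- do.call(rbind, lapply(entities, function(e) {
      tg <- sets[[e]]
      sgn <- ifelse(tg %in% fao, 1L,
                    sample(c(-1L, 1L), length(tg), replace = TRUE))
      data.frame(entity = e, target = tg, sign = sgn)
    }))
    rownames(edges) <- NULL

    ## planted shares over the union of planted modules (both modules are
    ## planted as concordant DEGs, so this is the truth the downstream
    ## stratification estimates)
    mod <- union(fao, config$fibrosisGenes)
    anyDrug <- mod[mod %in% unique(unlist(sets[drugs]))]
    anyIso <- mod[mod %in% unique(unlist(sets[isotypes]))]
    truth <- list(
      targetSets = sets,
      fenofibrateShareOfModule = if (length(anyDrug))
        100 * sum(anyDrug %in% sets$fenofibrate) / length(anyDrug) else NA,
      pparaShareOfModule = if (length(anyIso))
        100 * sum(anyIso %in% sets$PPARA) / length(anyIso) else NA)
    list(edges = edges, targetSets = sets, truth = truth)
  })
}

.defaultNmrPeaks <- function() {
  rbind(
    data.frame(ppm = c(7.84, 7.64, 7.50, 7.28, 3.97, 1.08),
               family = "clearance"),
    data.frame(ppm = c(6.52, 5.72, 3.01, 2.66, 2.54, 2.44), family = "tca"),
    data.frame(ppm = c(9.28, 8.90, 8.21, 4.48), family = "nicotinamide"),
    data.frame(ppm = c(5.23, 3.90, 3.72, 3.49, 3.25), family = "glucose"),
    ## dense background of urinary peaks unrelated to the intervention
    ## (real urine matrices carry ~100+ resolved peak groups); their
    ## majority keeps the quotient median anchored on dilution
    local({
      grid <- seq(0.55, 9.75, by = 0.115)
      fam <- c(7.84, 7.64, 7.50, 7.28, 3.97, 1.08, 6.52, 5.72, 3.01, 2.66,
               2.54, 2.44, 9.28, 8.90, 8.21, 4.48, 5.23, 3.90, 3.72, 3.49,
               3.25)
      keep <- vapply(grid, function(p) all(abs(fam - p) > 0.055),
                     logical(1))
      data.frame(ppm = round(grid[keep], 3), family = "stable")
    }))
}

.defaultNmrGroupEffects <- function() {
  m <- rbind(clearance   = c(1, 0.60, 0.35, 0.90),
             tca         = c(1, 1.50, 2.20, 1.10),
             nicotinamide = c(1, 1.00, 1.00, 2.50),
             glucose     = c(1, 8.00, 15.0, 2.00),
             stable      = c(1, 1, 1, 1))
  colnames(m) <- c("healthy", "untreated_mild", "untreated_severe", "DMT")
  m
}

#' Simulate a urinary 1H-NMR cohort with planted metabolite families
#'
#' Each spectrum is a sum of Gaussian (optionally Lorentzian) peaks at
#' planted ppm positions, scaled by a family x group effect (clearance
#' metabolites fall in disease, TCA intermediates rise in disease,
#' nicotinamide-pathway metabolites rise after treatment, glucose interferes
#' massively in untreated disease), multiplied by a per-sample dilution
#' factor, plus a smooth baseline and white noise. The baseline is not
#' scaled by dilution, so probabilistic-quotient factors are identifiable.
#'
#' @param config A [syntheticStudyConfig()].
#' @return An [NMRSpectra-class]; `plantedTruth(x)` records the peak table
#'   (position, family, width, per-group expected amplitude) and per-sample
#'   dilution factors.
#' @export
simulateNMRCohort <- function(config) {
  stopifnot(inherits(config, "syntheticStudyConfig"))
  nm <- config$nmr
  withSeed(config$seed + 37L, {
    ppm <- seq(nm$ppmRange[1], nm$ppmRange[2], length.out = nm$nPoints)
    peaks <- nm$peaks %||% .defaultNmrPeaks()
    if (any(peaks$ppm > max(nm$ppmRange)) ||
        any(peaks$ppm < min(nm$ppmRange)))
      stop("peak ppm outside the axis range")
    eff <- nm$groupEffects %||% .defaultNmrGroupEffects()
    np <- nrow(peaks)
    if (is.null(peaks$sigma)) peaks$sigma <- stats::runif(np, 0.005, 0.009)
    if (is.null(peaks$baseAmp)) {
      amp <- c(clearance = 5, tca = 3.5, nicotinamide = 3.5,
               glucose = 30, stable = 4)
      peaks$baseAmp <- amp[peaks$family] * exp(stats::rnorm(np, 0, 0.25))
    }

    groups <- rep(names(nm$groups), nm$groups)
    n <- length(groups)
    ids <- paste(groups, stats::ave(seq_len(n), groups, FUN = seq_along),
                 sep = "_")
    dil <- stats::runif(n, nm$dilutionRange[1], nm$dilutionRange[2])

    shapeFun <- if (nm$shape == "lorentzian") {
      function(x, mu, s) 1 / (1 + ((x - mu) / s)^2)
    } else {
      function(x, mu, s) exp(-(x - mu)^2 / (2 * s^2))
    }

    intens <- matrix(0, nm$nPoints, n, dimnames = list(NULL, ids))
    ## broad features only (scales well above the correction window) so the
    ## running-quantile baseline can track it
    baselineShape <- 0.5 + 0.4 * sin(2 * pi * ppm / 18) +
      exp(-(ppm - 3.6)^2 / (2 * 2.0^2))
    for (j in seq_len(n)) {
      mults <- eff[peaks$family, groups[j]]
      jitter <- exp(stats::rnorm(np, 0, nm$peakJitterSD))
      sig <- rep(0, nm$nPoints)
      for (p in seq_len(np)) {
        sig <- sig + peaks$baseAmp[p] * mults[p] * jitter[p] *
          shapeFun(ppm, peaks$ppm[p], peaks$sigma[p])
      }
      gScale <- c(healthy = 0.4, untreated_mild = 1.6,
                  untreated_severe = 2.4, DMT = 0.7)[groups[j]]
      intens[, j] <- dil[j] * sig +
        nm$baselineAmplitude * gScale * baselineShape +
        stats::rnorm(nm$nPoints, 0, nm$noiseSD)
    }

    ## expected undiluted apex amplitude per peak per group
    expected <- peaks$baseAmp * eff[peaks$family, , drop = FALSE]
    colnames(expected) <- paste0("amp_", colnames(eff))
    truth <- list(
      peaks = cbind(peaks, as.data.frame(expected)),
      dilution = setNames(dil, ids),
      groupEffects = eff)
    NMRSpectra(ppm, intens, group = groups, truth = truth)
  })
}

#' Simulate per-animal morphometry tables
#'
#' Glomerular tuft area, podocyte foot-process frequency, GBM thickness and
#' mitochondrial axis / shape measures are drawn from group-shifted normals
#' truncated at zero. Mitochondrial minor axis and area are derived from the
#' planted major axis and roundness so that the roundness formula holds
#' exactly on the generated table.
#'
#' @param config A [syntheticStudyConfig()].
#' @return List with `measurements` (data.frame, one row per animal) and
#'   `truth` (the group mean/sd parameters used).
#' @export
simulateMorphometry <- function(config) {
  stopifnot(inherits(config, "syntheticStudyConfig"))
  mo <- config$morphometry
  for (v in mo$params) if (any(v$sd < 0))
    stop("negative scale parameters")
  withSeed(config$seed + 53L, {
    groups <- rep(names(mo$groups), mo$groups)
    n <- length(groups)
    draw <- function(par) {
      pmax(.Machine$double.eps,
           stats::rnorm(n, par$mean[groups], par$sd[groups]))
    }
    d <- data.frame(
      animal = paste0("animal_", sprintf("%02d", seq_len(n))),
      group = groups,
      glom_area_um2 = draw(mo$params$glom_area_um2),
      pfpf_per8um = draw(mo$params$pfpf_per8um),
      gbm_nm = draw(mo$params$gbm_nm),
      mito_major_um = draw(mo$params$mito_major_um),
      mito_roundness = pmin(1, draw(mo$params$mito_roundness)))
    d$mito_minor_um <- d$mito_major_um * d$mito_roundness
    d$mito_area_um2 <- pi / 4 * d$mito_major_um * d$mito_minor_um
    list(measurements = d, truth = mo$params)
  })
}

#' Planted stratification truth for the synthetic study
#'
#' Computes, from generator outputs alone, the quantities the downstream
#' stratification estimates on recovered DEGs: over the union of the
#' planted modules (all planted concordant DEGs), the share of
#' any-entity-responsive genes that respond to the focal entity, and the
#' proximal-tubule share of the focal-responsive genes present in the
#' atlas.
#'
#' @param config A [syntheticStudyConfig()].
#' @param networks Output of [simulateDrugNetworks()].
#' @param atlasTruth The `truth` data.frame of [simulateAtlas()].
#' @param focalEntity Entity name (default "fenofibrate").
#' @param entities Class members (default the five medications).
#' @return List: `focalShare`, `ptShare` (percentages).
#' @export
plantedStratificationTruth <- function(config, networks, atlasTruth,
                                       focalEntity = "fenofibrate",
                                       entities = c("fenofibrate",
                                                    "liraglutide",
                                                    "metformin", "ramipril",
                                                    "rosuvastatin")) {
  mod <- union(config$faoGenes, config$fibrosisGenes)
  sets <- networks$targetSets[entities]
  anyResp <- mod[mod %in% unique(unlist(sets))]
  focal <- anyResp[anyResp %in% sets[[focalEntity]]]
  inAtlas <- intersect(focal, atlasTruth$feature)
  ptN <- sum(atlasTruth$compartment[match(inAtlas, atlasTruth$feature)] ==
               "proximal_tubule")
  list(focalShare = if (length(anyResp))
    100 * length(focal) / length(anyResp) else NA_real_,
    ptShare = if (length(inAtlas)) 100 * ptN / length(inAtlas) else
      NA_real_)
}
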