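# Small shared fixtures built in code.

# a compact synthetic study configuration for fast tests
smallStudyConfig <- function(seed = 7, ...) {
  syntheticStudyConfig(
    seed = seed, nGenes = 400, nFaoGenes = 40, nFibrosisGenes = 40,
    drugSpecs = list(
      sizes = c(fenofibrate = 120, liraglutide = 60, metformin = 70,
                ramipril = 50, rosuvastatin = 60,
                PPARA = 100, PPARD = 50, PPARG = 60),
      extPoolSize = 800),
    nmr = list(nPoints = 6000,
               groups = c(healthy = 5, untreated_mild = 5,
                          untreated_severe = 4, DMT = 4)),
    ...)
}

# a noise-free single-peak NMR configuration
onePeakConfig <- function(ppm = 3.0, amp = 5, sigma = 0.01, seed = 3,
                          groups = c(healthy = 2, untreated_mild = 1,
                                     untreated_severe = 1, DMT = 1),
                          dilutionRange = c(1, 1)) {
  syntheticStudyConfig(seed = seed, nmr = list(
    nPoints = 6000,
    peaks = data.frame(ppm = ppm, family = "stable", sigma = sigma,
                       baseAmp = amp),
    groups = groups, dilutionRange = dilutionRange,
    noiseSD = 0, baselineAmplitude = 0, peakJitterSD = 0))
}

# DEG set fixtures with chosen cardinalities
makeDEGs <- function(n, direction = "up", prefix = "g",
                     contrast = "fixture") {
  DEGSet(paste0(prefix, seq_len(n)), rep(direction, n), contrast)
}
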