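#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state on exit, so generator calls are reproducible without
#' perturbing the session RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Printed study percentages use commercial rounding (half away from zero),
#' not the IEEE 754 banker's rounding of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(75.757, 1)  # 75.8
#' roundHalfUp(0.25, 1)    # 0.3, where round() gives 0.2
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## shared ontology: the 14 tubular epithelial cell types, fixed order
.TUBULE_CELL_TYPES <- c("S1", "S2", "S3", "DTL1", "DTL2", "DTL3", "ATL",
                        "mTAL", "cTAL", "DCT", "CNT", "CCD", "OMCD", "IMCD")
.PT_CELL_TYPES <- c("S1", "S2", "S3")

#' Tubule cell-type ontology
#'
#' The fixed, ordered vector of the 14 renal tubular epithelial cell types
#' used by the localization atlas, from the proximal tubule segments (S1-S3)
#' through the collecting duct (IMCD).
#'
#' @return Character vector of length 14.
#' @export
tubuleCellTypes <- function() .TUBULE_CELL_TYPES

#' Proximal tubule cell types
#'
#' @return Character vector: the S1, S2 and S3 proximal tubule segments.
#' @export
proximalTubuleCellTypes <- function() .PT_CELL_TYPES

`%||%` <- function(a, b) if (is.null(a)) b else a
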