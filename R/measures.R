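#' Weibel-Gomez glomerular volume from tuft area
#'
#' V = (beta / d) * A^(3/2), the stereological conversion from mean profile
#' area to particle volume, with the sphere shape coefficient beta = 1.38
#' and size-distribution coefficient d = 1.01.
#'
#' @param area Tuft area(s) in um^2, non-negative.
#' @param beta,d Shape and size-distribution coefficients.
#' @return Volume(s) in um^3.
#' @export
#' @examples
#' glomerularVolume(10000)  # ~1.366e6 um^3
glomerularVolume <- function(area, beta = 1.38, d = 1.01) {
  if (any(area < 0)) stop("area must be non-negative")
  (beta / d) * area^1.5
}

#' Object roundness from area and major axis
#'
#' roundness = 4 * area / (pi * major^2); equals minor/major (the inverse
#' aspect ratio) for an ellipse, and 1 for a circle.
#'
#' @param area Cross-sectional area.
#' @param majorAxis Major axis length (> 0), same length unit.
#' @return Roundness in (0, 1] for convex shapes.
#' @export
roundness <- function(area, majorAxis) {
  if (any(majorAxis <= 0)) stop("major axis must be positive")
  4 * area / (pi * majorAxis^2)
}

#' Podocyte foot-process diameter from foot-process frequency
#'
#' PFPD is the reciprocal of PFPF over the 8 um GBM measurement window:
#' PFPD = 8000 / PFPF nanometres.
#'
#' @param pfpf Foot processes per 8 um of glomerular basement membrane
#'   (> 0).
#' @return Diameter in nm.
#' @export
#' @examples
#' pfpdFromPfpf(16)  # 500 nm
pfpdFromPfpf <- function(pfpf) {
  if (any(pfpf <= 0)) stop("PFPF must be positive")
  8000 / pfpf
}

#' Percentage delta change
#'
#' 100 * (post - pre) / pre, per animal.
#'
#' @param pre,post Pre- and post-intervention values; `pre` must be
#'   non-zero.
#' @return Percent change.
#' @export
deltaPercent <- function(pre, post) {
  if (any(pre == 0)) stop("pre-intervention value must be non-zero")
  100 * (post - pre) / pre
}

#' Relative quantification by the comparative Ct (ddCt) method
#'
#' Per sample, dCt = target Ct - reference Ct; ddCt subtracts the mean dCt
#' of the calibrator group; RQ = 2^(-ddCt). The calibrator group's RQ has
#' geometric mean 1 by construction.
#'
#' @param records data.frame with columns `sample`, `group`, `targetCt`,
#'   `referenceCt`.
#' @param calibratorGroup Group label serving as calibrator (e.g. the
#'   healthy controls).
#' @return The records with added `dCt`, `ddCt`, `RQ` columns.
#' @export
relativeQuantificationDdct <- function(records, calibratorGroup) {
  stopifnot(all(c("sample", "group", "targetCt", "referenceCt") %in%
                  names(records)))
  if (!any(records$group == calibratorGroup))
    stop("calibrator group not present")
  if (!all(is.finite(records$targetCt)) ||
      !all(is.finite(records$referenceCt)))
    stop("Ct values must be finite")
  records$dCt <- records$targetCt - records$referenceCt
  calMean <- mean(records$dCt[records$group == calibratorGroup])
  records$ddCt <- records$dCt - calMean
  records$RQ <- 2^(-records$ddCt)
  records
}
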