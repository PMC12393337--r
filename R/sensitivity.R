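## Calibration-curve analysis, limit of detection, pathlength scaling.

#' Fit a concentration-response calibration line
#'
#' Ordinary least squares of response versus concentration; the residual SD
#' uses the n - 2 denominator.
#'
#' @param concentration_uM concentration levels, uM (>= 3, not all equal).
#' @param response responses (fitted peak height, OD, by default; or band
#'   area, OD cm^-1).
#' @param pathlength_um cell pathlength, um (metadata).
#' @param responseMetric "height" or "area".
#' @return a completed [CalibrationSeries-class].
#' @export
calibrationFit <- function(concentration_uM, response,
                           pathlength_um = NA_real_,
                           responseMetric = c("height", "area")) {
  responseMetric <- match.arg(responseMetric)
  if (length(unique(concentration_uM)) < 2)
    stop("rank-deficient series: all concentrations identical")
  obj <- new("CalibrationSeries", concentration_uM = concentration_uM,
             response = response, pathlength_um = pathlength_um,
             responseMetric = responseMetric)
  fit <- stats::lm(response ~ concentration_uM)
  sm <- summary(fit)
  obj@slope <- unname(stats::coef(fit)[2])
  obj@intercept <- unname(stats::coef(fit)[1])
  obj@slopeSE <- sm$coefficients[2, 2]
  obj@interceptSE <- sm$coefficients[1, 2]
  obj@sigmaResid <- sm$sigma
  obj
}

#' Limit of detection from a calibration line
#'
#' lod = factor * sigma_resid / slope, with the factor recorded in the
#' result (3.3 by default, the usual calibration-line convention; 3.0 is a
#' common alternative).
#'
#' @param series a completed [CalibrationSeries-class].
#' @param factor LOD multiplier.
#' @return a [LodResult-class].
#' @export
lodEstimate <- function(series, factor = 3.3) {
  if (is.na(series@slope)) stop("series must be fitted first")
  if (series@slope <= 0)
    stop("non-positive calibration slope: no real absorber response")
  new("LodResult", lod_uM = factor * series@sigmaResid / series@slope,
      factor = factor, sigmaResid = series@sigmaResid,
      slope = series@slope, pathlength_um = series@pathlength_um)
}

#' Sensitivity ratio between two limits of detection
#'
#' @param lodA,lodB [LodResult-class] objects or plain LOD values, uM.
#' @return dimensionless ratio lodA / lodB (> 1 means B is more sensitive).
#' @export
sensitivityRatio <- function(lodA, lodB) {
  a <- if (is(lodA, "LodResult")) lodValue(lodA) else lodA
  b <- if (is(lodB, "LodResult")) lodValue(lodB) else lodB
  if (a <= 0 || b <= 0) stop("LODs must be > 0")
  a / b
}

#' Predicted LOD under Beer-Lambert pathlength scaling
#'
#' At fixed absorbance noise the calibration slope is proportional to the
#' pathlength, so the predicted LOD scales as L_ref / L_new.
#'
#' @param lodRef_uM reference LOD, uM.
#' @param lRef_um,lNew_um reference and new pathlengths, um.
#' @return predicted LOD at the new pathlength, uM.
#' @export
pathlengthScaling <- function(lodRef_uM, lRef_um, lNew_um) {
  if (lRef_um <= 0 || lNew_um <= 0) stop("pathlengths must be > 0")
  lodRef_uM * lRef_um / lNew_um
}
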