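## Balanced dual-beam signal chain: raw sweeps -> calibrated absorbance.

#' Construct a processing configuration
#'
#' Defaults: no phase error, Savitzky-Golay window 11 / order 3, Fourier
#' low-pass at 0.25 of Nyquist, quadratic baseline through three anchor
#' windows flanking the nitrile band region.
#'
#' @param phaseDeg lock-in phase error, degrees in (-180, 180].
#' @param sgWindow,sgOrder Savitzky-Golay parameters (window NA disables).
#' @param fourierCutoff fraction of Nyquist (NA disables).
#' @param baselineOrder polynomial order of the baseline correction.
#' @param baselineAnchors list of c(lo, hi) cm^-1 anchor windows (empty list
#'   disables baseline correction).
#' @return a [ProcessingConfig-class] object.
#' @export
processingConfig <- function(phaseDeg = 0, sgWindow = 11, sgOrder = 3,
                             fourierCutoff = 0.25, baselineOrder = 2,
                             baselineAnchors = list(c(2150, 2170),
                                                    c(2185, 2205),
                                                    c(2265, 2285))) {
  new("ProcessingConfig", phaseDeg = phaseDeg, sgWindow = as.numeric(sgWindow),
      sgOrder = as.numeric(sgOrder), fourierCutoff = as.numeric(fourierCutoff),
      baselineOrder = baselineOrder, baselineAnchors = baselineAnchors)
}

#' Phase-correct a raw sweep
#'
#' Rotates each channel's (in-phase, quadrature) lock-in pair by the phase
#' error. When the record carries no quadrature data it is taken as zero, so
#' the in-phase projection is multiplied by cos(phase) and the rotated
#' quadrature is stored, making the operation invertible.
#'
#' @param raw a [RawSweep-class].
#' @param phaseDeg phase error in degrees, (-180, 180].
#' @return the rotated [RawSweep-class].
#' @export
phaseCorrect <- function(raw, phaseDeg) {
  if (phaseDeg <= -180 || phaseDeg > 180)
    stop("phaseDeg must lie in (-180, 180]")
  th <- phaseDeg * pi / 180
  n <- length(raw@wavenumber)
  qr <- if (length(raw@vRefQ)) raw@vRefQ else numeric(n)
  qb <- if (length(raw@vBalQ)) raw@vBalQ else numeric(n)
  out <- raw
  out@vRef <- raw@vRef * cos(th) + qr * sin(th)
  out@vRefQ <- -raw@vRef * sin(th) + qr * cos(th)
  out@vBal <- raw@vBal * cos(th) + qb * sin(th)
  out@vBalQ <- -raw@vBal * sin(th) + qb * cos(th)
  out
}

#' Derive a balance calibration from a blank-blank sweep
#'
#' The gain factor g maps the reference channel onto the blank-path beam
#' intensity. On a true blank-blank record the balanced channel is zero and
#' the reconstructed ratio is identically one for any g, so g is not
#' identifiable from the record's voltages; it is an instrument calibration
#' setting, read from the sweep metadata (`gain`) or supplied explicitly.
#' The residual baseline A0(nu) is the reconstructed absorbance of the
#' calibration record, smoothed by a low-order polynomial so detector noise
#' does not propagate into later spectra.
#'
#' @param blankBlank a blank-blank [RawSweep-class].
#' @param gain scalar or per-point gain; default `blankBlank@metadata$gain`,
#'   else 1.
#' @param baselineOrder polynomial order of the A0 smoother (default 2);
#'   `NA` keeps the raw per-point residual.
#' @return a [BalanceCalibration-class].
#' @export
calibrateBalance <- function(blankBlank, gain = NULL, baselineOrder = 2) {
  if (any(blankBlank@vRef <= 0))
    stop("reference channel non-positive: saturated or sign-flipped sweep")
  if (is.null(gain)) gain <- blankBlank@metadata$gain
  if (is.null(gain)) gain <- 1
  nu <- blankBlank@wavenumber
  g <- rep_len(gain, length(nu))
  if (any(g <= 0)) stop("gain must be > 0")
  ratio <- (g * blankBlank@vRef + blankBlank@vBal) / (g * blankBlank@vRef)
  if (any(ratio <= 0))
    stop("non-positive intensity ratio at ",
         paste(round(nu[ratio <= 0][1], 2), "cm-1"))
  a0 <- -log10(ratio)
  if (!is.na(baselineOrder)) {
    z <- (nu - mean(nu)) / diff(range(nu))
    a0 <- stats::fitted(stats::lm(a0 ~ stats::poly(z, baselineOrder,
                                                   raw = TRUE)))
    a0 <- as.numeric(a0)
  }
  new("BalanceCalibration", wavenumber = nu, gain = g, baseline = a0)
}

#' Reconstruct absorbance from a balanced sweep
#'
#' Computes A(nu) = -log10((g vRef + vBal) / (g vRef)) - A0(nu); the
#' parenthesised ratio is the sample/blank beam-intensity ratio, in which
#' the correlated source fluctuation cancels exactly.
#'
#' @param raw a sample-cell [RawSweep-class].
#' @param cal a [BalanceCalibration-class] on the same grid.
#' @return a [Spectrum-class] with history record "absorbance".
#' @export
computeAbsorbance <- function(raw, cal) {
  stopIfGridMismatch(raw@wavenumber, cal@wavenumber, "sweep and calibration")
  num <- cal@gain * raw@vRef + raw@vBal
  den <- cal@gain * raw@vRef
  bad <- which(num <= 0 | den <= 0)
  if (length(bad))
    stop("non-positive intensity ratio at ",
         round(raw@wavenumber[bad[1]], 2), " cm-1")
  a <- -log10(num / den) - cal@baseline
  new("Spectrum", wavenumber = raw@wavenumber, absorbance = a,
      history = list(list(step = "absorbance",
                          params = list(gain = unname(cal@gain[1])))))
}

#' Single-beam absorbance from sequential sweeps
#'
#' Emulates a conventional single-beam measurement: the sample-path beam
#' intensity of one acquisition ratioed against that of a second, separately
#' acquired record. Because the two acquisitions carry independent source
#' fluctuations, nothing cancels; used to quantify the balanced-detection
#' advantage.
#'
#' @param sampleSweep,blankSweep two [RawSweep-class] records on one grid.
#' @param gain reference-channel gain (default from metadata).
#' @return a [Spectrum-class].
#' @export
singleBeamAbsorbance <- function(sampleSweep, blankSweep, gain = NULL) {
  stopIfGridMismatch(sampleSweep@wavenumber, blankSweep@wavenumber)
  if (is.null(gain)) gain <- sampleSweep@metadata$gain
  if (is.null(gain)) gain <- 1
  iS <- gain * sampleSweep@vRef + sampleSweep@vBal
  iB <- gain * blankSweep@vRef + blankSweep@vBal
  if (any(iS <= 0 | iB <= 0)) stop("non-positive beam intensity")
  new("Spectrum", wavenumber = sampleSweep@wavenumber,
      absorbance = -log10(iS / iB),
      history = list(list(step = "single_beam_absorbance", params = list())))
}

## Mirror-pad a vector by k points each side (no edge duplication).
mirrorPad <- function(x, k) {
  n <- length(x)
  stopifnot(k < n)
  c(x[(k + 1):2], x, x[(n - 1):(n - k)])
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with mirror-extension edge
#' handling.
#'
#' @param spec a [Spectrum-class].
#' @param window odd number of points, > order, <= grid length.
#' @param order polynomial order.
#' @return smoothed [Spectrum-class]; history updated.
#' @export
sgFilter <- function(spec, window = 11, order = 3) {
  n <- length(spec@wavenumber)
  if (window %% 2 != 1 || window <= order || window > n)
    stop("sgWindow must be odd, greater than the order and <= grid length")
  k <- (window - 1) / 2
  coef <- signal::sgolay(p = order, n = window)[k + 1, ]
  xp <- mirrorPad(spec@absorbance, k)
  y <- as.numeric(stats::filter(xp, coef, sides = 2))[(k + 1):(k + n)]
  out <- spec
  out@absorbance <- y
  appendHistory(out, "sg_filter", list(window = window, order = order))
}

#' Fourier low-pass filter
#'
#' Low-pass filtering in the Fourier-conjugate domain of the wavenumber
#' axis; the spectrum is mirror-extended (even extension) before the FFT so
#' endpoints introduce no wrap-around discontinuity, and the output is real.
#'
#' @param spec a [Spectrum-class].
#' @param cutoff fraction of Nyquist in (0, 1]; components above it are
#'   removed.
#' @return filtered [Spectrum-class].
#' @export
fourierFilter <- function(spec, cutoff = 0.25) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  x <- spec@absorbance
  n <- length(x)
  xe <- c(x, rev(x))
  N <- 2L * n
  X <- stats::fft(xe)
  kmax <- floor(cutoff * N / 2)
  keep <- logical(N)
  keep[1:(kmax + 1)] <- TRUE                      # DC .. kmax
  if (kmax >= 1) keep[(N - kmax + 1):N] <- TRUE   # conjugate half
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE) / N)[seq_len(n)]
  out <- spec
  out@absorbance <- y
  appendHistory(out, "fourier_filter", list(cutoff = cutoff))
}

#' Polynomial baseline correction through anchor windows
#'
#' Fits a polynomial to the absorbance inside the anchor windows (regions
#' assumed free of analyte bands) and subtracts it across the grid.
#'
#' @param spec a [Spectrum-class].
#' @param anchors list of c(lo, hi) cm^-1 windows.
#' @param polyOrder polynomial order (default 1).
#' @param bandWindow optional c(lo, hi) band region; a warning is issued if
#'   any anchor overlaps it.
#' @return corrected [Spectrum-class].
#' @export
baselineCorrect <- function(spec, anchors, polyOrder = 1, bandWindow = NULL) {
  if (!length(anchors)) stop("at least one anchor window is required")
  if (!is.null(bandWindow))
    for (w in anchors)
      if (w[1] <= bandWindow[2] && w[2] >= bandWindow[1])
        warning("anchor window [", w[1], ", ", w[2],
                "] overlaps the band region")
  nu <- spec@wavenumber
  idx <- windowIndices(nu, anchors)
  if (length(idx) < polyOrder + 1)
    stop("too few anchor points for the requested polynomial order")
  z <- (nu - mean(nu)) / diff(range(nu))
  fit <- stats::lm(spec@absorbance[idx] ~ stats::poly(z[idx], polyOrder,
                                                      raw = TRUE))
  base <- cbind(1, stats::poly(z, polyOrder, raw = TRUE)) %*% stats::coef(fit)
  out <- spec
  out@absorbance <- spec@absorbance - as.numeric(base)
  appendHistory(out, "baseline_correct",
                list(anchors = anchors, order = polyOrder))
}

#' Average replicate spectra
#'
#' Pointwise mean with standard error SD/sqrt(n).
#'
#' @param spectra list of [Spectrum-class] on identical grids.
#' @return a [Spectrum-class] with the `se` slot filled.
#' @export
averageSpectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  nu <- wavenumber(spectra[[1]])
  for (s in spectra) stopIfGridMismatch(nu, wavenumber(s), "replicates")
  m <- vapply(spectra, absorbance, numeric(length(nu)))
  m <- matrix(m, nrow = length(nu))
  n <- ncol(m)
  avg <- rowMeans(m)
  se <- if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else numeric(length(nu))
  new("Spectrum", wavenumber = nu, absorbance = avg, se = se,
      history = list(list(step = "average", params = list(n = n))))
}

#' Process a raw sweep pair to a calibrated spectrum
#'
#' Full default chain: phase correction -> balance calibration ->
#' absorbance reconstruction -> Savitzky-Golay -> Fourier filter ->
#' baseline correction. Each stage appends a history record.
#'
#' @param sampleSweep sample-cell [RawSweep-class].
#' @param calibration blank-blank [RawSweep-class] or a ready
#'   [BalanceCalibration-class].
#' @param config a [ProcessingConfig-class].
#' @return a [Spectrum-class].
#' @export
processSweep <- function(sampleSweep, calibration,
                         config = processingConfig()) {
  validObject(config)
  if (config@phaseDeg != 0)
    sampleSweep <- phaseCorrect(sampleSweep, config@phaseDeg)
  cal <- if (is(calibration, "BalanceCalibration")) calibration
         else calibrateBalance(if (config@phaseDeg != 0)
                                 phaseCorrect(calibration, config@phaseDeg)
                               else calibration)
  spec <- computeAbsorbance(sampleSweep, cal)
  if (!is.na(config@sgWindow))
    spec <- sgFilter(spec, config@sgWindow, config@sgOrder)
  if (!is.na(config@fourierCutoff))
    spec <- fourierFilter(spec, config@fourierCutoff)
  if (length(config@baselineAnchors))
    spec <- baselineCorrect(spec, config@baselineAnchors,
                            config@baselineOrder)
  spec
}
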