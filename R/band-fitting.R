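## Pseudo-Voigt band location, fitting and frequency-shift detection.

#' Detect candidate band centers
#'
#' Local maxima in a window, filtered by topographic prominence and ordered
#' by decreasing prominence.
#'
#' @param spec a [Spectrum-class].
#' @param minProminence minimum prominence, OD.
#' @param window c(lo, hi) cm^-1 search window (default whole grid).
#' @return data.frame: center_cm1, height, prominence (possibly 0 rows).
#' @export
detectPeaks <- function(spec, minProminence = 0, window = NULL) {
  nu <- spec@wavenumber
  a <- spec@absorbance
  if (is.null(window)) window <- range(nu)
  idx <- which(nu >= window[1] & nu <= window[2])
  if (length(idx) < 3)
    return(data.frame(center_cm1 = numeric(), height = numeric(),
                      prominence = numeric()))
  x <- a[idx]
  n <- length(x)
  isMax <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (!length(isMax))
    return(data.frame(center_cm1 = numeric(), height = numeric(),
                      prominence = numeric()))
  prom <- vapply(isMax, function(i) {
    h <- x[i]
    ## walk outward until terrain exceeds the peak (or the window edge)
    left <- x[1:i]
    higherL <- which(left > h)
    minL <- min(left[(max(higherL, 0) + 1):i])
    right <- x[i:n]
    higherR <- which(right > h)
    stopR <- if (length(higherR)) min(higherR) else length(right)
    minR <- min(right[1:stopR])
    h - max(minL, minR)
  }, numeric(1))
  keep <- prom >= minProminence & prom > 0
  out <- data.frame(center_cm1 = nu[idx][isMax[keep]],
                    height = x[isMax[keep]], prominence = prom[keep])
  out[order(-out$prominence), , drop = FALSE]
}

## Internal: build an unconverged placeholder fit.
failedFit <- function(window, note) {
  new("BandFit", center = NA_real_, centerSE = NA_real_, fwhm = NA_real_,
      fwhmSE = NA_real_, amplitude = NA_real_, amplitudeSE = NA_real_,
      gaussFraction = NA_real_, area = NA_real_,
      window = as.numeric(window), residRMS = NA_real_, converged = FALSE,
      note = note)
}

#' Fit pseudo-Voigt bands
#'
#' Nonlinear least squares of a sum of pseudo-Voigt profiles plus a local
#' linear baseline, inside a fit window. Standard errors come from the
#' covariance of the converged fit; non-convergence is flagged on the
#' result, never silent.
#'
#' @param spec a [Spectrum-class].
#' @param nBands number of bands (>= 1).
#' @param init optional numeric vector of initial centers; defaults to
#'   [detectPeaks()] candidates in the window. If two candidates fall within
#'   half a FWHM of each other the higher-prominence one is kept and the
#'   ambiguity is recorded in the result's `note`.
#' @param window c(lo, hi) cm^-1; default +/- 25 cm^-1 around the leading
#'   candidate.
#' @param eta pseudo-Voigt Gaussian fraction; fixed unless `fitEta`.
#' @param fitEta logical; fit the shape fraction (bounded to [0, 1]).
#' @param halfWindow half-width used when `window` is derived from a
#'   candidate center, cm^-1.
#' @return list of [BandFit-class], one per band.
#' @export
fitBands <- function(spec, nBands = 1, init = NULL, window = NULL,
                     eta = 0.5, fitEta = FALSE, halfWindow = 25) {
  stopifnot(nBands >= 1)
  nu <- spec@wavenumber
  note <- ""
  if (is.null(init)) {
    cand <- detectPeaks(spec, minProminence = 0, window = window)
    if (!nrow(cand))
      return(rep(list(failedFit(window %||% range(nu),
                                "no candidate peaks")), nBands))
    ## collapse near-duplicate candidates (within half a nominal width)
    if (nrow(cand) > 1) {
      keep <- rep(TRUE, nrow(cand))
      for (i in 2:nrow(cand))
        if (any(abs(cand$center_cm1[i] -
                    cand$center_cm1[keep & seq_len(nrow(cand)) < i]) < 5)) {
          keep[i] <- FALSE
          note <- "ambiguous candidates collapsed by prominence"
        }
      cand <- cand[keep, , drop = FALSE]
    }
    init <- cand$center_cm1[seq_len(min(nBands, nrow(cand)))]
  }
  if (length(init) < nBands) {
    warning("fewer candidate peaks than requested bands; ",
            "padding initial centers at the window center")
    wc <- if (!is.null(window)) mean(window) else mean(init)
    init <- c(init, rep(wc, nBands - length(init)))
    note <- paste(note, "constrained fit: candidates < nBands")
  }
  if (is.null(window))
    window <- c(min(init) - halfWindow, max(init) + halfWindow)
  window <- c(max(window[1], min(nu)), min(window[2], max(nu)))
  idx <- which(nu >= window[1] & nu <= window[2])
  if (length(idx) < 4 * nBands + 3)
    return(rep(list(failedFit(window, "window too narrow")), nBands))

  x <- nu[idx]
  y <- spec@absorbance[idx]
  x0 <- mean(x)
  base0 <- stats::median(y)

  parNames <- unlist(lapply(seq_len(nBands), function(i)
    paste0(c("c", "w", "a"), i)))
  start <- list()
  lower <- upper <- numeric()
  for (i in seq_len(nBands)) {
    start[[paste0("c", i)]] <- init[i]
    start[[paste0("w", i)]] <- 10
    start[[paste0("a", i)]] <- max(y[which.min(abs(x - init[i]))] - base0,
                                   1e-6)
    lower <- c(lower, window[1], 1.5, -Inf)
    upper <- c(upper, window[2], diff(window), Inf)
  }
  start$b0 <- base0
  start$b1 <- 0
  lower <- c(lower, -Inf, -Inf)
  upper <- c(upper, Inf, Inf)
  etaPar <- FALSE
  if (fitEta) {
    start$e1 <- eta
    lower <- c(lower, 0)
    upper <- c(upper, 1)
    etaPar <- TRUE
  }

  model <- function(par) {
    yy <- par[["b0"]] + par[["b1"]] * (x - x0)
    e <- if (etaPar) par[["e1"]] else eta
    for (i in seq_len(nBands))
      yy <- yy + par[[paste0("a", i)]] *
        pseudoVoigt(x, par[[paste0("c", i)]], par[[paste0("w", i)]], e)
    yy
  }
  resid <- function(p) {
    par <- as.list(p)
    y - model(par)
  }
  p0 <- unlist(start)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5) ||
      !all(is.finite(unlist(fit$par))))
    return(rep(list(failedFit(window, "nonlinear fit did not converge")),
               nBands))

  p <- unlist(fit$par)
  dof <- length(y) - length(p)
  rms <- sqrt(sum(fit$fvec^2) / length(y))
  ## nls.lm's `hessian` is the Gauss-Newton J'J; covariance = s2 * (J'J)^-1
  covm <- tryCatch({
    s2 <- sum(fit$fvec^2) / dof
    s2 * chol2inv(chol(fit$hessian))
  }, error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, length(p)) else sqrt(pmax(diag(covm), 0))
  names(se) <- names(p)

  eFit <- if (etaPar) p[["e1"]] else eta
  lapply(seq_len(nBands), function(i) {
    amp <- p[[paste0("a", i)]]
    wid <- p[[paste0("w", i)]]
    new("BandFit",
        center = p[[paste0("c", i)]], centerSE = se[[paste0("c", i)]],
        fwhm = wid, fwhmSE = se[[paste0("w", i)]],
        amplitude = amp, amplitudeSE = se[[paste0("a", i)]],
        gaussFraction = eFit, area = pseudoVoigtArea(amp, wid, eFit),
        window = as.numeric(window), residRMS = rms, converged = TRUE,
        note = trimws(note))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frequency shift between two band fits
#'
#' @param fitA,fitB converged [BandFit-class] objects (e.g. apo and holo).
#' @param variant optional variant label.
#' @param conditionA,conditionB condition labels.
#' @return a [ShiftResult-class] with shift = center_b - center_a and the
#'   standard errors propagated in quadrature.
#' @export
frequencyShift <- function(fitA, fitB, variant = NA_character_,
                           conditionA = "apo", conditionB = "holo") {
  if (!isConverged(fitA) || !isConverged(fitB))
    stop("frequencyShift requires two converged band fits")
  new("ShiftResult",
      shift = fitB@center - fitA@center,
      uncertainty = sqrt(fitA@centerSE^2 + fitB@centerSE^2),
      variant = variant, conditionA = conditionA, conditionB = conditionB)
}

#' Signal-to-noise ratio of a spectrum
#'
#' Peak height above a local linear baseline in the signal window, divided
#' by the RMS residual after linear detrending in the (disjoint) noise
#' window.
#'
#' @param spec a [Spectrum-class].
#' @param signalWindow,noiseWindow c(lo, hi) cm^-1, disjoint.
#' @return dimensionless SNR; `Inf` when the noise RMS is exactly zero.
#' @export
snrEstimate <- function(spec, signalWindow, noiseWindow) {
  if (signalWindow[1] <= noiseWindow[2] && signalWindow[2] >= noiseWindow[1])
    stop("signal and noise windows must be disjoint")
  nu <- spec@wavenumber
  a <- spec@absorbance
  iS <- which(nu >= signalWindow[1] & nu <= signalWindow[2])
  iN <- which(nu >= noiseWindow[1] & nu <= noiseWindow[2])
  stopifnot(length(iS) >= 3, length(iN) >= 3)
  ## signal: peak above the chord between window endpoints
  chord <- stats::approx(nu[iS][c(1, length(iS))], a[iS][c(1, length(iS))],
                         xout = nu[iS])$y
  sig <- max(a[iS] - chord)
  res <- stats::residuals(stats::lm(a[iN] ~ nu[iN]))
  rms <- sqrt(mean(res^2))
  if (rms == 0) return(Inf)
  sig / rms
}
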