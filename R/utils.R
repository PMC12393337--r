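## Internal helpers.

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Unit-peak pseudo-Voigt profile (Gaussian fraction eta).
#' Pseudo-Voigt profile
#'
#' Unit-peak pseudo-Voigt band: the weighted sum
#' \eqn{\eta G + (1-\eta) L} of a Gaussian and a Lorentzian sharing the same
#' center and full width at half maximum.
#'
#' @param nu wavenumber grid, cm^-1.
#' @param center band center, cm^-1.
#' @param fwhm full width at half maximum, cm^-1.
#' @param eta Gaussian fraction in [0, 1].
#' @return numeric vector of unit-peak profile values.
#' @export
pseudoVoigt <- function(nu, center, fwhm, eta = 0.5) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- (nu - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  eta * g + (1 - eta) * l
}

## Analytic area of a unit-peak pseudo-Voigt of amplitude `amp`.
pseudoVoigtArea <- function(amp, fwhm, eta) {
  amp * fwhm * (eta * 0.5 * sqrt(pi / log(2)) + (1 - eta) * pi / 2)
}

stopIfGridMismatch <- function(nuA, nuB, what = "grids") {
  if (length(nuA) != length(nuB) || any(abs(nuA - nuB) > 1e-9))
    stop("grid mismatch: ", what, " must share an identical wavenumber grid")
  invisible(TRUE)
}

## Indices of grid points falling in any of a list of c(lo, hi) windows.
windowIndices <- function(nu, windows) {
  if (!length(windows)) return(integer())
  idx <- lapply(windows, function(w) which(nu >= w[1] & nu <= w[2]))
  sort(unique(unlist(idx)))
}

appendHistory <- function(spec, step, params) {
  spec@history <- c(spec@history, list(list(step = step, params = params)))
  spec
}
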