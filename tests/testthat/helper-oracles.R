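## Independent oracles, coded naively and separately from the package
## implementations they check.

## Naive Coulomb field: explicit loop over charges, no vectorisation.
naiveField <- function(coords, charges, point, exclude = integer()) {
  E <- c(0, 0, 0)
  for (i in seq_len(nrow(coords))) {
    if (i %in% exclude) next
    d <- point - coords[i, ]
    r <- sqrt(sum(d^2))
    E <- E + 1439.96 * charges[i] * d / r^3
  }
  E
}

## Naive projected field: average of naive fields at C and N, dotted with
## the C->N unit vector.
naiveProjected <- function(coords, charges, probe, exclude = integer()) {
  rC <- coords[probe[1], ]
  rN <- coords[probe[2], ]
  nhat <- (rN - rC) / sqrt(sum((rN - rC)^2))
  excl <- union(probe, exclude)
  eC <- naiveField(coords, charges, rC, excl)
  eN <- naiveField(coords, charges, rN, excl)
  sum(0.5 * (eC + eN) * nhat)
}

## Naive hydrogen-bond check, donor-vertex convention.
naiveHbond <- function(rA, rD, rH, distCut, angCut) {
  d <- sqrt(sum((rA - rD)^2))
  v1 <- rH - rD
  v2 <- rA - rD
  ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
    180 / pi
  d <= distCut && ang <= angCut
}

## Naive Savitzky-Golay: per-point least-squares polynomial fit on the
## mirror-padded signal (loops, lm()).
naiveSG <- function(x, window, order) {
  k <- (window - 1) / 2
  n <- length(x)
  xp <- c(x[(k + 1):2], x, x[(n - 1):(n - k)])
  out <- numeric(n)
  for (i in seq_len(n)) {
    seg <- xp[i:(i + 2 * k)]
    t <- (-k):k
    fit <- stats::lm(seg ~ stats::poly(t, order, raw = TRUE))
    out[i] <- stats::predict(fit, newdata = data.frame(t = 0))
  }
  out
}

## A clean noiseless band spectrum on the default grid.
bandSpectrum <- function(center = 2235, fwhm = 10, amp = 1e-3, eta = 0.5,
                         extra = 0) {
  nu <- seq(2000, 2300, by = 0.5)
  new("Spectrum", wavenumber = nu,
      absorbance = amp * pseudoVoigt(nu, center, fwhm, eta) + extra)
}
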