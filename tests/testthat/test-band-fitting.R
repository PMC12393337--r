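test_that("peak detection finds synthetic bands and nothing in flat spectra", {
  nu <- seq(2000, 2300, by = 0.5)
  flat <- new("Spectrum", wavenumber = nu, absorbance = numeric(length(nu)))
  expect_identical(nrow(detectPeaks(flat)), 0L)

  one <- bandSpectrum(center = 2226.4)
  cand <- detectPeaks(one, minProminence = 1e-4, window = c(2200, 2260))
  expect_identical(nrow(cand), 1L)
  expect_lt(abs(cand$center_cm1[1] - 2226.4), 0.5)

  nuAll <- wavenumber(one)
  two <- new("Spectrum", wavenumber = nuAll,
             absorbance = 1e-3 * pseudoVoigt(nuAll, 2225, 10) +
               8e-4 * pseudoVoigt(nuAll, 2240, 10))
  cand2 <- detectPeaks(two, minProminence = 1e-4, window = c(2200, 2260))
  expect_identical(nrow(cand2), 2L)
})

test_that("a noiseless pseudo-Voigt is fitted to within 0.01 cm-1", {
  spec <- bandSpectrum(center = 2226.4, fwhm = 10, amp = 5e-4)
  fit <- fitBands(spec, window = c(2200, 2255))[[1]]
  expect_true(isConverged(fit))
  expect_lt(abs(fit@center - 2226.4), 0.01)
  expect_lt(abs(fit@fwhm - 10), 0.05)
  expect_equal(fit@amplitude, 5e-4, tolerance = 1e-3)
  expect_equal(fit@area, pseudoVoigtArea(5e-4, 10, 0.5), tolerance = 0.01)
})

test_that("flat spectra yield a flagged, never silent, non-convergence", {
  nu <- seq(2000, 2300, by = 0.5)
  flat <- new("Spectrum", wavenumber = nu, absorbance = numeric(length(nu)))
  fit <- fitBands(flat, window = c(2200, 2260))[[1]]
  expect_false(isConverged(fit))
  expect_match(fit@note, "no candidate")
  expect_error(frequencyShift(fit, fit), "converged")
})

test_that("synthetic apo-F92 cell spectra fit to 2226.4 within 0.3 cm-1 over seeds", {
  centers <- vapply(1:20, function(s) {
    pair <- generateCellSpectrum("F92oCNF", "apo", snr = 20, seed = s)
    spec <- processSweep(pair$sample, pair$calibration)
    fitBands(spec, window = c(2205, 2265))[[1]]@center
  }, numeric(1))
  expect_lt(abs(mean(centers) - 2226.4), 0.3)
})

test_that("shift arithmetic and quadrature error propagation are exact", {
  mk <- function(center, se) new("BandFit", center = center, centerSE = se,
                                 fwhm = 10, fwhmSE = 0.1, amplitude = 1e-3,
                                 amplitudeSE = 1e-5, gaussFraction = 0.5,
                                 area = 1e-2, window = c(2200, 2260),
                                 residRMS = 0, converged = TRUE)
  same <- frequencyShift(mk(2226.4, 0.2), mk(2226.4, 0.2))
  expect_equal(shiftValue(same)[["shift"]], 0)
  expect_equal(shiftValue(same)[["se"]], sqrt(2) * 0.2)
  s345 <- frequencyShift(mk(2226.4, 0.3), mk(2241.3, 0.4))
  expect_equal(shiftValue(s345)[["shift"]], 14.9)
  expect_equal(shiftValue(s345)[["se"]], 0.5)
})

test_that("an end-to-end synthetic apo/holo F92 pair recovers the +14.9 shift", {
  fitOne <- function(cond, s) {
    pair <- generateCellSpectrum("F92oCNF", cond, snr = 20, seed = s)
    fitBands(processSweep(pair$sample, pair$calibration),
             window = c(2205, 2265))[[1]]
  }
  sh <- frequencyShift(fitOne("apo", 31), fitOne("holo", 32),
                       variant = "F92oCNF")
  expect_lt(abs(shiftValue(sh)[["shift"]] - 14.9),
            max(3 * shiftValue(sh)[["se"]], 0.3))
})

test_that("center recovery is unbiased across all fixture variants", {
  fx <- frequencyFixture()
  variants <- c("F28oCNF", "F62oCNF", "F92oCNF", "F96oCNF", "free_oCNF")
  nSeeds <- 40
  for (v in variants) {
    centers <- vapply(seq_len(nSeeds), function(s) {
      pair <- generateCellSpectrum(v, "apo", fixture = fx, snr = 15,
                                   seed = 5000 + s)
      fitBands(processSweep(pair$sample, pair$calibration),
               window = c(2205, 2265))[[1]]@center
    }, numeric(1))
    truth <- fx$apo_cm1[fx$variant == v]
    expect_lt(abs(mean(centers) - truth), 0.1,
              label = paste("center bias for", v))
  }
})

test_that("shift uncertainties cover the true shift at >= 90%", {
  ## fit on unsmoothed absorbance: the least-squares covariance assumes
  ## white residuals, which smoothing filters would correlate
  cfg <- processingConfig(sgWindow = NA, fourierCutoff = NA)
  n <- 50
  covered <- vapply(seq_len(n), function(s) {
    fitOne <- function(cond, off) {
      pair <- generateCellSpectrum("F96oCNF", cond, snr = 12,
                                   seed = 9000 + 2 * s + off)
      fitBands(processSweep(pair$sample, pair$calibration, cfg),
               window = c(2205, 2265))[[1]]
    }
    sh <- shiftValue(frequencyShift(fitOne("apo", 0), fitOne("holo", 1)))
    abs(sh[["shift"]] - 6.3) <= 1.96 * sh[["se"]]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("fits are equivariant under a shift of the wavenumber origin", {
  spec <- bandSpectrum(center = 2226.4, amp = 5e-4)
  delta <- 37.25
  shifted <- new("Spectrum", wavenumber = wavenumber(spec) + delta,
                 absorbance = absorbance(spec))
  f0 <- fitBands(spec, window = c(2200, 2255))[[1]]
  f1 <- fitBands(shifted, window = c(2200, 2255) + delta)[[1]]
  expect_equal(f1@center - f0@center, delta, tolerance = 1e-6)
  expect_equal(f1@fwhm, f0@fwhm, tolerance = 1e-8)
})

test_that("SNR estimation matches its construction and flags zero noise", {
  set.seed(77)
  nu <- seq(2000, 2300, by = 0.5)
  sigma <- 5e-5
  snrs <- vapply(1:8, function(i) {
    a <- 10 * sigma * pseudoVoigt(nu, 2235, 10) + rnorm(length(nu), 0, sigma)
    snrEstimate(new("Spectrum", wavenumber = nu, absorbance = a),
                signalWindow = c(2215, 2255), noiseWindow = c(2050, 2150))
  }, numeric(1))
  expect_equal(mean(snrs), 10, tolerance = 0.2)

  flat <- new("Spectrum", wavenumber = nu, absorbance = numeric(length(nu)))
  expect_identical(snrEstimate(flat, c(2215, 2255), c(2050, 2150)), Inf)
  expect_error(snrEstimate(flat, c(2215, 2255), c(2250, 2280)), "disjoint")
})

test_that("the QCL preset outperforms the FTIR preset in matched-sample SNR", {
  snrOf <- function(preset, s) {
    pr <- instrumentPreset(preset)
    samp <- sampleModel(bands = nitrileBand(), concentration_uM = 140,
                        pathlength_um = pr$pathlength_um)
    pair <- generateSweep(pr$instrument, samp, seed = s)
    spec <- processSweep(pair$sample, pair$calibration)
    snrEstimate(spec, c(2215, 2255), c(2050, 2150))
  }
  qcl <- mean(vapply(1:5, function(s) snrOf("qcl", s), numeric(1)))
  ftir <- mean(vapply(1:5, function(s) snrOf("ftir", s), numeric(1)))
  expect_gt(qcl, ftir)
})
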