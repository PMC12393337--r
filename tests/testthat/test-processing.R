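mkSweep <- function(vRef, vBal, nu = NULL, vRefQ = numeric(),
                    vBalQ = numeric(), gain = 1) {
  n <- max(length(vRef), length(vBal))
  if (is.null(nu)) nu <- seq(2000, by = 0.5, length.out = n)
  new("RawSweep", wavenumber = nu, vRef = rep_len(vRef, n),
      vBal = rep_len(vBal, n), vRefQ = vRefQ, vBalQ = vBalQ,
      metadata = list(gain = gain), aTrue = numeric())
}

test_that("phase correction is the in-phase rotation and is invertible", {
  s <- mkSweep(vRef = 1.0, vBal = 0.3)
  expect_identical(phaseCorrect(s, 0)@vRef, s@vRef)
  expect_equal(phaseCorrect(s, 60)@vRef, rep(0.5, length(s@vRef)),
               tolerance = 1e-12)
  back <- phaseCorrect(phaseCorrect(s, 37.5), -37.5)
  expect_lt(max(abs(back@vRef - s@vRef)), 1e-12)
  expect_lt(max(abs(back@vBal - s@vBal)), 1e-12)
  expect_error(phaseCorrect(s, 181), "phaseDeg")
})

test_that("balance calibration recovers the instrument gain and nulls its own sweep", {
  inst <- instrumentModel(gainImbalance = 1.05)
  pair <- generateSweep(inst, sampleModel(concentration_uM = 0), seed = 1)
  cal <- calibrateBalance(pair$calibration)
  expect_equal(unique(cal@gain), 1.05, tolerance = 1e-12)
  reapplied <- computeAbsorbance(pair$calibration, cal)
  expect_lt(max(abs(absorbance(reapplied))), 1e-12)
})

test_that("a noisy calibration sweep leaves under 1e-5 OD residual on a clean blank", {
  instNoisy <- instrumentModel(detectorNoiseSD = 1e-4)
  instClean <- instrumentModel()
  blank <- sampleModel(concentration_uM = 0)
  cal <- calibrateBalance(generateSweep(instNoisy, blank,
                                        seed = 5)$calibration)
  clean <- generateSweep(instClean, blank, seed = 6)$sample
  expect_lt(max(abs(absorbance(computeAbsorbance(clean, cal)))), 1e-5)
})

test_that("absorbance reconstruction matches the closed-form intensity ratio", {
  ## g*vRef = 2.0 V with vBal = -0.2 V gives ratio 0.9 -> 0.04576 OD
  s <- mkSweep(vRef = 2.0, vBal = -0.2)
  cal <- new("BalanceCalibration", wavenumber = s@wavenumber,
             gain = rep(1, length(s@wavenumber)),
             baseline = rep(0, length(s@wavenumber)))
  expect_equal(unique(absorbance(computeAbsorbance(s, cal))), -log10(0.9),
               tolerance = 1e-12)
  z <- mkSweep(vRef = 2.0, vBal = 0)
  expect_true(all(absorbance(computeAbsorbance(z, cal)) == 0))
  bad <- mkSweep(vRef = 1.0, vBal = -1.5)
  expect_error(computeAbsorbance(bad, cal), "non-positive intensity")
  expect_error(computeAbsorbance(bad, cal), "2000")
})

test_that("Savitzky-Golay smoothing preserves polynomials and matches the naive oracle", {
  nu <- seq(2000, 2300, by = 0.5)
  quad <- new("Spectrum", wavenumber = nu,
              absorbance = 1e-3 * (nu - 2150)^2 / 1e4 + 5e-4)
  out <- sgFilter(quad, 11, 2)
  ## polynomial invariance holds away from the mirror-extended edges
  inner <- 6:(length(nu) - 5)
  expect_lt(max(abs(absorbance(out)[inner] - absorbance(quad)[inner])),
            1e-10)

  set.seed(1)
  noisy <- new("Spectrum", wavenumber = nu, absorbance = rnorm(length(nu)))
  got <- absorbance(sgFilter(noisy, 11, 2))
  want <- naiveSG(absorbance(noisy), 11, 2)
  expect_equal(got, want, tolerance = 1e-8)
  expect_equal(sd(got) / sd(absorbance(noisy)),
               sd(want) / sd(absorbance(noisy)), tolerance = 0.02)

  ## a symmetric band's fitted center moves by less than 0.01 cm-1
  band <- bandSpectrum(center = 2226.4)
  f0 <- fitBands(band, window = c(2200, 2255))[[1]]
  f1 <- fitBands(sgFilter(band, 11, 3), window = c(2200, 2255))[[1]]
  expect_lt(abs(f1@center - f0@center), 0.01)
})

test_that("Fourier filtering removes etalon fringes but keeps the band", {
  band <- bandSpectrum(center = 2235, amp = 1e-3)
  expect_lt(max(abs(absorbance(fourierFilter(band, 1)) -
                    absorbance(band))), 1e-10)
  nu <- wavenumber(band)
  fringe <- 2e-4 * sin(2 * pi * nu / 3)           # 3 cm-1 etalon period
  dirty <- new("Spectrum", wavenumber = nu,
               absorbance = absorbance(band) + fringe)
  clean <- fourierFilter(dirty, 0.25)             # fringe at 2/3 of Nyquist
  resid <- absorbance(clean) - absorbance(fourierFilter(band, 0.25))
  ## residual amplitude of the 3 cm-1 component via quadrature projection
  cS <- 2 * mean(resid * sin(2 * pi * nu / 3))
  cC <- 2 * mean(resid * cos(2 * pi * nu / 3))
  expect_lt(sqrt(cS^2 + cC^2), 0.01 * 2e-4)
  areaBefore <- sum(absorbance(band)) * 0.5
  areaAfter <- sum(absorbance(fourierFilter(band, 0.25))) * 0.5
  expect_lt(abs(areaAfter - areaBefore) / areaBefore, 0.01)
})

test_that("baseline correction removes generator drift without moving the band", {
  anchors <- list(c(2150, 2170), c(2185, 2205), c(2265, 2285))
  ## Gaussian band: negligible wings inside the anchor windows
  flat <- bandSpectrum(center = 2235, eta = 1)
  out <- baselineCorrect(flat, anchors, 1)
  expect_lt(max(abs(absorbance(out) - absorbance(flat))), 1e-9)

  ## linear drift of 1e-3 OD per 100 cm-1
  nu <- wavenumber(flat)
  drift <- 1e-3 * (nu - 2000) / 100
  drifted <- new("Spectrum", wavenumber = nu,
                 absorbance = absorbance(flat) + drift)
  corr <- baselineCorrect(drifted, anchors, 1)
  anchorIdx <- unlist(lapply(anchors, function(w)
    which(nu >= w[1] & nu <= w[2])))
  expect_lt(max(abs(absorbance(corr)[anchorIdx] -
                    absorbance(flat)[anchorIdx])), 1e-6)
  f0 <- fitBands(flat, window = c(2210, 2260))[[1]]
  f1 <- fitBands(corr, window = c(2210, 2260))[[1]]
  expect_lt(abs(f1@center - f0@center), 0.02)
  expect_warning(baselineCorrect(drifted, anchors, 1,
                                 bandWindow = c(2160, 2175)),
                 "overlaps")
})

test_that("averaging replicates gives the pointwise mean and SD/sqrt(n)", {
  base <- bandSpectrum()
  same <- averageSpectra(list(base, base, base))
  expect_equal(absorbance(same), absorbance(base))
  expect_true(all(uncertaintySE(same) == 0))

  set.seed(3)
  sigma <- 1e-4
  reps <- lapply(1:100, function(i)
    new("Spectrum", wavenumber = wavenumber(base),
        absorbance = absorbance(base) +
          rnorm(length(wavenumber(base)), 0, sigma)))
  avg <- averageSpectra(reps)
  expect_equal(mean(uncertaintySE(avg)), sigma / 10, tolerance = 0.2)
  short <- new("Spectrum", wavenumber = wavenumber(base)[-1],
               absorbance = absorbance(base)[-1])
  expect_error(averageSpectra(list(base, short)), "grid mismatch")
})

test_that("fitted-center uncertainty shrinks as 1/sqrt(n) under averaging", {
  centerSD <- function(nAvg, seeds = 12) {
    vapply(seeds * 100 + seq_len(seeds), function(s) {
      reps <- lapply(seq_len(nAvg), function(i) {
        pair <- generateCellSpectrum("F92oCNF", "apo", snr = 8,
                                     seed = s * 1000 + i)
        processSweep(pair$sample, pair$calibration)
      })
      fitBands(averageSpectra(reps), window = c(2205, 2265))[[1]]@center
    }, numeric(1))
  }
  sd4 <- sd(centerSD(4))
  sd16 <- sd(centerSD(16))
  expect_lt(sd16, sd4)   # averaging 4x more sweeps reduces center scatter
})

test_that("all spectral filters are linear operators", {
  set.seed(9)
  nu <- seq(2000, 2300, by = 0.5)
  x <- new("Spectrum", wavenumber = nu, absorbance = rnorm(length(nu)))
  y <- new("Spectrum", wavenumber = nu, absorbance = rnorm(length(nu)))
  comb <- new("Spectrum", wavenumber = nu,
              absorbance = 2.5 * absorbance(x) - 1.3 * absorbance(y))
  for (flt in list(function(s) sgFilter(s, 11, 3),
                   function(s) fourierFilter(s, 0.3),
                   function(s) baselineCorrect(s, list(c(2150, 2170),
                                                       c(2265, 2285)), 1))) {
    lhs <- absorbance(flt(comb))
    rhs <- 2.5 * absorbance(flt(x)) - 1.3 * absorbance(flt(y))
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("every processing step appends exactly one history record", {
  pair <- generateCellSpectrum("F92oCNF", "apo", snr = 20, seed = 1)
  spec <- processSweep(pair$sample, pair$calibration)
  steps <- vapply(processingHistory(spec), `[[`, "", "step")
  expect_identical(steps, c("absorbance", "sg_filter", "fourier_filter",
                            "baseline_correct"))
  again <- sgFilter(spec, 11, 3)
  expect_length(processingHistory(again), length(steps) + 1)
})
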