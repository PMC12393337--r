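## Synthetic instrument: balanced dual-beam sweeps with known ground truth.
##
## Forward model (per grid point, noiseless parts first):
##   I_arm(nu)  = P(nu) * (1 + f(nu)) * T_arm(nu),  T = 10^(-A)
##   V_ref(nu)  = g^-1 * I_blank(nu)            + detector noise
##   V_bal(nu)  = I_sample(nu) - I_blank(nu)    + detector noise
## f(nu) is the multiplicative source fluctuation, identical in both channels
## at each grid point (the QCL intensity noise that balancing cancels); g is
## the reference-channel gain imbalance, an instrument calibration setting
## carried in sweep metadata.

#' Construct an instrument model
#'
#' @param wavenumberStart,wavenumberStop,wavenumberStep sweep grid, cm^-1
#'   (default 2000-2300 at 0.5, the nitrile-window acquisition range).
#' @param laserPower function(nu) -> relative source intensity; default a
#'   broad smooth profile peaking mid-window.
#' @param sourceFluctuationSD relative SD of the correlated source
#'   fluctuation (default 0).
#' @param detectorNoiseSD additive detector noise SD, volts (default 0).
#' @param gainImbalance reference-channel gain factor g (default 1).
#' @param etalonAmplitude,etalonPeriod optional sinusoidal fringe on the
#'   sample cell's OD (default off, period 3 cm^-1).
#' @return an [InstrumentModel-class] object.
#' @export
instrumentModel <- function(wavenumberStart = 2000, wavenumberStop = 2300,
                            wavenumberStep = 0.5,
                            laserPower = function(nu)
                              0.8 + 0.4 * exp(-((nu - 2150) / 180)^2),
                            sourceFluctuationSD = 0,
                            detectorNoiseSD = 0,
                            gainImbalance = 1,
                            etalonAmplitude = 0,
                            etalonPeriod = 3) {
  new("InstrumentModel",
      wavenumberStart = wavenumberStart, wavenumberStop = wavenumberStop,
      wavenumberStep = wavenumberStep, laserPower = laserPower,
      sourceFluctuationSD = sourceFluctuationSD,
      detectorNoiseSD = detectorNoiseSD, gainImbalance = gainImbalance,
      etalonAmplitude = etalonAmplitude, etalonPeriod = etalonPeriod)
}

#' Construct a sample model
#'
#' @param bands data.frame(center_cm1, fwhm_cm1, peak_od_per_mM_cm,
#'   gauss_fraction); see [nitrileBand()].
#' @param concentration_uM analyte concentration, uM.
#' @param pathlength_um cell pathlength, um (Teflon spacers 50-250 um).
#' @param waterCenter_cm1,waterFwhm_cm1,waterOdPerUm water combination-band
#'   background: center (default 2100 cm^-1), width, peak OD per um of
#'   pathlength.
#' @param driftCoef polynomial baseline-drift coefficients (OD) in powers of
#'   (nu - 2150)/100; default none.
#' @return a [SampleModel-class] object.
#' @export
sampleModel <- function(bands = nitrileBand(), concentration_uM = 0,
                        pathlength_um = 250,
                        waterCenter_cm1 = 2100, waterFwhm_cm1 = 140,
                        waterOdPerUm = 0.0012,
                        driftCoef = numeric()) {
  new("SampleModel", bands = bands, concentration_uM = concentration_uM,
      pathlength_um = pathlength_um, waterCenter_cm1 = waterCenter_cm1,
      waterFwhm_cm1 = waterFwhm_cm1, waterOdPerUm = waterOdPerUm,
      driftCoef = driftCoef)
}

#' One-row band table for a nitrile absorber
#'
#' Default band strength 0.2 OD mM^-1 cm^-1 (a typical aromatic-nitrile
#' molar absorptivity of ~200 M^-1 cm^-1) and FWHM 10 cm^-1.
#'
#' @param center_cm1 band center, cm^-1 (default 2235, aqueous benzonitrile).
#' @param fwhm_cm1 full width at half maximum, cm^-1.
#' @param peak_od_per_mM_cm peak absorbance per mM per cm.
#' @param gauss_fraction pseudo-Voigt Gaussian fraction.
#' @return a one-row data.frame usable as the `bands` slot.
#' @export
nitrileBand <- function(center_cm1 = 2235, fwhm_cm1 = 10,
                        peak_od_per_mM_cm = 0.2, gauss_fraction = 0.5) {
  data.frame(center_cm1 = center_cm1, fwhm_cm1 = fwhm_cm1,
             peak_od_per_mM_cm = peak_od_per_mM_cm,
             gauss_fraction = gauss_fraction)
}

## Ground-truth decadic absorbance of a sample model on a grid.
sampleAbsorbance <- function(sample, nu) {
  A <- numeric(length(nu))
  b <- sample@bands
  cL <- (sample@concentration_uM / 1000) * (sample@pathlength_um * 1e-4)
  if (nrow(b) && cL > 0)
    for (i in seq_len(nrow(b)))
      A <- A + b$peak_od_per_mM_cm[i] * cL *
        pseudoVoigt(nu, b$center_cm1[i], b$fwhm_cm1[i], b$gauss_fraction[i])
  if (sample@waterOdPerUm > 0)
    A <- A + sample@waterOdPerUm * sample@pathlength_um *
      pseudoVoigt(nu, sample@waterCenter_cm1, sample@waterFwhm_cm1, 1)
  if (length(sample@driftCoef)) {
    z <- (nu - 2150) / 100
    A <- A + drop(outer(z, seq_along(sample@driftCoef) - 1, `^`) %*%
                    sample@driftCoef)
  }
  A
}

#' Simulate one balanced sweep pair (sample cell + blank-blank calibration)
#'
#' Emits the sample-cell record and the matching blank-blank calibration
#' record, both on the instrument grid, with the ground-truth differential
#' absorbance attached to the sample record.
#'
#' @param instrument an [InstrumentModel-class].
#' @param sample,blank [SampleModel-class] objects for the sample and blank
#'   cells; grids and pathlengths are taken from `instrument` and the models.
#' @param seed integer RNG seed for this acquisition.
#' @return list with elements `sample` and `calibration` ([RawSweep-class]);
#'   `sample@aTrue` holds the ground-truth absorbance the processing chain
#'   should recover (sample minus blank OD, plus any etalon fringe).
#' @export
generateSweep <- function(instrument, sample, blank = NULL, seed = 1) {
  validObject(instrument)
  validObject(sample)
  if (is.null(blank))
    blank <- sampleModel(bands = sample@bands, concentration_uM = 0,
                         pathlength_um = sample@pathlength_um,
                         waterCenter_cm1 = sample@waterCenter_cm1,
                         waterFwhm_cm1 = sample@waterFwhm_cm1,
                         waterOdPerUm = sample@waterOdPerUm)
  validObject(blank)
  if (abs(sample@pathlength_um - blank@pathlength_um) > 1e-9)
    stop("grid mismatch: sample and blank cells must share the pathlength")
  nu <- seq(instrument@wavenumberStart, instrument@wavenumberStop,
            by = instrument@wavenumberStep)
  P <- instrument@laserPower(nu)
  g <- instrument@gainImbalance

  aSample <- sampleAbsorbance(sample, nu)
  if (instrument@etalonAmplitude > 0)
    aSample <- aSample + instrument@etalonAmplitude *
      sin(2 * pi * nu / instrument@etalonPeriod)
  aBlank <- sampleAbsorbance(blank, nu)
  tS <- 10^(-aSample)
  tB <- 10^(-aBlank)

  withSeed(seed, {
    f <- if (instrument@sourceFluctuationSD > 0)
      rnorm(length(nu), 0, instrument@sourceFluctuationSD) else 0
    src <- P * (1 + f)
    mkNoise <- function() if (instrument@detectorNoiseSD > 0)
      rnorm(length(nu), 0, instrument@detectorNoiseSD) else 0
    vRefS <- src * tB / g + mkNoise()
    vBalS <- src * (tS - tB) + mkNoise()
    ## calibration acquisition: blank cells in both paths, fresh noise draw
    f2 <- if (instrument@sourceFluctuationSD > 0)
      rnorm(length(nu), 0, instrument@sourceFluctuationSD) else 0
    src2 <- P * (1 + f2)
    vRefC <- src2 * tB / g + mkNoise()
    vBalC <- 0 * nu + mkNoise()
  })

  meta <- list(pathlength_um = sample@pathlength_um, seed = seed, gain = g)
  list(
    sample = new("RawSweep", wavenumber = nu, vRef = vRefS, vBal = vBalS,
                 vRefQ = numeric(), vBalQ = numeric(),
                 metadata = c(meta, list(cell_id = "sample")),
                 aTrue = aSample - aBlank),
    calibration = new("RawSweep", wavenumber = nu, vRef = vRefC,
                      vBal = vBalC, vRefQ = numeric(), vBalQ = numeric(),
                      metadata = c(meta, list(cell_id = "blank-blank")),
                      aTrue = numeric())
  )
}

#' Simulate a Beer-Lambert calibration series
#'
#' One sweep pair per concentration level with identical noise statistics
#' across levels; the band amplitude is strictly proportional to
#' concentration before noise.
#'
#' @param concentrations_uM numeric vector of >= 3 concentration levels, uM.
#' @param instrument an [InstrumentModel-class].
#' @param sampleTemplate a [SampleModel-class]; its concentration slot is
#'   overwritten per level.
#' @param seed integer; level i uses seed + i.
#' @return list of sweep pairs as returned by [generateSweep()].
#' @export
generateCalibrationSeries <- function(concentrations_uM, instrument,
                                      sampleTemplate = sampleModel(),
                                      seed = 1) {
  if (length(concentrations_uM) < 3)
    stop("a calibration series needs at least 3 concentration levels")
  if (any(concentrations_uM < 0)) stop("concentrations must be >= 0")
  lapply(seq_along(concentrations_uM), function(i) {
    s <- sampleTemplate
    s@concentration_uM <- concentrations_uM[i]
    generateSweep(instrument, s, seed = seed + i)
  })
}

#' The packaged in-cell nitrile frequency fixture
#'
#' Apo centers, binding-induced shifts and derived holo centers for the
#' nitrile-labelled PYP variants, the C69A no-binding control, free oCNF in
#' water, sfGFP Y66oCNF and aqueous benzonitrile.
#'
#' @return data.frame: variant, apo_cm1, shift_cm1, holo_cm1, source.
#' @export
frequencyFixture <- function() {
  path <- system.file("extdata", "frequency_fixture.csv",
                      package = "nitrileIR", mustWork = TRUE)
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(abs(fx$holo_cm1 - (fx$apo_cm1 + fx$shift_cm1)) < 1e-9))
  fx
}

#' Simulate an in-cell nitrile spectrum acquisition
#'
#' Builds a cellular sample (default 140 uM probe, 250 um pathlength,
#' cellular baseline drift) with the band center taken from the frequency
#' fixture for the requested variant and condition, and detector noise set
#' so the raw absorbance signal-to-noise at the band peak equals `snr`.
#' The no-binding control condition uses the apo center regardless of
#' incubation (the C69A behaviour).
#'
#' @param variant fixture variant name, e.g. "F92oCNF".
#' @param condition "apo", "holo" or "no_binding_control".
#' @param fixture fixture table, default [frequencyFixture()].
#' @param snr peak absorbance over raw absorbance-noise SD; > 0.
#' @param seed integer seed.
#' @param concentration_uM probe concentration (default 140 uM, the
#'   estimated in-cell working concentration).
#' @param pathlength_um cell pathlength (default 250 um).
#' @param instrument optional [InstrumentModel-class]; detector noise is
#'   overridden from `snr`.
#' @return sweep pair list as from [generateSweep()], with the true band
#'   center in `$center_cm1`.
#' @export
generateCellSpectrum <- function(variant, condition = c("apo", "holo",
                                                        "no_binding_control"),
                                 fixture = frequencyFixture(), snr = 20,
                                 seed = 1, concentration_uM = 140,
                                 pathlength_um = 250, instrument = NULL) {
  condition <- match.arg(condition)
  if (snr <= 0) stop("snr must be > 0")
  row <- fixture[fixture$variant == variant, , drop = FALSE]
  if (nrow(row) != 1)
    stop("unknown variant '", variant, "' in frequency fixture")
  center <- switch(condition,
                   apo = row$apo_cm1,
                   holo = row$holo_cm1,
                   no_binding_control = row$apo_cm1)

  sample <- sampleModel(
    bands = nitrileBand(center_cm1 = center),
    concentration_uM = concentration_uM, pathlength_um = pathlength_um,
    driftCoef = c(2e-4, -1.5e-4, 5e-5))
  peakA <- sample@bands$peak_od_per_mM_cm[1] *
    (concentration_uM / 1000) * (pathlength_um * 1e-4)

  if (is.null(instrument)) instrument <- instrumentModel()
  nuC <- center
  iBlankAtPeak <- instrument@laserPower(nuC) *
    10^(-sampleAbsorbance(sampleModel(concentration_uM = 0,
                                      pathlength_um = pathlength_um), nuC))
  instrument@detectorNoiseSD <- (peakA / snr) * log(10) * iBlankAtPeak

  out <- generateSweep(instrument, sample, seed = seed)
  out$center_cm1 <- center
  out$variant <- variant
  out$condition <- condition
  out
}
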