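#' @import methods
NULL

## ---------------------------------------------------------------------------
## Instrument / sample models (synthetic-data ground truth)
## ---------------------------------------------------------------------------

#' Instrument model for the balanced dual-beam QCL simulator
#'
#' Describes the tunable-laser sweep grid, source power profile, the
#' multiplicative source fluctuation shared by both detection channels,
#' per-channel additive detector noise, the reference-channel gain imbalance
#' and an optional etalon fringe.
#'
#' @slot wavenumberStart,wavenumberStop,wavenumberStep sweep grid, cm^-1.
#' @slot laserPower function(nu) -> relative intensity (smooth, positive).
#' @slot sourceFluctuationSD relative SD of the multiplicative source
#'   fluctuation, identical in both channels at each grid point.
#' @slot detectorNoiseSD additive detector noise SD, volts, independent per
#'   channel.
#' @slot gainImbalance dimensionless reference-channel gain factor g.
#' @slot etalonAmplitude,etalonPeriod sinusoidal fringe added to the sample
#'   cell's optical density (OD, cm^-1 period); amplitude 0 disables it.
#' @exportClass InstrumentModel
setClass("InstrumentModel",
  representation(
    wavenumberStart = "numeric",
    wavenumberStop = "numeric",
    wavenumberStep = "numeric",
    laserPower = "function",
    sourceFluctuationSD = "numeric",
    detectorNoiseSD = "numeric",
    gainImbalance = "numeric",
    etalonAmplitude = "numeric",
    etalonPeriod = "numeric"
  )
)

setValidity("InstrumentModel", function(object) {
  msg <- character()
  if (object@wavenumberStep <= 0) msg <- c(msg, "wavenumberStep must be > 0")
  if (object@wavenumberStart >= object@wavenumberStop)
    msg <- c(msg, "wavenumberStart must be < wavenumberStop")
  if (object@sourceFluctuationSD < 0 || object@detectorNoiseSD < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@gainImbalance <= 0) msg <- c(msg, "gainImbalance must be > 0")
  if (object@etalonAmplitude < 0) msg <- c(msg, "etalonAmplitude must be >= 0")
  if (object@etalonPeriod <= 0) msg <- c(msg, "etalonPeriod must be > 0")
  nu <- seq(object@wavenumberStart, object@wavenumberStop,
            by = object@wavenumberStep)
  p <- object@laserPower(nu)
  if (any(!is.finite(p)) || any(p <= 0))
    msg <- c(msg, "laser power profile must be strictly positive on the grid")
  if (length(msg)) msg else TRUE
})

#' Sample model: Beer-Lambert bands plus cell background
#'
#' A liquid/cell sample as seen by the simulator: a set of pseudo-Voigt
#' nitrile bands, the water combination-band background near 2100 cm^-1,
#' and a polynomial baseline drift (cellular background).
#'
#' @slot bands data.frame with columns center_cm1, fwhm_cm1,
#'   peak_od_per_mM_cm (peak absorbance per mM per cm), gauss_fraction.
#' @slot concentration_uM analyte concentration, micromolar.
#' @slot pathlength_um cell pathlength, micrometres.
#' @slot waterCenter_cm1,waterFwhm_cm1,waterOdPerUm water combination band:
#'   center, width and peak OD per micrometre of pathlength.
#' @slot driftCoef polynomial baseline-drift coefficients (OD), in powers of
#'   (nu - 2150)/100.
#' @exportClass SampleModel
setClass("SampleModel",
  representation(
    bands = "data.frame",
    concentration_uM = "numeric",
    pathlength_um = "numeric",
    waterCenter_cm1 = "numeric",
    waterFwhm_cm1 = "numeric",
    waterOdPerUm = "numeric",
    driftCoef = "numeric"
  )
)

setValidity("SampleModel", function(object) {
  msg <- character()
  b <- object@bands
  need <- c("center_cm1", "fwhm_cm1", "peak_od_per_mM_cm", "gauss_fraction")
  if (!all(need %in% names(b)))
    msg <- c(msg, paste("bands must have columns", paste(need, collapse = ", ")))
  else {
    if (nrow(b) && any(b$fwhm_cm1 <= 0)) msg <- c(msg, "band fwhm must be > 0")
    if (nrow(b) && any(b$gauss_fraction < 0 | b$gauss_fraction > 1))
      msg <- c(msg, "gauss_fraction must lie in [0, 1]")
  }
  if (object@pathlength_um <= 0) msg <- c(msg, "pathlength must be > 0")
  if (object@concentration_uM < 0) msg <- c(msg, "concentration must be >= 0")
  if (object@waterOdPerUm < 0) msg <- c(msg, "water band amplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Sweeps, calibration, spectra
## ---------------------------------------------------------------------------

#' Raw dual-channel laser sweep
#'
#' One demodulated sweep of the balanced spectrometer: the wavenumber grid,
#' the reference-channel voltage (blank path), the balanced-channel voltage
#' (sample minus blank path) and, optionally, the quadrature components of
#' each channel from the lock-in. When the record comes from the synthetic
#' generator, the ground-truth absorbance is carried in `aTrue`.
#'
#' @slot wavenumber strictly increasing grid, cm^-1.
#' @slot vRef,vBal in-phase channel voltages, V.
#' @slot vRefQ,vBalQ quadrature channel voltages, V (zero when the lock-in
#'   exported magnitudes only).
#' @slot metadata named list (pathlength_um, cell_id, seed, gain, ...).
#' @slot aTrue ground-truth absorbance (OD) for synthetic records, else
#'   length 0.
#' @exportClass RawSweep
setClass("RawSweep",
  representation(
    wavenumber = "numeric",
    vRef = "numeric",
    vBal = "numeric",
    vRefQ = "numeric",
    vBalQ = "numeric",
    metadata = "list",
    aTrue = "numeric"
  ),
  prototype(metadata = list(), aTrue = numeric())
)

setValidity("RawSweep", function(object) {
  msg <- character()
  n <- length(object@wavenumber)
  if (length(object@vRef) != n || length(object@vBal) != n)
    msg <- c(msg, "wavenumber, vRef and vBal must have equal length")
  if (length(object@vRefQ) && length(object@vRefQ) != n)
    msg <- c(msg, "vRefQ length mismatch")
  if (length(object@vBalQ) && length(object@vBalQ) != n)
    msg <- c(msg, "vBalQ length mismatch")
  if (n > 1 && any(diff(object@wavenumber) <= 0))
    msg <- c(msg, "wavenumber grid must be strictly increasing")
  if (length(object@aTrue) && length(object@aTrue) != n)
    msg <- c(msg, "aTrue length mismatch")
  if (length(msg)) msg else TRUE
})

#' Balance calibration derived from a blank-blank sweep
#'
#' Per-grid-point gain factor g(nu) used to reconstruct the blank-path beam
#' intensity from the reference channel, plus a residual baseline A0(nu)
#' measured on the blank-blank calibration record.
#'
#' @slot wavenumber grid, cm^-1.
#' @slot gain g(nu), dimensionless, > 0.
#' @slot baseline residual absorbance structure A0(nu), OD.
#' @exportClass BalanceCalibration
setClass("BalanceCalibration",
  representation(wavenumber = "numeric", gain = "numeric",
                 baseline = "numeric")
)

setValidity("BalanceCalibration", function(object) {
  msg <- character()
  n <- length(object@wavenumber)
  if (length(object@gain) != n || length(object@baseline) != n)
    msg <- c(msg, "gain and baseline must match the grid length")
  if (any(object@gain <= 0)) msg <- c(msg, "gain must be > 0 everywhere")
  if (length(msg)) msg else TRUE
})

#' Absorbance spectrum with processing history
#'
#' @slot wavenumber grid, cm^-1.
#' @slot absorbance decadic absorbance, OD.
#' @slot se optional per-point standard error, OD (length 0 when absent).
#' @slot history append-only list of processing-step records, each a list
#'   with elements `step` and `params`.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavenumber = "numeric", absorbance = "numeric",
                 se = "numeric", history = "list"),
  prototype(se = numeric(), history = list())
)

setValidity("Spectrum", function(object) {
  msg <- character()
  n <- length(object@wavenumber)
  if (length(object@absorbance) != n)
    msg <- c(msg, "absorbance must match the grid length")
  if (length(object@se) && length(object@se) != n)
    msg <- c(msg, "se must be empty or match the grid length")
  if (n > 1 && any(diff(object@wavenumber) <= 0))
    msg <- c(msg, "wavenumber grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Processing configuration for the sweep -> spectrum chain
#'
#' @slot phaseDeg lock-in phase error to correct, degrees in (-180, 180].
#' @slot sgWindow,sgOrder Savitzky-Golay window (odd points) and polynomial
#'   order; window NA disables the filter.
#' @slot fourierCutoff low-pass cutoff as a fraction of Nyquist in the
#'   Fourier-conjugate domain of the wavenumber axis; NA disables.
#' @slot baselineOrder,baselineAnchors baseline polynomial order and anchor
#'   windows (list of c(lo, hi) cm^-1); empty list disables.
#' @exportClass ProcessingConfig
setClass("ProcessingConfig",
  representation(phaseDeg = "numeric", sgWindow = "numeric",
                 sgOrder = "numeric", fourierCutoff = "numeric",
                 baselineOrder = "numeric", baselineAnchors = "list")
)

setValidity("ProcessingConfig", function(object) {
  msg <- character()
  if (!is.na(object@sgWindow)) {
    if (object@sgWindow %% 2 != 1) msg <- c(msg, "sgWindow must be odd")
    if (object@sgWindow <= object@sgOrder)
      msg <- c(msg, "sgWindow must exceed sgOrder")
  }
  if (!is.na(object@fourierCutoff) &&
      (object@fourierCutoff <= 0 || object@fourierCutoff > 1))
    msg <- c(msg, "fourierCutoff must lie in (0, 1]")
  if (object@phaseDeg <= -180 || object@phaseDeg > 180)
    msg <- c(msg, "phaseDeg must lie in (-180, 180]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Band fits and shifts
## ---------------------------------------------------------------------------

#' Fitted band parameters with uncertainties
#'
#' @slot center,centerSE band center, cm^-1, with standard error.
#' @slot fwhm,fwhmSE full width at half maximum, cm^-1.
#' @slot amplitude,amplitudeSE peak absorbance, OD.
#' @slot gaussFraction pseudo-Voigt Gaussian weight in [0, 1].
#' @slot area integrated band area, OD cm^-1.
#' @slot window fit window, c(lo, hi) cm^-1.
#' @slot residRMS RMS of fit residuals, OD.
#' @slot converged logical convergence flag.
#' @slot note diagnostic note (e.g. ambiguous candidates), "" when clean.
#' @exportClass BandFit
setClass("BandFit",
  representation(center = "numeric", centerSE = "numeric",
                 fwhm = "numeric", fwhmSE = "numeric",
                 amplitude = "numeric", amplitudeSE = "numeric",
                 gaussFraction = "numeric", area = "numeric",
                 window = "numeric", residRMS = "numeric",
                 converged = "logical", note = "character"),
  prototype(note = "")
)

setValidity("BandFit", function(object) {
  msg <- character()
  if (object@converged) {
    if (object@fwhm <= 0) msg <- c(msg, "fwhm must be > 0")
    if (length(object@window) == 2 &&
        (object@center < object@window[1] || object@center > object@window[2]))
      msg <- c(msg, "center must lie inside the fit window")
    if (any(c(object@centerSE, object@fwhmSE, object@amplitudeSE) < 0,
            na.rm = TRUE))
      msg <- c(msg, "standard errors must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Apo -> holo frequency-shift result
#'
#' @slot shift center_b - center_a, cm^-1.
#' @slot uncertainty quadrature-propagated SE, cm^-1.
#' @slot variant,conditionA,conditionB labels.
#' @exportClass ShiftResult
setClass("ShiftResult",
  representation(shift = "numeric", uncertainty = "numeric",
                 variant = "character", conditionA = "character",
                 conditionB = "character"),
  prototype(variant = NA_character_, conditionA = "a", conditionB = "b")
)

## ---------------------------------------------------------------------------
## Calibration / LOD
## ---------------------------------------------------------------------------

#' Concentration-response calibration series with fitted line
#'
#' @slot concentration_uM,response concentration levels (uM) and responses
#'   (OD peak height by default).
#' @slot pathlength_um cell pathlength, um.
#' @slot slope,slopeSE,intercept,interceptSE ordinary-least-squares line.
#' @slot sigmaResid residual SD (n - 2 denominator), response units.
#' @slot responseMetric "height" or "area".
#' @exportClass CalibrationSeries
setClass("CalibrationSeries",
  representation(concentration_uM = "numeric", response = "numeric",
                 pathlength_um = "numeric",
                 slope = "numeric", slopeSE = "numeric",
                 intercept = "numeric", interceptSE = "numeric",
                 sigmaResid = "numeric", responseMetric = "character"),
  prototype(slope = NA_real_, slopeSE = NA_real_, intercept = NA_real_,
            interceptSE = NA_real_, sigmaResid = NA_real_,
            responseMetric = "height")
)

setValidity("CalibrationSeries", function(object) {
  msg <- character()
  if (length(object@concentration_uM) != length(object@response))
    msg <- c(msg, "concentration and response must have equal length")
  if (length(object@concentration_uM) < 3)
    msg <- c(msg, "a calibration series needs at least 3 levels")
  if (any(object@concentration_uM < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Limit-of-detection result
#'
#' @slot lod_uM limit of detection, uM.
#' @slot factor multiplier in lod = factor * sigma / slope (3.3 default).
#' @slot sigmaResid,slope inputs the LOD was derived from.
#' @slot pathlength_um pathlength of the underlying series, um.
#' @exportClass LodResult
setClass("LodResult",
  representation(lod_uM = "numeric", factor = "numeric",
                 sigmaResid = "numeric", slope = "numeric",
                 pathlength_um = "numeric")
)

## ---------------------------------------------------------------------------
## Trajectories and field analysis
## ---------------------------------------------------------------------------

#' Two-state probe-environment trajectory model
#'
#' Ground-truth generative model for a nitrile probe that exchanges between a
#' hydrogen-bonded state (donor close to the nitrile nitrogen, oriented) and
#' a free state (donor far), following a two-state Markov chain started from
#' its stationary distribution.
#'
#' @slot nFrames,nReplicates frame count and replicate count (frames are per
#'   replicate; replicates are independent chains).
#' @slot occupancy stationary hydrogen-bonded probability p in [0, 1].
#' @slot switchScale Markov switching scale s in (0, 1]; transition
#'   probabilities are free->bonded s*p and bonded->free s*(1-p).
#' @slot bondedDistance_A,freeDistance_A N...D heavy-atom distance in the
#'   two states, Angstrom (bonded < free).
#' @slot donorChargeD_e,donorChargeH_e donor heavy-atom and hydrogen partial
#'   charges, e.
#' @slot backgroundCharge_e,backgroundDistance_A fixed axial background
#'   charge (e) and its distance beyond N (Angstrom), setting the free-state
#'   field level.
#' @slot nSolvent,solventCharge_e,solventShell_A solvent shell: charge count,
#'   magnitude (alternating sign), mean shell radius.
#' @slot jitterSD_A per-frame positional jitter SD, Angstrom.
#' @slot stateMeans_MVcm named c(bonded=, free=) noiseless-geometry
#'   projected-field means, MV/cm (ground truth).
#' @exportClass TrajectoryModel
setClass("TrajectoryModel",
  representation(
    nFrames = "numeric", nReplicates = "numeric",
    occupancy = "numeric", switchScale = "numeric",
    bondedDistance_A = "numeric", freeDistance_A = "numeric",
    donorChargeD_e = "numeric", donorChargeH_e = "numeric",
    backgroundCharge_e = "numeric", backgroundDistance_A = "numeric",
    nSolvent = "numeric", solventCharge_e = "numeric",
    solventShell_A = "numeric", jitterSD_A = "numeric",
    stateMeans_MVcm = "numeric"
  )
)

setValidity("TrajectoryModel", function(object) {
  msg <- character()
  if (object@occupancy < 0 || object@occupancy > 1)
    msg <- c(msg, "occupancy must lie in [0, 1]")
  if (object@switchScale <= 0 || object@switchScale > 1)
    msg <- c(msg, "switchScale must lie in (0, 1]")
  if (object@bondedDistance_A >= object@freeDistance_A)
    msg <- c(msg, "bonded-state distance must be < free-state distance")
  if (object@nFrames < 1 || object@nReplicates < 1)
    msg <- c(msg, "nFrames and nReplicates must be >= 1")
  if (object@jitterSD_A < 0) msg <- c(msg, "jitterSD_A must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Coordinate trajectory with charges and ground-truth state labels
#'
#' @slot coords numeric array [nAtoms, 3, nFrames], Angstrom.
#' @slot charges data.frame: atom_index, charge_e, role (probe_C, probe_N,
#'   donor_D, donor_H, solvent, background), element.
#' @slot stateLabels character per frame ("bonded"/"free"); ground truth for
#'   synthetic trajectories, length 0 otherwise.
#' @slot replicate integer replicate id per frame.
#' @slot truth named list of generative ground truth (occupancy, state
#'   means), empty for real data.
#' @exportClass ProbeTrajectory
setClass("ProbeTrajectory",
  representation(coords = "array", charges = "data.frame",
                 stateLabels = "character", replicate = "integer",
                 truth = "list"),
  prototype(stateLabels = character(), truth = list())
)

setValidity("ProbeTrajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msg <- c(msg, "coords must be an [nAtoms, 3, nFrames] array")
  else {
    if (nrow(object@charges) != d[1])
      msg <- c(msg, "charges must have one row per atom")
    if (length(object@replicate) != d[3])
      msg <- c(msg, "replicate must have one entry per frame")
    if (length(object@stateLabels) &&
        length(object@stateLabels) != d[3])
      msg <- c(msg, "stateLabels must be empty or one per frame")
  }
  if (!all(c("atom_index", "charge_e", "role") %in% names(object@charges)))
    msg <- c(msg, "charges needs columns atom_index, charge_e, role")
  if (length(msg)) msg else TRUE
})

#' Hydrogen-bond geometric criteria
#'
#' @slot distanceCutoff_A acceptor-N to donor-heavy-atom cutoff, Angstrom
#'   (inclusive; default 4.0).
#' @slot angleCutoff_deg angular cutoff, degrees (inclusive; default 30).
#' @slot angleVertex "donor" (angle between D->H and D->A at the donor heavy
#'   atom) or "hydrogen" (deviation of the D-H...A angle from linearity).
#' @slot donorElements donor heavy-atom element whitelist.
#' @exportClass HBondCriteria
setClass("HBondCriteria",
  representation(distanceCutoff_A = "numeric", angleCutoff_deg = "numeric",
                 angleVertex = "character", donorElements = "character")
)

setValidity("HBondCriteria", function(object) {
  msg <- character()
  if (object@distanceCutoff_A <= 0 || object@angleCutoff_deg <= 0)
    msg <- c(msg, "cutoffs must be > 0")
  if (!object@angleVertex %in% c("donor", "hydrogen"))
    msg <- c(msg, "angleVertex must be 'donor' or 'hydrogen'")
  if (length(msg)) msg else TRUE
})

#' State-resolved projected-field summary
#'
#' @slot stateMeans,stateSDs named (bonded/free) means and SDs, MV/cm.
#' @slot populations named state fractions, summing to 1.
#' @slot overallMean pooled mean field over all frames, MV/cm.
#' @slot replicateMeans per-replicate mean fields, MV/cm.
#' @slot aggregateMean mean of replicate means, MV/cm.
#' @slot histBreaks,histCounts field histogram (MV/cm bin edges, counts).
#' @slot criteria the HBondCriteria used (recorded for provenance).
#' @exportClass FieldSummary
setClass("FieldSummary",
  representation(stateMeans = "numeric", stateSDs = "numeric",
                 populations = "numeric", overallMean = "numeric",
                 replicateMeans = "numeric", aggregateMean = "numeric",
                 histBreaks = "numeric", histCounts = "numeric",
                 criteria = "HBondCriteria")
)

setValidity("FieldSummary", function(object) {
  msg <- character()
  if (abs(sum(object@populations) - 1) > 1e-9)
    msg <- c(msg, "state populations must sum to 1")
  w <- sum(object@populations * object@stateMeans[names(object@populations)],
           na.rm = TRUE)
  if (is.finite(w) && abs(w - object@overallMean) > 1e-9)
    msg <- c(msg, "overall mean must equal the population-weighted state means")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Structures and assay reports
## ---------------------------------------------------------------------------

#' Atomic structure model (PDB-derived)
#'
#' @slot atoms data.frame: eleno, elety, resid, resno, chain, x, y, z,
#'   occupancy, element.
#' @slot sourceId accession / filename the structure came from.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame", sourceId = "character"),
  prototype(sourceId = NA_character_)
)

setValidity("StructureModel", function(object) {
  msg <- character()
  need <- c("elety", "resid", "resno", "chain", "x", "y", "z", "element")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns", paste(need, collapse = ", ")))
  else if (nrow(object@atoms) &&
           !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Binding-assay report
#'
#' @slot results data.frame: variant, apo_center, apo_se, holo_center,
#'   holo_se, shift, uncertainty, call, failed, note.
#' @slot threshold_cm1 absolute shift threshold for a binding call.
#' @slot kSigma uncertainty multiple a shift must also exceed.
#' @slot metadata run metadata (seed, snr, nSeeds, ...).
#' @exportClass AssayReport
setClass("AssayReport",
  representation(results = "data.frame", threshold_cm1 = "numeric",
                 kSigma = "numeric", metadata = "list"),
  prototype(metadata = list())
)
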