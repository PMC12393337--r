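## Plain-text interchange: sweep/spectrum CSV, trajectory XYZ, charge
## tables, band-fit JSON.

#' Write / read a raw sweep as CSV
#'
#' Columns wavenumber_cm1, v_ref_V, v_bal_V; metadata as leading
#' `# key=value` comment lines.
#'
#' @param sweep a [RawSweep-class].
#' @param path file path.
#' @return `writeSweepCSV`: the path, invisibly; `readSweepCSV`: a
#'   [RawSweep-class].
#' @export
writeSweepCSV <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sweep@metadata
  for (k in names(meta))
    if (is.atomic(meta[[k]]) && length(meta[[k]]) == 1)
      writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  utils::write.csv(data.frame(wavenumber_cm1 = sweep@wavenumber,
                              v_ref_V = sweep@vRef, v_bal_V = sweep@vBal),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSweepCSV
#' @export
readSweepCSV <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in metaLines) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(kv[2]))
      meta[[trimws(kv[1])]] <- if (is.na(val)) trimws(kv[2]) else val
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  new("RawSweep", wavenumber = df$wavenumber_cm1, vRef = df$v_ref_V,
      vBal = df$v_bal_V, vRefQ = numeric(), vBalQ = numeric(),
      metadata = meta, aTrue = numeric())
}

#' Write / read a spectrum as CSV
#'
#' Columns wavenumber_cm1, absorbance_OD and, when present, se_OD.
#'
#' @param spec a [Spectrum-class].
#' @param path file path.
#' @return `writeSpectrumCSV`: the path, invisibly; `readSpectrumCSV`: a
#'   [Spectrum-class].
#' @export
writeSpectrumCSV <- function(spec, path) {
  df <- data.frame(wavenumber_cm1 = spec@wavenumber,
                   absorbance_OD = spec@absorbance)
  if (length(spec@se)) df$se_OD <- spec@se
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumCSV
#' @export
readSpectrumCSV <- function(path) {
  df <- utils::read.csv(path)
  new("Spectrum", wavenumber = df$wavenumber_cm1,
      absorbance = df$absorbance_OD,
      se = if (!is.null(df$se_OD)) df$se_OD else numeric(),
      history = list(list(step = "read_csv", params = list(path = path))))
}

#' Write / read a trajectory as multi-frame XYZ plus charge table
#'
#' XYZ: per frame an atom count line, a comment line, then
#' `element x y z` (Angstrom). Charge table CSV: atom_index, charge_e,
#' role, element. State labels CSV: frame_index, state.
#'
#' @param traj a [ProbeTrajectory-class].
#' @param xyzPath,chargePath,labelPath file paths (label path optional).
#' @return `writeTrajectoryXYZ`: the xyz path, invisibly;
#'   `readTrajectoryXYZ`: a [ProbeTrajectory-class].
#' @export
writeTrajectoryXYZ <- function(traj, xyzPath, chargePath = NULL,
                               labelPath = NULL) {
  nA <- dim(traj@coords)[1]
  nF <- dim(traj@coords)[3]
  el <- if (!is.null(traj@charges$element)) traj@charges$element
        else rep("X", nA)
  con <- file(xyzPath, "w")
  on.exit(close(con))
  for (f in seq_len(nF)) {
    writeLines(as.character(nA), con)
    writeLines(sprintf("frame %d replicate %d", f, traj@replicate[f]), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el,
                       traj@coords[, 1, f], traj@coords[, 2, f],
                       traj@coords[, 3, f]), con)
  }
  if (!is.null(chargePath))
    utils::write.csv(traj@charges, chargePath, row.names = FALSE)
  if (!is.null(labelPath) && length(traj@stateLabels))
    utils::write.csv(data.frame(frame_index = seq_len(nF),
                                state = traj@stateLabels),
                     labelPath, row.names = FALSE)
  invisible(xyzPath)
}

#' @rdname writeTrajectoryXYZ
#' @param replicate optional per-frame replicate ids for `readTrajectoryXYZ`
#'   (default: all frames one replicate).
#' @export
readTrajectoryXYZ <- function(xyzPath, chargePath, labelPath = NULL,
                              replicate = NULL) {
  lines <- readLines(xyzPath)
  charges <- utils::read.csv(chargePath, stringsAsFactors = FALSE)
  nA <- as.integer(lines[1])
  stride <- nA + 2L
  nF <- length(lines) %/% stride
  coords <- array(NA_real_, dim = c(nA, 3, nF))
  for (f in seq_len(nF)) {
    block <- lines[((f - 1L) * stride + 3L):((f - 1L) * stride + 2L + nA)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), function(p)
      as.numeric(p[2:4])))
    coords[, , f] <- m
  }
  labels <- character()
  if (!is.null(labelPath))
    labels <- utils::read.csv(labelPath, stringsAsFactors = FALSE)$state
  if (is.null(replicate)) replicate <- rep(1L, nF)
  new("ProbeTrajectory", coords = coords, charges = charges,
      stateLabels = labels, replicate = as.integer(replicate),
      truth = list())
}

#' Serialize a band fit to JSON
#'
#' @param fit a [BandFit-class].
#' @param path file path.
#' @return `writeBandFitJSON`: the path, invisibly; `readBandFitJSON`: a
#'   [BandFit-class].
#' @export
writeBandFitJSON <- function(fit, path) {
  x <- list(center = fit@center, centerSE = fit@centerSE, fwhm = fit@fwhm,
            fwhmSE = fit@fwhmSE, amplitude = fit@amplitude,
            amplitudeSE = fit@amplitudeSE, gaussFraction = fit@gaussFraction,
            area = fit@area, window = fit@window, residRMS = fit@residRMS,
            converged = fit@converged, note = fit@note)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBandFitJSON
#' @export
readBandFitJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("BandFit", center = x$center, centerSE = x$centerSE, fwhm = x$fwhm,
      fwhmSE = x$fwhmSE, amplitude = x$amplitude,
      amplitudeSE = x$amplitudeSE, gaussFraction = x$gaussFraction,
      area = x$area, window = as.numeric(x$window), residRMS = x$residRMS,
      converged = x$converged, note = x$note %||% "")
}
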