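#' Accessor generics
#'
#' Small accessor generics shared by the sweep/spectrum/fit classes, so user
#' code never reaches into slots.
#'
#' @param object an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumber", function(object) standardGeneric("wavenumber"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("uncertaintySE", function(object) standardGeneric("uncertaintySE"))

#' @rdname accessors
#' @export
setGeneric("processingHistory",
           function(object) standardGeneric("processingHistory"))

#' @rdname accessors
#' @export
setGeneric("bandCenter", function(object) standardGeneric("bandCenter"))

#' @rdname accessors
#' @export
setGeneric("bandFWHM", function(object) standardGeneric("bandFWHM"))

#' @rdname accessors
#' @export
setGeneric("bandAmplitude", function(object) standardGeneric("bandAmplitude"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("shiftValue", function(object) standardGeneric("shiftValue"))

#' @rdname accessors
#' @export
setGeneric("lodValue", function(object) standardGeneric("lodValue"))

#' @rdname accessors
#' @export
setGeneric("structureAtoms", function(object) standardGeneric("structureAtoms"))

#' @rdname accessors
#' @export
setGeneric("assayResults", function(object) standardGeneric("assayResults"))

setMethod("wavenumber", "RawSweep", function(object) object@wavenumber)
setMethod("wavenumber", "Spectrum", function(object) object@wavenumber)
setMethod("wavenumber", "BalanceCalibration", function(object) object@wavenumber)
setMethod("absorbance", "Spectrum", function(object) object@absorbance)
setMethod("uncertaintySE", "Spectrum", function(object) object@se)
setMethod("processingHistory", "Spectrum", function(object) object@history)
setMethod("bandCenter", "BandFit", function(object)
  c(value = object@center, se = object@centerSE))
setMethod("bandFWHM", "BandFit", function(object)
  c(value = object@fwhm, se = object@fwhmSE))
setMethod("bandAmplitude", "BandFit", function(object)
  c(value = object@amplitude, se = object@amplitudeSE))
setMethod("isConverged", "BandFit", function(object) object@converged)
setMethod("shiftValue", "ShiftResult", function(object)
  c(shift = object@shift, se = object@uncertainty))
setMethod("lodValue", "LodResult", function(object) object@lod_uM)
setMethod("structureAtoms", "StructureModel", function(object) object@atoms)
setMethod("assayResults", "AssayReport", function(object) object@results)

## show methods -------------------------------------------------------------

setMethod("show", "RawSweep", function(object) {
  cat(sprintf("RawSweep: %d points, %.1f-%.1f cm-1\n",
              length(object@wavenumber), min(object@wavenumber),
              max(object@wavenumber)))
  if (!is.null(object@metadata$cell_id))
    cat("  cell_id:", object@metadata$cell_id, "\n")
  if (length(object@aTrue)) cat("  carries ground-truth absorbance\n")
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.1f-%.1f cm-1, peak %.2e OD\n",
              length(object@wavenumber), min(object@wavenumber),
              max(object@wavenumber),
              if (length(object@absorbance)) max(object@absorbance) else NA))
  if (length(object@history))
    cat("  history:", paste(vapply(object@history, `[[`, "", "step"),
                            collapse = " -> "), "\n")
})

setMethod("show", "BandFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "BandFit: center %.2f +/- %.3f cm-1, FWHM %.2f, amp %.3e OD\n",
      object@center, object@centerSE, object@fwhm, object@amplitude))
  else
    cat("BandFit: not converged", if (nzchar(object@note))
      paste0("(", object@note, ")"), "\n")
})

setMethod("show", "ShiftResult", function(object) {
  cat(sprintf("ShiftResult [%s]: %+.2f +/- %.2f cm-1 (%s -> %s)\n",
              object@variant, object@shift, object@uncertainty,
              object@conditionA, object@conditionB))
})

setMethod("show", "LodResult", function(object) {
  cat(sprintf("LOD: %.2f uM (factor %.1f, slope %.3e, sigma %.3e)\n",
              object@lod_uM, object@factor, object@slope, object@sigmaResid))
})

setMethod("show", "FieldSummary", function(object) {
  cat("FieldSummary (MV/cm):\n")
  for (s in names(object@stateMeans))
    cat(sprintf("  %s: mean %.1f, sd %.1f, population %.3f\n", s,
                object@stateMeans[s], object@stateSDs[s],
                object@populations[s]))
  cat(sprintf("  overall %.1f; replicate aggregate %.1f (n=%d replicates)\n",
              object@overallMean, object@aggregateMean,
              length(object@replicateMeans)))
})

setMethod("show", "AssayReport", function(object) {
  cat("AssayReport (threshold", object@threshold_cm1, "cm-1, k =",
      object@kSigma, "):\n")
  print(object@results, row.names = FALSE)
})
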