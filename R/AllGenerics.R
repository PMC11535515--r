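#' Accessors for macromech objects
#'
#' `frames()` returns the per-frame table of a [FieldProtocol-class] or
#' [PinchRecording-class]; `groundTruth()` the generator ground-truth list;
#' `beadDiameter()` the bead diameter (um); `curvePoints()` the point table
#' of a [StressStrainCurve-class]; `eTan()` the fitted tangential modulus;
#' `alphaMean()`, `alphaSd()` and `staticForce()` the components of a
#' [BWFit-class].
#'
#' @param object a macromech S4 object.
#' @return The slot value (a data.frame, numeric or list, see above).
#' @name accessors
#' @examples
#' prot <- genFieldProtocol(nCycles = 2)
#' head(frames(prot))
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FieldProtocol", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("frames", "PinchRecording", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "PinchRecording", function(object) object@groundTruth)
#' @rdname accessors
#' @export
setMethod("groundTruth", "TetherDataset", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setGeneric("beadDiameter", function(object) standardGeneric("beadDiameter"))
#' @rdname accessors
#' @export
setMethod("beadDiameter", "PinchRecording", function(object) object@beadDiameter)

#' @rdname accessors
#' @export
setGeneric("curvePoints", function(object) standardGeneric("curvePoints"))
#' @rdname accessors
#' @export
setMethod("curvePoints", "StressStrainCurve", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("eTan", function(object) standardGeneric("eTan"))
#' @rdname accessors
#' @export
setMethod("eTan", "ModulusFit", function(object) object@eTan)

#' @rdname accessors
#' @export
setGeneric("alphaMean", function(object) standardGeneric("alphaMean"))
#' @rdname accessors
#' @export
setMethod("alphaMean", "BWFit", function(object) object@alphaMean)

#' @rdname accessors
#' @export
setGeneric("alphaSd", function(object) standardGeneric("alphaSd"))
#' @rdname accessors
#' @export
setMethod("alphaSd", "BWFit", function(object) object@alphaSd)

#' @rdname accessors
#' @export
setGeneric("staticForce", function(object) standardGeneric("staticForce"))
#' @rdname accessors
#' @export
setMethod("staticForce", "BWFit", function(object) object@f0)

#' @rdname accessors
#' @export
setGeneric("tetherSummary", function(object) standardGeneric("tetherSummary"))
#' @rdname accessors
#' @export
setMethod("tetherSummary", "TetherDataset", function(object) object@summary)

setMethod("show", "FieldProtocol", function(object) {
  cat(sprintf(
    "FieldProtocol: %d cycles, %.3g/%.3g/%.3g mT (low/nominal/high), %g s period, %g s ramp, %g fps, %d frames\n",
    object@nCycles, object@lowField, object@nominalField, object@highField,
    object@period, object@rampDuration, object@frameRate, nrow(object@frames)))
})

setMethod("show", "MagnetizationModel", function(object) {
  cat(sprintf("MagnetizationModel: m(B) = %.4g * B/(B + %.3g mT) A m^2\n",
              object@mSat, object@bHalf))
})

setMethod("show", "PinchRecording", function(object) {
  f <- object@frames
  cat(sprintf("PinchRecording: %d frames, bead diameter %.3g um", nrow(f),
              object@beadDiameter))
  if (nrow(f))
    cat(sprintf(", t = [%.3g, %.3g] s, %d flagged", min(f$t_s), max(f$t_s),
                sum(f$flagged)))
  cat(if (length(object@groundTruth)) ", with ground truth\n" else "\n")
})

setMethod("show", "CompressionCycle", function(object) {
  cat(sprintf("CompressionCycle %d: %d dip + %d ramp frames, h0Ref = %.4g nm\n",
              object@cycle, nrow(object@dip), nrow(object@ramp), object@h0Ref))
})

setMethod("show", "StressStrainCurve", function(object) {
  p <- object@points
  cat(sprintf("StressStrainCurve (cycle %d): %d points (%d kept), h0Ref = %.4g nm, R = %.3g um\n",
              object@cycle, nrow(p), sum(p$kept), object@h0Ref, object@beadRadius))
})

setMethod("show", "ModulusFit", function(object) {
  if (isTRUE(object@ok))
    cat(sprintf("ModulusFit: E_tan = %.4g Pa in [%g, %g] Pa (%d points, %s)\n",
                object@eTan, object@window[1], object@window[2],
                object@nPoints, object@method))
  else
    cat(sprintf("ModulusFit: failed (%d in-window points)\n", object@nPoints))
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve: %d samples at %g Hz, pull velocity %g um/s\n",
              nrow(object@data), object@samplingRate, object@pullVelocity))
})

setMethod("show", "TetherDataset", function(object) {
  cat(sprintf("TetherDataset: %d velocities, %d individual pulls\n",
              nrow(object@summary), nrow(object@forces)))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "BWFit", function(object) {
  if (isTRUE(object@ok))
    cat(sprintf("BWFit: Alpha = %.4g +/- %.4g pN^3 s/um, f0 = %.4g pN (n_sim = %d)\n",
                object@alphaMean, object@alphaSd, object@f0, object@nSim))
  else cat("BWFit: failed\n")
})

setMethod("show", "PodosomeDynamics", function(object) {
  p <- object@percentages
  cat(sprintf(
    "PodosomeDynamics: %d intervals, mean count %.3g; appearing %.1f%%, maintained %.1f%%, disappearing %.1f%%\n",
    nrow(object@intervals), object@meanCount,
    p[["appearing"]], p[["maintained"]], p[["disappearing"]]))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = ", "), "\n")
})
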