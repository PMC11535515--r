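#' Class "FieldProtocol": per-frame magnetic field trace
#'
#' A compression-relaxation field protocol for the magnetic pincher: the
#' field is held at a nominal value, periodically dropped to a low value,
#' then ramped linearly to a high value and brought back to nominal.
#'
#' @slot frames data.frame with columns `t_s`, `B_mT`, `phase`
#'   (one of "nominal", "dip", "ramp") and `cycle` (0 outside cycles).
#' @slot nominalField,lowField,highField field levels (mT).
#' @slot period,rampDuration,dipDuration cycle timing (s).
#' @slot nCycles number of compression cycles.
#' @slot frameRate acquisition rate (frames/s).
#' @seealso [genFieldProtocol()]
#' @export
setClass("FieldProtocol",
  representation(
    frames = "data.frame",
    nominalField = "numeric", lowField = "numeric", highField = "numeric",
    period = "numeric", rampDuration = "numeric", dipDuration = "numeric",
    nCycles = "integer", frameRate = "numeric"
  )
)

setValidity("FieldProtocol", function(object) {
  f <- object@frames
  msg <- character()
  if (!all(c("t_s", "B_mT", "phase", "cycle") %in% names(f)))
    msg <- c(msg, "frames must have columns t_s, B_mT, phase, cycle")
  if (!(0 < object@lowField && object@lowField < object@nominalField &&
        object@nominalField < object@highField))
    msg <- c(msg, "need 0 < low < nominal < high field")
  if (object@rampDuration >= object@period)
    msg <- c(msg, "ramp duration must be shorter than the period")
  if (object@nCycles < 1L) msg <- c(msg, "nCycles must be >= 1")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (nrow(f) && is.unsorted(f$t_s, strictly = TRUE))
    msg <- c(msg, "t_s must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Class "MagnetizationModel": bead magnetic moment vs field
#'
#' Saturating magnetization of a superparamagnetic bead,
#' m(B) = mSat * B / (B + bHalf), so m(0) = 0, m is monotone increasing
#' and approaches mSat for large fields.
#'
#' @slot mSat saturation magnetic moment (A m^2).
#' @slot bHalf field at half saturation (mT).
#' @seealso [magneticMoment()], [computePinchForce()], [defaultMagnetization()]
#' @export
setClass("MagnetizationModel",
  representation(mSat = "numeric", bHalf = "numeric")
)

setValidity("MagnetizationModel", function(object) {
  if (object@mSat <= 0) return("mSat must be > 0")
  if (object@bHalf <= 0) return("bHalf must be > 0")
  TRUE
})

#' Class "PinchRecording": synchronized bead-pair record of a pinching movie
#'
#' Per-frame bead-pair positions, magnetic field, and the derived
#' center-to-center distance, cortex thickness and pinching force.
#'
#' @slot frames data.frame with columns `t_s`, `B_mT`, `phase`, `cycle`,
#'   `x1_um`, `y1_um`, `z1_um`, `x2_um`, `y2_um`, `z2_um`, `D_um`,
#'   `h_nm`, `F_pN`, `flagged` (frames to exclude, e.g. phagocytosis).
#' @slot beadDiameter bead diameter (um).
#' @slot magnetization the [MagnetizationModel-class] used to compute forces.
#' @slot groundTruth list of generator ground truth (empty for real data).
#' @seealso [genPinchRecording()], [analyzePinchRecording()]
#' @export
setClass("PinchRecording",
  representation(
    frames = "data.frame",
    beadDiameter = "numeric",
    magnetization = "MagnetizationModel",
    groundTruth = "list"
  )
)

setValidity("PinchRecording", function(object) {
  f <- object@frames
  need <- c("t_s", "B_mT", "phase", "cycle", "x1_um", "y1_um", "z1_um",
            "x2_um", "y2_um", "z2_um", "D_um", "h_nm", "F_pN", "flagged")
  msg <- character()
  if (!all(need %in% names(f)))
    msg <- c(msg, paste("frames must have columns:", paste(need, collapse = ", ")))
  if (object@beadDiameter <= 0) msg <- c(msg, "beadDiameter must be > 0")
  if (nrow(f)) {
    if (is.unsorted(f$t_s, strictly = TRUE)) msg <- c(msg, "t_s must be strictly increasing")
    if (any(f$D_um < 0, na.rm = TRUE)) msg <- c(msg, "D_um must be >= 0")
    if (any(f$F_pN < 0, na.rm = TRUE)) msg <- c(msg, "F_pN must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Class "CompressionCycle": one dip + ramp compression event
#'
#' @slot cycle cycle index within the recording.
#' @slot dip data.frame of low-field frames preceding the ramp.
#' @slot ramp data.frame of ramp frames (field increasing).
#' @slot h0Ref reference (pre-compression) cortex thickness (nm).
#' @slot dipForce median pinching force during the dip (pN).
#' @export
setClass("CompressionCycle",
  representation(cycle = "integer", dip = "data.frame", ramp = "data.frame",
                 h0Ref = "numeric", dipForce = "numeric")
)

setValidity("CompressionCycle", function(object) {
  if (length(object@h0Ref) == 1L && is.finite(object@h0Ref) && object@h0Ref <= 0)
    return("h0Ref must be > 0")
  TRUE
})

#' Class "StressStrainCurve": strain-stress points of one compression
#'
#' Points are computed from the thin-layer contact model: for indentation
#' delta = h0Ref - h, strain eps = delta / h0Ref and stress
#' sigma = F / (pi * R * delta).
#'
#' @slot points data.frame with columns `F_pN`, `h_nm`, `delta_nm`, `eps`,
#'   `sigma_Pa`, `u` (= sqrt(sigma*eps), noise-free stress-strain scale)
#'   and `kept` (passes the indentation noise floor).
#' @slot h0Ref reference thickness (nm).
#' @slot beadRadius indenting bead radius (um).
#' @slot cycle provenance cycle index.
#' @export
setClass("StressStrainCurve",
  representation(points = "data.frame", h0Ref = "numeric",
                 beadRadius = "numeric", cycle = "integer")
)

#' Class "ModulusFit": tangential elastic modulus in a stress window
#'
#' @slot eTan tangential modulus dsigma/deps (Pa); `NA` if the fit failed.
#' @slot window stress window (Pa) in which the tangent is evaluated.
#' @slot nPoints number of in-window points.
#' @slot residual residual standard deviation of the fit.
#' @slot ok logical; `FALSE` when fewer than 3 in-window points.
#' @slot method "layer" (noise-robust reparameterized fit) or "direct".
#' @export
setClass("ModulusFit",
  representation(eTan = "numeric", window = "numeric", nPoints = "integer",
                 residual = "numeric", ok = "logical", method = "character")
)

setValidity("ModulusFit", function(object) {
  if (isTRUE(object@ok) && (!is.finite(object@eTan) || object@eTan <= 0))
    return("a successful fit must have eTan > 0")
  if (isTRUE(object@ok) && object@nPoints < 3L)
    return("a successful fit needs >= 3 in-window points")
  TRUE
})

#' Class "ForceCurve": one AFM tether-pulling force trace
#'
#' @slot data data.frame with columns `t_s`, `z_um`, `f_pN`.
#' @slot samplingRate sampling rate (Hz).
#' @slot pullVelocity cantilever retraction velocity (um/s).
#' @export
setClass("ForceCurve",
  representation(data = "data.frame", samplingRate = "numeric",
                 pullVelocity = "numeric")
)

setValidity("ForceCurve", function(object) {
  d <- object@data
  if (!all(c("t_s", "z_um", "f_pN") %in% names(d)))
    return("data must have columns t_s, z_um, f_pN")
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  if (nrow(d) && is.unsorted(d$t_s)) return("t_s must be increasing")
  TRUE
})

#' Class "TetherDataset": per-velocity tether break-force summary
#'
#' @slot summary data.frame with columns `velocity_um_s`, `mean_force_pN`,
#'   `sem_pN`, `n` (one row per pulling velocity).
#' @slot forces data.frame of individual break forces
#'   (`velocity_um_s`, `cell`, `force_pN`); may be empty for
#'   summary-only datasets.
#' @slot groundTruth list of generator ground truth (empty for real data).
#' @seealso [genTetherDataset()], [fitAlphaMC()]
#' @export
setClass("TetherDataset",
  representation(summary = "data.frame", forces = "data.frame",
                 groundTruth = "list")
)

setValidity("TetherDataset", function(object) {
  s <- object@summary
  if (!all(c("velocity_um_s", "mean_force_pN", "sem_pN", "n") %in% names(s)))
    return("summary must have columns velocity_um_s, mean_force_pN, sem_pN, n")
  if (nrow(s)) {
    if (any(s$sem_pN < 0)) return("SEM must be >= 0")
    if (any(s$n < 1)) return("n must be >= 1")
    if (any(s$velocity_um_s <= 0)) return("velocities must be > 0")
  }
  TRUE
})

#' Class "BWFit": Monte-Carlo Brochard-Wyart fit of the MCA parameter
#'
#' @slot alphaMean,alphaSd mean and SD of the attachment parameter Alpha
#'   (pN^3 s/um) over Monte-Carlo draws.
#' @slot f0 fitted static tether force (pN) on the unperturbed data.
#' @slot nSim number of Monte-Carlo draws.
#' @slot seed RNG seed used.
#' @slot ok logical fit status.
#' @slot draws per-draw Alpha values.
#' @seealso [fitAlphaMC()], [compareAlpha()]
#' @export
setClass("BWFit",
  representation(alphaMean = "numeric", alphaSd = "numeric", f0 = "numeric",
                 nSim = "integer", seed = "integer", ok = "logical",
                 draws = "numeric")
)

setValidity("BWFit", function(object) {
  if (isTRUE(object@ok)) {
    if (object@alphaSd < 0) return("alphaSd must be >= 0")
    if (object@nSim < 1L) return("nSim must be >= 1")
  }
  TRUE
})

#' Class "PodosomeDynamics": appearing / maintained / disappearing counts
#'
#' @slot intervals data.frame with one row per consecutive frame pair:
#'   `from`, `to`, `appearing`, `maintained`, `disappearing`.
#' @slot percentages named numeric: percentages of `appearing`,
#'   `maintained`, `disappearing` relative to the mean podosome count.
#' @slot meanCount mean podosome count across frames.
#' @slot flags character vector of quality flags (e.g. "all-empty").
#' @seealso [podosomeDynamics()]
#' @export
setClass("PodosomeDynamics",
  representation(intervals = "data.frame", percentages = "numeric",
                 meanCount = "numeric", flags = "character")
)

setValidity("PodosomeDynamics", function(object) {
  iv <- object@intervals
  if (nrow(iv) && any(iv$maintained < 0 | iv$appearing < 0 | iv$disappearing < 0))
    return("counts must be >= 0")
  if (any(object@percentages < 0, na.rm = TRUE))
    return("percentages must be >= 0")
  TRUE
})
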