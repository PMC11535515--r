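#' Segment a pinch recording into compression cycles
#'
#' Cycles are detected from the field trace alone: contiguous runs of
#' frames near the low-field level form the dips, and the frames of
#' monotonically increasing field that follow each dip form the ramps.
#' The reference thickness `h0Ref` of each cycle is the median thickness
#' over its (unflagged) dip frames. Flagged frames (e.g. phagocytosis in
#' progress) are excluded; a cycle whose dip or ramp is entirely flagged
#' is omitted.
#'
#' @param rec a [PinchRecording-class].
#' @param minDipContrast minimum field drop (mT) below the nominal level
#'   for dips to be searched at all; a constant trace yields an empty
#'   list.
#' @return list of [CompressionCycle-class] objects.
#' @export
segmentCompressions <- function(rec, minDipContrast = 0.5) {
  fr <- frames(rec)
  if (!nrow(fr)) return(list())
  B <- fr$B_mT
  Bnom <- median(B)
  Bmin <- min(B)
  if (Bnom - Bmin < minDipContrast) return(list())
  dipThr <- Bmin + 0.25 * (Bnom - Bmin)
  inDip <- B <= dipThr
  runs <- rle(inDip)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dipRuns <- which(runs$values)
  cycles <- list()
  cid <- 0L
  for (k in dipRuns) {
    dipIdx <- starts[k]:ends[k]
    # trailing frames of the dip run with rising field are already the
    # foot of the ramp (the threshold alone cannot separate them)
    while (length(dipIdx) > 1L &&
           B[dipIdx[length(dipIdx)]] > B[dipIdx[length(dipIdx) - 1L]])
      dipIdx <- dipIdx[-length(dipIdx)]
    rampFoot <- setdiff(starts[k]:ends[k], dipIdx)
    # ramp: increasing field after the dip, up to (and including) the peak
    i <- ends[k] + 1L
    rampIdx <- integer()
    while (i <= nrow(fr) && B[i] > dipThr &&
           (i == ends[k] + 1L || B[i] >= B[i - 1L])) {
      if (i > ends[k] + 1L && B[i] == B[i - 1L]) break  # plateau, not a ramp
      rampIdx <- c(rampIdx, i)
      i <- i + 1L
    }
    rampIdx <- c(rampFoot, rampIdx)
    if (!length(rampIdx)) next
    cid <- cid + 1L
    dip <- fr[dipIdx, , drop = FALSE]
    ramp <- fr[rampIdx, , drop = FALSE]
    dip <- dip[!dip$flagged, , drop = FALSE]
    ramp <- ramp[!ramp$flagged, , drop = FALSE]
    if (!nrow(dip) || !nrow(ramp)) next
    cycles[[length(cycles) + 1L]] <-
      new("CompressionCycle", cycle = cid, dip = dip, ramp = ramp,
          h0Ref = median(dip$h_nm, na.rm = TRUE),
          dipForce = median(dip$F_pN, na.rm = TRUE))
  }
  cycles
}

#' Median cortical thickness at the nominal field
#'
#' The primary thickness metric: the median of the cortex thickness over
#' all unflagged frames whose field is within `tol` of the nominal
#' value.
#'
#' @param rec a [PinchRecording-class].
#' @param nominal nominal field (mT), default 5.
#' @param tol field tolerance (mT), default 0.25.
#' @return Median thickness (nm).
#' @export
medianThicknessAtNominal <- function(rec, nominal = 5, tol = 0.25) {
  fr <- frames(rec)
  sel <- !fr$flagged & abs(fr$B_mT - nominal) <= tol & is.finite(fr$h_nm)
  if (!any(sel)) stop("no unflagged frames within tol of the nominal field")
  median(fr$h_nm[sel])
}

#' Strain-stress curve of one compression cycle
#'
#' Converts the (force, thickness) pairs of a compression into
#' thin-layer strain and stress: `delta = h0Ref - h`,
#' `eps = delta / h0Ref`, `sigma = F / (pi * R * delta)`
#' ([contactStress()]). The column `u = sqrt(sigma * eps)` equals
#' `sqrt(F / (pi * R * h0Ref))` and therefore carries no thickness
#' noise; it is the predictor used by the noise-robust modulus fit.
#' Points whose indentation falls below `deltaFloor` are marked
#' `kept = FALSE` and are excluded from the direct slope fit.
#'
#' @param cycle a [CompressionCycle-class].
#' @param RBead indenting bead radius (um).
#' @param h0Ref reference thickness (nm); defaults to the cycle's dip
#'   median. The pre-indentation-corrected analyzer passes an updated
#'   value here.
#' @param deltaFloor indentation noise floor (nm); points below it are
#'   dropped from the per-point curve (use ~2x the localization noise SD
#'   for noisy data, 0 for noiseless).
#' @param includeDip logical; include the dip frames as (small-strain)
#'   points of the curve.
#' @return A [StressStrainCurve-class].
#' @examples
#' # sigma for F = 100 pN, R = 2.25 um, delta = 50 nm is ~283 Pa
#' contactStress(F = 100, R = 2.25, delta = 50)
#' @export
stressStrain <- function(cycle, RBead, h0Ref = cycle@h0Ref, deltaFloor = 0,
                         includeDip = TRUE) {
  stopIfNot(h0Ref > 0, "h0Ref must be > 0")
  stopIfNot(RBead > 0, "RBead must be > 0")
  fr <- if (includeDip) rbind(cycle@dip, cycle@ramp) else cycle@ramp
  delta <- h0Ref - fr$h_nm
  eps <- delta / h0Ref
  sigma <- ifelse(delta > 0, contactStress(fr$F_pN, RBead, delta), NA_real_)
  u <- sqrt(fr$F_pN * 1e3 / (pi * RBead * h0Ref))  # = sqrt(sigma * eps), noise-free
  kept <- is.finite(delta) & delta >= max(deltaFloor, .Machine$double.eps) &
    fr$F_pN > 0 & is.finite(sigma)
  if (!any(kept)) stop("all points fall below the indentation noise floor")
  pts <- data.frame(F_pN = fr$F_pN, h_nm = fr$h_nm, delta_nm = delta,
                    eps = eps, sigma_Pa = sigma, u = u, kept = kept)
  new("StressStrainCurve", points = pts, h0Ref = h0Ref, beadRadius = RBead,
      cycle = cycle@cycle)
}

#' Fit the tangential elastic modulus in a stress window
#'
#' Two estimators of the low-stress tangent `dsigma/deps` evaluated in
#' the stress window (default 150-350 Pa):
#'
#' * `method = "layer"` (default): regression of strain on
#'   `u = sqrt(sigma * eps)` (with intercept), using every point of the
#'   compression. On the linear thin-layer law `sigma = E * eps` one has
#'   `eps = u / sqrt(E)` identically, so the estimated
#'   `E = 1 / slope^2` equals the window tangent exactly while the
#'   noise, which lives entirely in the strain coordinate, enters the
#'   regression linearly and symmetrically (no divergence of
#'   `sigma = F / (pi R delta)` at small noisy indentations). The
#'   intercept absorbs reference-thickness error. `nPoints` counts the
#'   points whose model stress `u * sqrt(E)` lies inside the window and
#'   at least 3 are required, as for the direct fit.
#' * `method = "direct"`: the literal least-squares slope of `sigma` on
#'   `eps` over the kept in-window points. Appropriate for clean or
#'   idealized curves.
#'
#' @param curve a [StressStrainCurve-class].
#' @param window stress window `c(lo, hi)` in Pa.
#' @param method "layer" or "direct".
#' @return A [ModulusFit-class]; `ok = FALSE` (and `eTan = NA`) when
#'   fewer than 3 points fall in the window or the slope is not
#'   positive.
#' @export
fitTangentialModulus <- function(curve, window = c(150, 350),
                                 method = c("layer", "direct")) {
  method <- match.arg(method)
  pts <- curve@points
  failed <- function(n) new("ModulusFit", eTan = NA_real_, window = window,
                            nPoints = as.integer(n), residual = NA_real_,
                            ok = FALSE, method = method)
  if (method == "direct") {
    sel <- pts$kept & pts$sigma_Pa >= window[1] & pts$sigma_Pa <= window[2]
    if (sum(sel) < 3L) return(failed(sum(sel)))
    fit <- lm(sigma_Pa ~ eps, data = pts[sel, ])
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope <= 0) return(failed(sum(sel)))
    return(new("ModulusFit", eTan = slope, window = window,
               nPoints = as.integer(sum(sel)),
               residual = sqrt(mean(fit$residuals^2)), ok = TRUE,
               method = method))
  }
  use <- is.finite(pts$u) & is.finite(pts$eps) & pts$F_pN > 0
  if (sum(use) < 3L) return(failed(0L))
  fit <- lm(eps ~ u, data = pts[use, ])
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) return(failed(0L))
  E <- 1 / slope^2
  nIn <- sum(use & pts$u * sqrt(E) >= window[1] & pts$u * sqrt(E) <= window[2])
  if (nIn < 3L) return(failed(nIn))
  new("ModulusFit", eTan = E, window = window, nPoints = as.integer(nIn),
      residual = sqrt(mean(fit$residuals^2)), ok = TRUE, method = method)
}

#' Full per-cell pincher analysis
#'
#' Segments a recording into compression cycles, corrects each cycle's
#' reference thickness for the pre-indentation already present at the
#' low-field dip (the dip force is small but not zero, so the dip
#' thickness underestimates the resting thickness by
#' `delta_dip = sqrt(F_dip * h0 / (pi R E))`; the correction is solved by
#' fixed-point iteration jointly with the modulus fit, and converges to
#' the exact forward model on noiseless data), fits the tangential
#' modulus per cycle, and summarizes the cell by the median modulus
#' across successful cycles and the median thickness at the nominal
#' field.
#'
#' @param rec a [PinchRecording-class].
#' @param window modulus stress window (Pa).
#' @param nominal,tol nominal field and tolerance (mT) for the thickness
#'   metric.
#' @param method modulus fit method, see [fitTangentialModulus()].
#' @param deltaFloor indentation floor (nm) passed to [stressStrain()].
#' @param correctPreindentation logical; apply the dip pre-indentation
#'   correction (default TRUE).
#' @param maxIter,tolH0 fixed-point iteration controls (nm).
#' @return list with `h_med_nm`, `E_tan_Pa`, `n_cycles`, `n_cycles_ok`
#'   and a per-cycle data.frame `cycles` (`cycle`, `h0_ref_nm`,
#'   `E_Pa`, `n_points`, `ok`).
#' @examples
#' rec <- genPinchRecording(h0 = 300, E = 5000, locNoiseXY = 0, locNoiseZ = 0,
#'                          protocol = genFieldProtocol(nCycles = 2), seed = 1)
#' analyzePinchRecording(rec)$E_tan_Pa  # ~5000
#' @export
analyzePinchRecording <- function(rec, window = c(150, 350), nominal = 5,
                                  tol = 0.25, method = c("layer", "direct"),
                                  deltaFloor = 0, correctPreindentation = TRUE,
                                  maxIter = 30L, tolH0 = 1e-9) {
  method <- match.arg(method)
  R <- beadDiameter(rec) / 2
  cycles <- segmentCompressions(rec)
  res <- lapply(cycles, function(cy) {
    h0 <- cy@h0Ref
    fitE <- NA_real_; nPts <- 0L; ok <- FALSE
    for (it in seq_len(if (correctPreindentation) maxIter else 1L)) {
      curve <- tryCatch(stressStrain(cy, RBead = R, h0Ref = h0,
                                     deltaFloor = deltaFloor),
                        error = function(e) NULL)
      if (is.null(curve)) break
      fit <- fitTangentialModulus(curve, window = window, method = method)
      nPts <- fit@nPoints; ok <- fit@ok
      if (!fit@ok) break
      fitE <- fit@eTan
      if (!correctPreindentation) break
      deltaDip <- sqrt(cy@dipForce * 1e3 * h0 / (pi * R * fitE))
      h0new <- cy@h0Ref + deltaDip
      if (abs(h0new - h0) < tolH0) { h0 <- h0new; break }
      h0 <- h0new
    }
    data.frame(cycle = cy@cycle, h0_ref_nm = h0, E_Pa = fitE,
               n_points = nPts, ok = ok)
  })
  cyTab <- if (length(res)) do.call(rbind, res)
  else data.frame(cycle = integer(), h0_ref_nm = numeric(), E_Pa = numeric(),
                  n_points = integer(), ok = logical())
  okE <- cyTab$E_Pa[cyTab$ok]
  hMed <- tryCatch(medianThicknessAtNominal(rec, nominal, tol),
                   error = function(e) NA_real_)
  list(h_med_nm = hMed,
       E_tan_Pa = if (length(okE)) median(okE) else NA_real_,
       n_cycles = nrow(cyTab), n_cycles_ok = sum(cyTab$ok),
       cycles = cyTab)
}
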