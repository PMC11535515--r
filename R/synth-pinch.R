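#' Generate a compression-relaxation field protocol
#'
#' Builds the per-frame magnetic field trace of the pinching protocol:
#' the field is held at `nominalField`, and once per `period` it is
#' dropped to `lowField` for `dipDuration`, ramped linearly to
#' `highField` over `rampDuration`, and brought back to the nominal
#' level. The trace starts and ends at the nominal field and contains
#' exactly `nCycles` dip + ramp events.
#'
#' @param nominalField nominal field (mT), default 5.
#' @param lowField low-dip field (mT), default 1.
#' @param highField ramp peak field (mT), default 54.
#' @param period cycle period (s), default 10.
#' @param rampDuration ramp duration (s), default 1.5.
#' @param nCycles number of compression cycles, default 8.
#' @param frameRate acquisition rate (frames/s), default 100.
#' @param dipDuration duration of the low-field dip (s), default 0.5;
#'   the dip provides the reference frames from which the resting
#'   thickness is estimated.
#' @return A [FieldProtocol-class] object.
#' @examples
#' prot <- genFieldProtocol(nCycles = 2)
#' range(frames(prot)$B_mT)
#' @export
genFieldProtocol <- function(nominalField = 5, lowField = 1, highField = 54,
                             period = 10, rampDuration = 1.5, nCycles = 8,
                             frameRate = 100, dipDuration = 0.5) {
  stopIfNot(lowField > 0 && nominalField > lowField && highField > nominalField,
            "need 0 < lowField < nominalField < highField")
  stopIfNot(frameRate > 0, "frameRate must be > 0")
  stopIfNot(nCycles >= 1, "nCycles must be >= 1")
  stopIfNot(rampDuration > 0 && dipDuration > 0 &&
              rampDuration + dipDuration < period,
            "need 0 < dipDuration + rampDuration < period")
  nCycles <- as.integer(nCycles)
  hold <- period - dipDuration - rampDuration
  total <- nCycles * period + hold
  t <- seq(0, total, by = 1 / frameRate)
  tc <- t %% period                      # time within cycle
  cyc <- pmin(t %/% period + 1L, nCycles)
  inTail <- t > nCycles * period + 1e-9
  # phase within a cycle: [0, hold) nominal, [hold, hold+dip) dip,
  # (hold+dip, period] ramp (so the peak frame carries B = highField)
  phase <- rep("nominal", length(t))
  B <- rep(nominalField, length(t))
  isZero <- abs(tc) < 1e-9 & t > 0      # exact cycle boundary = ramp peak
  tc[isZero] <- period
  cyc[isZero & !inTail] <- pmax(cyc[isZero & !inTail] - 1L, 1L)
  dip <- !inTail & tc >= hold - 1e-9 & tc < hold + dipDuration - 1e-9
  ramp <- !inTail & tc >= hold + dipDuration - 1e-9 & tc <= period + 1e-9 & !dip
  phase[dip] <- "dip"; B[dip] <- lowField
  phase[ramp] <- "ramp"
  B[ramp] <- lowField + (highField - lowField) *
    (tc[ramp] - hold - dipDuration) / rampDuration
  cycle <- ifelse(phase == "nominal", 0L, cyc)
  fr <- data.frame(t_s = t, B_mT = B, phase = phase, cycle = as.integer(cycle))
  new("FieldProtocol", frames = fr,
      nominalField = nominalField, lowField = lowField, highField = highField,
      period = period, rampDuration = rampDuration, dipDuration = dipDuration,
      nCycles = nCycles, frameRate = frameRate)
}

#' Simulate a magnetic-pincher recording with known ground truth
#'
#' Forward model of the pinching experiment: at each frame the bead
#' magnetic moment follows the magnetization model, the indentation of
#' the elastic cortex layer is solved self-consistently against the
#' dipole-pair force ([solveIndentation()]), and the two bead centers
#' are placed along the field axis at the resulting separation.
#' Isotropic Gaussian localization noise (XY and Z SDs may differ) is
#' then added per bead and per frame, and the recorded distance,
#' thickness and force columns are recomputed from the noisy centers as
#' a tracking pipeline would.
#'
#' @param h0 resting cortex thickness (nm).
#' @param E elastic modulus of the cortex layer (Pa).
#' @param beadDiameter bead diameter (um); the indenting radius is
#'   `beadDiameter / 2`.
#' @param locNoiseXY,locNoiseZ localization noise SD per axis (nm).
#' @param protocol a [FieldProtocol-class].
#' @param mag a [MagnetizationModel-class].
#' @param flagCycles integer cycle indices to flag (e.g. simulated
#'   phagocytosis); flagged frames are excluded by the analyzers.
#' @param seed RNG seed (determinism: same seed, same recording).
#' @return A [PinchRecording-class] whose `groundTruth` list carries the
#'   generator parameters and the true per-frame thickness/force series.
#' @examples
#' rec <- genPinchRecording(h0 = 300, E = 5000, locNoiseXY = 0, locNoiseZ = 0,
#'                          protocol = genFieldProtocol(nCycles = 2), seed = 7)
#' rec
#' @export
genPinchRecording <- function(h0 = 300, E = 5000, beadDiameter = 4.5,
                              locNoiseXY = 15, locNoiseZ = 40,
                              protocol = genFieldProtocol(),
                              mag = defaultMagnetization(beadDiameter = beadDiameter),
                              flagCycles = integer(), seed = 1) {
  stopIfNot(h0 > 0, "h0 must be > 0")
  stopIfNot(E > 0, "E must be > 0")
  stopIfNot(beadDiameter > 0, "beadDiameter must be > 0")
  stopIfNot(locNoiseXY >= 0 && locNoiseZ >= 0, "noise SDs must be >= 0")
  pf <- frames(protocol)
  n <- nrow(pf)
  R <- beadDiameter / 2
  m <- magneticMoment(mag, pf$B_mT)
  sol <- solveIndentation(m, h0 = h0, E = E, R = R, beadDiameter = beadDiameter)
  hTrue <- h0 - sol$delta
  base <- c(10, 10, 5)  # um, arbitrary stage position
  withSeed(seed, {
    nz <- function(sdv) matrix(rnorm(2L * n, sd = sdv * 1e-3), ncol = 2L)
    nXY1 <- nz(locNoiseXY); nXY2 <- nz(locNoiseXY)
    nZ <- matrix(rnorm(2L * n, sd = locNoiseZ * 1e-3), ncol = 2L)
  })
  c1 <- cbind(base[1] + nXY1[, 1], base[2] + nXY1[, 2], base[3] + nZ[, 1])
  c2 <- cbind(base[1] + sol$D + nXY2[, 1], base[2] + nXY2[, 2],
              base[3] + nZ[, 2])
  D <- sqrt(rowSums((c1 - c2)^2))
  fr <- data.frame(
    t_s = pf$t_s, B_mT = pf$B_mT, phase = pf$phase, cycle = pf$cycle,
    x1_um = c1[, 1], y1_um = c1[, 2], z1_um = c1[, 3],
    x2_um = c2[, 1], y2_um = c2[, 2], z2_um = c2[, 3],
    D_um = D, h_nm = 1000 * (D - beadDiameter),
    F_pN = computePinchForce(D = D, B = pf$B_mT, mag = mag),
    flagged = pf$cycle %in% flagCycles
  )
  gt <- list(h0 = h0, E = E, beadDiameter = beadDiameter, R = R,
             locNoiseXY = locNoiseXY, locNoiseZ = locNoiseZ, seed = seed,
             h_true_nm = hTrue, F_true_pN = sol$F, delta_true_nm = sol$delta,
             protocol = protocol)
  new("PinchRecording", frames = fr, beadDiameter = beadDiameter,
      magnetization = mag, groundTruth = gt)
}

#' Render a pinch recording as a synthetic bright-field image stack
#'
#' Each bead is drawn as a radially symmetric Gaussian intensity spot
#' centered at its true subpixel position (no bright-field ring optics,
#' no defocus). Optional Poisson photon noise.
#'
#' @param rec a [PinchRecording-class].
#' @param pixelSize pixel size (um/px).
#' @param psfSigma spot Gaussian sigma (px).
#' @param imageSize `c(ny, nx)` in px; computed from the positions with a
#'   margin when `NULL`.
#' @param amplitude peak spot intensity above baseline.
#' @param baseline background intensity.
#' @param photonNoise logical; add Poisson noise with the intensity values
#'   taken as photon counts.
#' @param seed RNG seed for the photon noise.
#' @return numeric array `ny x nx x nframes` of intensities; an empty
#'   recording yields a `0 x 0 x 0` array.
#' @export
renderBeadFrames <- function(rec, pixelSize = 0.1, psfSigma = 2,
                             imageSize = NULL, amplitude = 200, baseline = 20,
                             photonNoise = FALSE, seed = 1) {
  stopIfNot(pixelSize > 0, "pixelSize must be > 0")
  fr <- frames(rec)
  if (nrow(fr) == 0L) return(array(numeric(0), dim = c(0L, 0L, 0L)))
  px <- cbind(fr$x1_um, fr$x2_um) / pixelSize
  py <- cbind(fr$y1_um, fr$y2_um) / pixelSize
  margin <- ceiling(4 * psfSigma) + 2L
  if (is.null(imageSize)) {
    nx <- ceiling(max(px)) + margin
    ny <- ceiling(max(py)) + margin
  } else {
    ny <- imageSize[1]; nx <- imageSize[2]
  }
  bad <- which(px < margin / 2 | px > nx - margin / 2 |
                 py < margin / 2 | py > ny - margin / 2, arr.ind = TRUE)
  if (length(bad))
    stop("beads out of frame at frame(s): ",
         paste(sort(unique(bad[, 1])), collapse = ", "))
  sep <- sqrt((px[, 1] - px[, 2])^2 + (py[, 1] - py[, 2])^2)
  if (any(sep < 2 * psfSigma))
    warning(sprintf("overlapping beads (separation < 2*psfSigma px) at %d frame(s)",
                    sum(sep < 2 * psfSigma)))
  xc <- seq_len(nx) - 0.5  # pixel-center coordinates
  yc <- seq_len(ny) - 0.5
  stack <- array(baseline, dim = c(ny, nx, nrow(fr)))
  for (f in seq_len(nrow(fr))) {
    img <- matrix(0, ny, nx)
    for (b in 1:2) {
      gx <- exp(-(xc - px[f, b])^2 / (2 * psfSigma^2))
      gy <- exp(-(yc - py[f, b])^2 / (2 * psfSigma^2))
      img <- img + amplitude * outer(gy, gx)
    }
    stack[, , f] <- stack[, , f] + img
  }
  if (photonNoise)
    withSeed(seed, {
      stack[] <- rpois(length(stack), lambda = pmax(stack, 0))
    })
  stack
}
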