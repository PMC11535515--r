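test_that("compression segmentation finds every cycle with tight boundaries", {
  prot <- genFieldProtocol(nCycles = 8, frameRate = 100)
  rec <- genPinchRecording(locNoiseXY = 0, locNoiseZ = 0, protocol = prot,
                           seed = 2)
  cyc <- segmentCompressions(rec)
  expect_length(cyc, 8L)
  # ramp boundaries within one frame of the generator's phase labels
  fr <- frames(rec)
  for (k in c(1, 5, 8)) {
    trueRamp <- range(fr$t_s[fr$phase == "ramp" & fr$cycle == k])
    gotRamp <- range(cyc[[k]]@ramp$t_s)
    expect_lt(abs(gotRamp[1] - trueRamp[1]), 1.5 / 100)
    expect_lt(abs(gotRamp[2] - trueRamp[2]), 1.5 / 100)
  }
})

test_that("constant-field traces yield no compressions", {
  rec <- genPinchRecording(protocol = shortProtocol(), seed = 2)
  rec@frames$B_mT <- 5
  expect_length(segmentCompressions(rec), 0L)
})

test_that("flagged (phagocytosis) cycles are omitted and flags are idempotent", {
  prot <- genFieldProtocol(nCycles = 4, frameRate = 100)
  recF <- genPinchRecording(locNoiseXY = 0, locNoiseZ = 0, protocol = prot,
                            flagCycles = 2L, seed = 3)
  cyc <- segmentCompressions(recF)
  expect_length(cyc, 3L)
  # a recording without flags is unchanged by flag-removal logic
  rec <- genPinchRecording(locNoiseXY = 0, locNoiseZ = 0, protocol = prot,
                           seed = 3)
  an1 <- analyzePinchRecording(rec)
  rec2 <- rec; rec2@frames <- rec2@frames[!rec2@frames$flagged, ]
  an2 <- analyzePinchRecording(rec2)
  expect_equal(an1$E_tan_Pa, an2$E_tan_Pa)
  expect_equal(an1$h_med_nm, an2$h_med_nm)
})

test_that("median thickness at nominal field matches its definition", {
  rec <- genPinchRecording(protocol = shortProtocol(), seed = 4)
  rec@frames$h_nm <- ifelse(abs(rec@frames$B_mT - 5) <= 0.25,
                            NA, rec@frames$h_nm)
  sel <- which(abs(rec@frames$B_mT - 5) <= 0.25)
  rec@frames$h_nm[sel] <- 300
  rec@frames$h_nm[sel[1:2]] <- c(290, 310)
  expect_equal(medianThicknessAtNominal(rec), 300)
  # single qualifying frame
  rec@frames$h_nm[sel[-1]] <- NA
  expect_equal(medianThicknessAtNominal(rec), 290)
  # none qualifying
  rec@frames$h_nm[sel] <- NA
  expect_error(medianThicknessAtNominal(rec), "no unflagged frames")
})

test_that("stress and strain follow the thin-layer contact formulas", {
  expect_equal(contactStress(F = 100, R = 2.25, delta = 50), 282.94,
               tolerance = 1e-4)
  expect_equal(50 / 300, 1 / 6)
  rec <- genPinchRecording(h0 = 300, E = 5000, locNoiseXY = 0, locNoiseZ = 0,
                           protocol = shortProtocol(), seed = 5)
  cyc <- segmentCompressions(rec)[[1]]
  curve <- stressStrain(cyc, RBead = 2.25)
  pts <- curvePoints(curve)
  expect_equal(pts$eps[pts$kept],
               pts$delta_nm[pts$kept] / curve@h0Ref)
  # with the pre-indentation-corrected reference, the noiseless curve is
  # monotone increasing in stress along the ramp
  an <- analyzePinchRecording(rec)
  curve2 <- stressStrain(cyc, RBead = 2.25, h0Ref = an$cycles$h0_ref_nm[1])
  p2 <- curvePoints(curve2)
  ramp <- p2[p2$kept & p2$F_pN > 1.01 * cyc@dipForce, ]
  ord <- order(ramp$eps)
  expect_true(all(diff(ramp$sigma_Pa[ord]) > 0))
})

test_that("zero-force and below-floor points are dropped from the curve", {
  rec <- genPinchRecording(h0 = 300, E = 5000, locNoiseXY = 0, locNoiseZ = 0,
                           protocol = shortProtocol(), seed = 5)
  cyc <- segmentCompressions(rec)[[1]]
  curve <- stressStrain(cyc, RBead = 2.25, deltaFloor = 5)
  expect_true(all(curvePoints(curve)$delta_nm[curvePoints(curve)$kept] >= 5))
  expect_error(stressStrain(cyc, RBead = 2.25, deltaFloor = 1e6),
               "noise floor")
})

test_that("modulus fit recovers an exact linear stress-strain curve", {
  eps <- seq(0.05, 0.25, length.out = 20)
  pts <- data.frame(F_pN = NA_real_, h_nm = NA_real_, delta_nm = eps * 300,
                    eps = eps, sigma_Pa = 2000 * eps,
                    u = sqrt(2000) * eps, kept = TRUE)
  curve <- new("StressStrainCurve", points = pts, h0Ref = 300,
               beadRadius = 2.25, cycle = 1L)
  fit <- fitTangentialModulus(curve, window = c(150, 350), method = "direct")
  expect_true(fit@ok)
  expect_equal(eTan(fit), 2000, tolerance = 1e-9)
  # the layer reparameterization gives the same answer (F column needed)
  pts$F_pN <- pts$sigma_Pa * pi * 2.25 * pts$delta_nm / 1e3
  curve2 <- new("StressStrainCurve", points = pts, h0Ref = 300,
                beadRadius = 2.25, cycle = 1L)
  fit2 <- fitTangentialModulus(curve2, method = "layer")
  expect_equal(eTan(fit2), 2000, tolerance = 1e-9)
})

test_that("fewer than 3 in-window points fails the fit", {
  eps <- c(0.05, 0.1, 0.5, 0.6)
  pts <- data.frame(F_pN = 1, h_nm = 1, delta_nm = eps * 300, eps = eps,
                    sigma_Pa = 2000 * eps, u = sqrt(2000) * eps, kept = TRUE)
  curve <- new("StressStrainCurve", points = pts, h0Ref = 300,
               beadRadius = 2.25, cycle = 1L)
  fit <- fitTangentialModulus(curve, window = c(150, 350), method = "direct")
  expect_false(fit@ok)
  expect_true(is.na(eTan(fit)))
})

test_that("noiseless round trip recovers the modulus within 1 percent", {
  rec <- genPinchRecording(h0 = 300, E = 5000, locNoiseXY = 0, locNoiseZ = 0,
                           seed = 6)
  an <- analyzePinchRecording(rec)
  expect_lt(abs(an$E_tan_Pa - 5000) / 5000, 0.01)
  gt <- groundTruth(rec)
  hTrue5 <- median(gt$h_true_nm[abs(frames(rec)$B_mT - 5) <= 0.25])
  expect_lt(abs(an$h_med_nm - hTrue5), 2)
})

test_that("noisy recordings still recover modulus and thickness", {
  ok <- vapply(1:10, function(s) {
    rec <- genPinchRecording(h0 = 300, E = 5000, seed = 200 + s)
    an <- analyzePinchRecording(rec)
    gt <- groundTruth(rec)
    hTrue5 <- median(gt$h_true_nm[abs(frames(rec)$B_mT - 5) <= 0.25])
    abs(an$E_tan_Pa - 5000) / 5000 < 0.25 && abs(an$h_med_nm - hTrue5) < 15
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
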