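test_that("field protocol reproduces the compression-relaxation scheme", {
  prot <- genFieldProtocol(5, 1, 54, 10, 1.5, nCycles = 8, frameRate = 10)
  fr <- frames(prot)
  expect_equal(max(fr$B_mT), 54)
  expect_equal(min(fr$B_mT), 1)
  expect_equal(fr$B_mT[1], 5)
  expect_equal(fr$B_mT[nrow(fr)], 5)
  # exactly 8 dip events (contiguous runs at the low field)
  runs <- rle(fr$B_mT == 1)
  expect_equal(sum(runs$values), 8L)
  # ramps are monotone and linear in time
  rampIdx <- which(fr$phase == "ramp" & fr$cycle == 3)
  expect_true(all(diff(fr$B_mT[rampIdx]) > 0))
  expect_equal(diff(fr$B_mT[rampIdx]), rep(diff(fr$B_mT[rampIdx])[1],
                                           length(rampIdx) - 1L))
})

test_that("field protocol rejects non-physical values and handles boundaries", {
  expect_error(genFieldProtocol(nCycles = 0), "nCycles")
  expect_error(genFieldProtocol(frameRate = 0), "frameRate")
  expect_error(genFieldProtocol(lowField = -1), "lowField")
  expect_error(genFieldProtocol(rampDuration = 12), "period")
  prot <- genFieldProtocol(5, 1, 54, 10, 1.5, nCycles = 1, frameRate = 1)
  fr <- frames(prot)
  expect_equal(fr$B_mT[1], 5)
  expect_gte(sum(fr$phase == "ramp"), 1L)
  expect_equal(max(fr$B_mT), 54)
})

test_that("noiseless pinch recordings satisfy the layer relation the analyzer inverts", {
  rec <- genPinchRecording(h0 = 300, E = 5000, locNoiseXY = 0, locNoiseZ = 0,
                           protocol = shortProtocol(), seed = 11)
  gt <- groundTruth(rec)
  fr <- frames(rec)
  sel <- gt$delta_true_nm > 1e-3
  # sigma(delta) = E * delta / h0 with sigma = F / (pi R delta), checked
  # by independent arithmetic on the recorded series
  sigma <- gt$F_true_pN[sel] * 1e3 / (pi * gt$R * gt$delta_true_nm[sel])
  expect_lt(max(abs(sigma / (gt$E * gt$delta_true_nm[sel] / gt$h0) - 1)), 1e-9)
  # noiseless: recorded thickness equals the true thickness
  expect_lt(max(abs(fr$h_nm - gt$h_true_nm)), 1e-6)
})

test_that("zero force leaves the cortex at its resting thickness", {
  sol <- solveIndentation(m = c(0, 0), h0 = 300, E = 5000, R = 2.25,
                          beadDiameter = 4.5)
  expect_equal(sol$delta, c(0, 0), tolerance = 1e-9)
  expect_equal(sol$F, c(0, 0))
})

test_that("over-compression is warned about, not silently clipped", {
  prot <- shortProtocol(nCycles = 1)
  expect_warning(
    genPinchRecording(h0 = 50, E = 50, locNoiseXY = 0, locNoiseZ = 0,
                      protocol = prot, seed = 1),
    "full-compression")
})

test_that("pinch generator is deterministic under a fixed seed", {
  a <- genPinchRecording(protocol = shortProtocol(), seed = 42)
  b <- genPinchRecording(protocol = shortProtocol(), seed = 42)
  expect_identical(frames(a), frames(b))
  c <- genPinchRecording(protocol = shortProtocol(), seed = 43)
  expect_false(identical(frames(a), frames(c)))
})

test_that("rendered beads have centroids at their true subpixel positions", {
  rec <- genPinchRecording(locNoiseXY = 0, locNoiseZ = 0,
                           protocol = genFieldProtocol(nCycles = 1,
                                                       frameRate = 2),
                           seed = 1)
  stack <- renderBeadFrames(rec, pixelSize = 0.1, psfSigma = 2)
  img <- stack[, , 1] - 20  # remove baseline
  fr <- frames(rec)[1, ]
  # centroid over a window around bead 1
  cx0 <- fr$x1_um / 0.1; cy0 <- fr$y1_um / 0.1
  xi <- round(cx0) + (-8:8); yi <- round(cy0) + (-8:8)
  win <- img[yi, xi]
  cx <- sum(colSums(win) * (xi - 0.5)) / sum(win)
  cy <- sum(rowSums(win) * (yi - 0.5)) / sum(win)
  expect_lt(abs(cx - cx0), 0.05)
  expect_lt(abs(cy - cy0), 0.05)
})

test_that("degenerate rendering inputs are reported", {
  emptyRec <- genPinchRecording(protocol = shortProtocol(), seed = 1)
  emptyRec@frames <- emptyRec@frames[0, ]
  expect_identical(dim(renderBeadFrames(emptyRec)), c(0L, 0L, 0L))
  near <- genPinchRecording(locNoiseXY = 0, locNoiseZ = 0,
                            protocol = genFieldProtocol(nCycles = 1,
                                                        frameRate = 2),
                            seed = 1)
  near@frames$x2_um <- near@frames$x1_um + 0.1  # 1 px apart
  expect_warning(renderBeadFrames(near, pixelSize = 0.1), "overlap")
  off <- genPinchRecording(locNoiseXY = 0, locNoiseZ = 0,
                           protocol = genFieldProtocol(nCycles = 1,
                                                       frameRate = 2),
                           seed = 1)
  off@frames$x1_um[1] <- -5
  expect_error(renderBeadFrames(off, pixelSize = 0.1), "out of frame")
})

test_that("noiseless tether break forces solve the force-velocity cubic exactly", {
  ds <- genTetherDataset(alpha = 50, f0 = 10, forceNoiseCv = 0, seed = 3)
  fo <- ds@forces
  resid <- fo$force_pN * (fo$force_pN^2 - 100) - 50 * fo$velocity_um_s
  expect_lt(max(abs(resid)), 1e-9)
  s <- tetherSummary(ds)
  expect_equal(s$sem_pN, rep(0, 4))
})

test_that("tether dataset has one pull per cell and velocity", {
  ds <- genTetherDataset(velocities = c(2, 5, 10, 30), nCells = 16, seed = 5)
  expect_equal(nrow(ds@forces), 64L)
  s <- tetherSummary(ds)
  expect_equal(s$n, rep(16L, 4))
  expect_equal(s$velocity_um_s, c(2, 5, 10, 30))
  a <- genTetherDataset(seed = 9); b <- genTetherDataset(seed = 9)
  expect_identical(a@forces, b@forces)
})

test_that("track generator hits the requested mean speed and is deterministic", {
  tr <- genTracks(nTracks = 250, duration = 14400, meanSpeed = 2, seed = 8)
  st <- summarizeTracks(tr)
  # mean instantaneous speed: total path / duration
  meanSpeed <- mean(st$total_distance / st$duration_min)
  expect_lt(abs(meanSpeed - 2) / 2, 0.05)
  expect_identical(genTracks(nTracks = 3, duration = 3600, seed = 1),
                   genTracks(nTracks = 3, duration = 3600, seed = 1))
})

test_that("infinitely persistent noise-free tracks are ballistic", {
  tr <- genTracks(nTracks = 5, duration = 7200, persistenceTime = 1e12,
                  seed = 2)
  st <- summarizeTracks(tr)
  expect_equal(st$confinement_ratio, rep(1, 5), tolerance = 1e-6)
})

test_that("event tables cover their degenerate limits", {
  expect_error(genEventTable("nonsense"), "unknown kind")
  pod <- genEventTable("podosome_movie",
                       list(birthRate = 0, deathRate = 0, jitterSd = 0),
                       seed = 4)
  dyn <- podosomeDynamics(pod)
  expect_equal(unname(dyn@percentages["maintained"]), 100)
  expect_equal(unname(dyn@percentages["appearing"]), 0)
  ev <- genEventTable("adhesion_events", list(stickFrac = 1e-9), seed = 4)
  ev$adhesion_s <- pmin(ev$adhesion_s, 29.9)
  af <- adhesionFractions(ev)
  expect_true(all(af$sticking_fraction[af$rolling > 0] == 0))
  dp <- genEventTable("depth_profile",
                      list(fracDeep = 0, shallowMax = 0), seed = 4)
  expect_equal(infiltrationSummary(dp$depth_um, 10)$percent_infiltrated, 0)
})
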