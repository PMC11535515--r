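gaussSpot <- function(x, y, nx = 40, ny = 40, sigma = 2, amp = 200,
                      baseline = 20, noiseSd = 0) {
  xc <- seq_len(nx) - 0.5; yc <- seq_len(ny) - 0.5
  img <- baseline + amp * outer(exp(-(yc - y)^2 / (2 * sigma^2)),
                                exp(-(xc - x)^2 / (2 * sigma^2)))
  if (noiseSd > 0) img <- img + matrix(rnorm(nx * ny, sd = noiseSd), ny, nx)
  img
}

test_that("bead detection is subpixel-accurate on synthetic spots", {
  img <- gaussSpot(10.30, 20.70)
  d <- detectBeadCenters(img, expectedRadiusPx = 2)
  expect_equal(nrow(d), 1L)
  expect_lt(sqrt((d$x - 10.30)^2 + (d$y - 20.70)^2), 0.1)
  # blank frame: no detections
  expect_equal(nrow(detectBeadCenters(matrix(7, 30, 30), 2)), 0L)
  # two well-separated beads: exactly two detections
  img2 <- gaussSpot(10, 10) + gaussSpot(30, 28) - 20
  d2 <- detectBeadCenters(img2, expectedRadiusPx = 2)
  expect_equal(nrow(d2), 2L)
})

test_that("detection bias stays below 0.1 px at SNR >= 10", {
  # bias = systematic (mean signed) error over random subpixel positions
  set.seed(101)
  errs <- replicate(300, {
    x <- runif(1, 12, 28); y <- runif(1, 12, 28)
    img <- gaussSpot(x, y, noiseSd = 20)  # SNR = 10
    d <- detectBeadCenters(img, expectedRadiusPx = 2)
    c(d$x[1] - x, d$y[1] - y)
  })
  expect_lt(abs(mean(errs[1, ])), 0.1)
  expect_lt(abs(mean(errs[2, ])), 0.1)
  # noiseless subpixel sweep: per-spot error well below 0.1 px
  sweep <- vapply(seq(0, 0.9, by = 0.1), function(off) {
    img <- gaussSpot(20 + off, 17.3)
    d <- detectBeadCenters(img, expectedRadiusPx = 2)
    abs(d$x[1] - (20 + off))
  }, numeric(1))
  expect_lt(max(sweep), 0.02)
})

test_that("assignment solver equals exhaustive enumeration", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- lapMinAssign(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 bruteAssignOracle(cost)$cost, tolerance = 1e-12)
  }
})

test_that("linking keeps identities of static and crossing beads", {
  det <- lapply(1:100, function(f) data.frame(x = c(0, 5), y = c(0, 0)))
  tr <- linkBeads(det, maxDisp = 1)
  expect_equal(length(unique(tr$track_id)), 2L)
  expect_equal(as.integer(table(tr$track_id)), c(100L, 100L))
  # two beads moving toward and past each other in y, never jumping
  # more than maxDisp per frame: identities must be preserved
  det2 <- lapply(1:41, function(f) {
    t <- (f - 21) / 10
    data.frame(x = c(-0.2, 0.2), y = c(t, -t))
  })
  tr2 <- linkBeads(det2, maxDisp = 0.3)
  expect_equal(length(unique(tr2$track_id)), 2L)
  t1 <- tr2[tr2$track_id == 1, ]
  expect_equal(t1$x, rep(-0.2, 41))
  # frame-pair assignment matches the brute-force oracle on <= 4 beads
  set.seed(21)
  for (i in 1:30) {
    n <- sample(2:4, 1)
    p1 <- matrix(runif(2 * n, 0, 10), ncol = 2)
    p2 <- p1 + matrix(rnorm(2 * n, sd = 0.2), ncol = 2)
    m <- matchPoints(p1, p2, radius = 1)
    o <- bruteMatchOracle(p1, p2, radius = 1)
    expect_equal(nrow(m$pairs), o$count)
    expect_equal(sum(m$pairs$dist), o$cost, tolerance = 1e-9)
  }
})

test_that("a single missing detection is bridged into one trajectory", {
  det <- lapply(1:30, function(f) data.frame(x = 1 + 0.01 * f, y = 0))
  det[[15]] <- data.frame(x = numeric(), y = numeric())
  tr <- linkBeads(det, maxDisp = 0.5, maxGap = 1)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 29L)
})

test_that("thickness is the bead gap, with overlap frames flagged", {
  t1 <- data.frame(frame = 1:2, x = c(0, 0), y = 0, z = 0)
  t2 <- data.frame(frame = 1:2, x = c(4.8, 4.4), y = 0, z = 0)
  h <- pairToThickness(t1, t2, beadDiameter = 4.5)
  expect_equal(h$h_nm[1], 300)
  expect_true(h$overlap[2])
  expect_true(is.na(h$h_nm[2]))
  expect_error(pairToThickness(t1, data.frame(frame = 5, x = 0, y = 0, z = 0),
                               4.5), "disjoint")
})

test_that("dipole force law: zero field, inverse fourth power, example value", {
  expect_identical(computePinchForce(D = 4.5, B = 0), 0)
  f1 <- computePinchForce(D = 4.6, B = 12)
  f2 <- computePinchForce(D = 9.2, B = 12)
  expect_equal(f2 / f1, 1 / 16, tolerance = 1e-12)
  expect_equal(computePinchForce(D = 4.6, m = 3.0e-13), 120.6, tolerance = 1e-3)
  expect_error(computePinchForce(D = 0, B = 5), "D")
})

test_that("force is monotone increasing in B and decreasing in D", {
  B <- seq(0, 60, by = 0.5)
  f <- computePinchForce(D = 4.6, B = B)
  expect_true(all(diff(f) > 0))
  D <- seq(4.5, 8, by = 0.05)
  f2 <- computePinchForce(D = D, B = 5)
  expect_true(all(diff(f2) < 0))
  # moment model sanity: m(0) = 0, monotone, below saturation
  mag <- defaultMagnetization()
  expect_identical(magneticMoment(mag, 0), 0)
  m <- magneticMoment(mag, B)
  expect_true(all(diff(m) > 0))
  expect_true(all(m < mag@mSat))
})

test_that("noiseless recordings reproduce generator thickness to < 1e-6 nm", {
  rec <- genPinchRecording(h0 = 250, E = 3000, locNoiseXY = 0, locNoiseZ = 0,
                           protocol = shortProtocol(), seed = 5)
  fr <- frames(rec)
  t1 <- data.frame(frame = seq_len(nrow(fr)), x = fr$x1_um, y = fr$y1_um,
                   z = fr$z1_um)
  t2 <- data.frame(frame = seq_len(nrow(fr)), x = fr$x2_um, y = fr$y2_um,
                   z = fr$z2_um)
  h <- pairToThickness(t1, t2, beadDiameter(rec))
  expect_lt(max(abs(h$h_nm - groundTruth(rec)$h_true_nm)), 1e-6)
})
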