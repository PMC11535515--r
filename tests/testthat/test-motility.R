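test_that("track summaries handle ballistic, closed and 3-4-5 tracks", {
  straight <- data.frame(t_s = seq(0, 600, 60), x_um = seq(0, 100, 10),
                         y_um = 0)
  s <- summarizeTrack(straight)
  expect_equal(s$median_speed, 10)
  expect_equal(s$confinement_ratio, 1)
  square <- data.frame(t_s = seq(0, 240, 60),
                       x_um = c(0, 1, 1, 0, 0), y_um = c(0, 0, 1, 1, 0))
  s2 <- summarizeTrack(square)
  expect_equal(s2$net_distance, 0)
  expect_equal(s2$confinement_ratio, 0)
  tr345 <- data.frame(t_s = c(0, 60, 120), x_um = c(0, 3, 6),
                      y_um = c(0, 4, 8))
  s3 <- summarizeTrack(tr345)
  expect_equal(s3$median_speed, 5)
  expect_equal(s3$confinement_ratio, 1)
})

test_that("the 1-hour track filter is strictly greater-than", {
  mk <- function(id, minutes) data.frame(track_id = id,
                                         t_s = c(0, minutes * 60),
                                         x_um = c(0, 1), y_um = 0)
  tracks <- rbind(mk(1, 59), mk(2, 60), mk(3, 61))
  kept <- filterTracks(tracks, minDuration = 60)
  expect_equal(unique(kept$track_id), 3)
  expect_equal(nrow(filterTracks(tracks[0, ], 60)), 0L)
  long <- mk(9, 16 * 60)
  expect_equal(unique(filterTracks(long, 60)$track_id), 9)
})

test_that("chemotaxis indices project on the gradient axis", {
  xTrack <- data.frame(track_id = 1, t_s = seq(0, 300, 60),
                       x_um = seq(0, 50, 10), y_um = 0)
  expect_equal(chemotaxisMetrics(xTrack)$fmi, 1)
  yTrack <- data.frame(track_id = 1, t_s = seq(0, 300, 60),
                       x_um = 0, y_um = seq(0, 50, 10))
  expect_equal(chemotaxisMetrics(yTrack)$fmi, 0)
  still <- data.frame(track_id = 1, t_s = c(0, 60, 120), x_um = 0, y_um = 0)
  ch <- chemotaxisMetrics(still)
  expect_equal(ch$fmi, 0)
  expect_equal(ch$flag, "zero-total")
})

test_that("confinement ratio and directionality coincide; |FMIx| <= CR", {
  tr <- genTracks(nTracks = 40, duration = 10800, seed = 12)
  st <- summarizeTracks(tr)
  ch <- chemotaxisMetrics(tr)
  expect_equal(st$confinement_ratio, ch$directionality)
  expect_true(all(abs(ch$fmi) <= st$confinement_ratio + 1e-12))
})

test_that("drifted walks break the forward-migration symmetry the right way", {
  drifted <- genTracks(nTracks = 120, duration = 10800, meanSpeed = 2,
                       driftSpeed = 0.6, seed = 13)
  expect_gt(mean(chemotaxisMetrics(drifted)$fmi), 0.05)
  reverse <- genTracks(nTracks = 120, duration = 10800, meanSpeed = 2,
                       driftSpeed = -0.6, seed = 13)
  expect_lt(mean(chemotaxisMetrics(reverse)$fmi), -0.05)
})

test_that("transwell summary counts in-matrix cells and layer distances", {
  tw <- transwellSummary(c(10, 3, 2), layerInterval = 30)
  expect_equal(tw$percent_migration, 100 / 3, tolerance = 1e-9)
  expect_equal(sort(unique(tw$distances_um)), c(30, 60))
  expect_equal(transwellSummary(c(10, 0, 0))$percent_migration, 0)
  one <- transwellSummary(data.frame(layer = c(0, 2), count = c(9, 1)),
                          layerInterval = 30)
  expect_equal(one$distances_um, 60)
  expect_error(transwellSummary(c(0, 0)), "no cells")
})

test_that("rolling and sticking fractions follow their definitions", {
  ev <- data.frame(vessel = 1, rolling = rep(c(TRUE, FALSE), c(20, 80)),
                   adhesion_s = c(rep(45, 5), rep(10, 15), rep(0, 80)))
  af <- adhesionFractions(ev)
  expect_equal(af$rolling_fraction, 20)
  expect_equal(af$sticking_fraction, 25)
  # 29.9 s does not count as stuck
  ev2 <- data.frame(vessel = 1, rolling = TRUE, adhesion_s = 29.9)
  expect_equal(adhesionFractions(ev2)$sticking_fraction, 0)
  # no rolling cells: sticking fraction undefined, not zero
  ev3 <- data.frame(vessel = 1, rolling = FALSE, adhesion_s = 0)
  expect_true(is.na(adhesionFractions(ev3)$sticking_fraction))
})

test_that("infiltration summary thresholds depths correctly", {
  s <- infiltrationSummary(c(5, 12, 30), threshold = 10)
  expect_equal(s$percent_infiltrated, 200 / 3, tolerance = 1e-9)
  expect_equal(infiltrationSummary(c(0, 0, 0), 10)$percent_infiltrated, 0)
  expect_equal(infiltrationSummary(c(0, 1, 2), 0)$percent_infiltrated,
               200 / 3, tolerance = 1e-9)
  expect_error(infiltrationSummary(numeric(0)), "empty")
})
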