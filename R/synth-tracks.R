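#' Simulate persistent-random-walk migration tracks
#'
#' Cell velocity follows a discrete Ornstein-Uhlenbeck process sampled
#' at the frame interval: each velocity component relaxes with
#' correlation `exp(-dt / persistenceTime)` toward zero around a
#' stationary SD chosen so that the mean instantaneous speed equals
#' `meanSpeed` (Rayleigh mean = SD * sqrt(pi/2)). Positions integrate
#' the frame velocity, so the measured per-step speed distribution has
#' exactly the requested mean; `driftSpeed` adds a constant velocity
#' along +x (the chemotactic gradient axis by convention).
#'
#' @param nTracks number of tracks.
#' @param dt frame interval (s), default 180 (3-min sampling).
#' @param duration track duration (s), default 57600 (16 h).
#' @param meanSpeed mean instantaneous speed (um/min).
#' @param persistenceTime velocity correlation time (s).
#' @param driftSpeed drift along +x (um/min), 0 for unbiased migration.
#' @param seed RNG seed.
#' @return data.frame with columns `track_id`, `t_s`, `x_um`, `y_um`.
#' @examples
#' tr <- genTracks(nTracks = 3, duration = 3600, seed = 1)
#' head(tr)
#' @export
genTracks <- function(nTracks = 50, dt = 180, duration = 57600,
                      meanSpeed = 2, persistenceTime = 1200,
                      driftSpeed = 0, seed = 1) {
  stopIfNot(dt > 0, "dt must be > 0")
  stopIfNot(duration > 0, "duration must be > 0")
  stopIfNot(meanSpeed >= 0, "meanSpeed must be >= 0")
  stopIfNot(nTracks >= 1, "nTracks must be >= 1")
  nSteps <- max(1L, ceiling(duration / dt))
  nPts <- nSteps + 1L
  sdv <- meanSpeed / 60 / sqrt(pi / 2)       # per-axis velocity SD, um/s
  phi <- exp(-dt / persistenceTime)
  driftX <- driftSpeed / 60                  # um/s
  withSeed(seed, {
    res <- lapply(seq_len(nTracks), function(id) {
      vx <- numeric(nSteps); vy <- numeric(nSteps)
      vx[1] <- rnorm(1, sd = sdv); vy[1] <- rnorm(1, sd = sdv)
      if (nSteps > 1L) {
        innov <- sdv * sqrt(1 - phi^2)
        ex <- rnorm(nSteps - 1L, sd = innov)
        ey <- rnorm(nSteps - 1L, sd = innov)
        for (k in 2:nSteps) {
          vx[k] <- phi * vx[k - 1L] + ex[k - 1L]
          vy[k] <- phi * vy[k - 1L] + ey[k - 1L]
        }
      }
      x <- c(0, cumsum((vx + driftX) * dt))
      y <- c(0, cumsum(vy * dt))
      data.frame(track_id = id, t_s = (seq_len(nPts) - 1L) * dt,
                 x_um = x, y_um = y)
    })
    do.call(rbind, res)
  })
}
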