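#' Simulate event tables for the motility and morphodynamics analyzers
#'
#' One generator for the small tabular fixtures of the downstream
#' stages. `kind` selects the table:
#'
#' * `"podosome_movie"`: podosome point sets over `nFrames` frames at
#'   `dtMin`-minute intervals from a birth-death process: each podosome
#'   survives a frame step with probability `exp(-deathRate * dtMin)`
#'   (surviving cores jitter by `jitterSd`), and `Poisson(birthRate *
#'   dtMin)` new podosomes appear uniformly in a `fov x fov` field.
#'   Columns: `frame`, `x_um`, `y_um`.
#' * `"adhesion_events"`: per-cell records of intravital adhesion in
#'   `nVessels` vessels with `Poisson(flux)` cells each; a cell rolls
#'   with probability `rollingFrac` and rolling cells draw an adhesion
#'   duration from an exponential whose rate is set so that
#'   `P(duration >= 30 s) = stickFrac`. Columns: `vessel`, `cell`,
#'   `rolling`, `adhesion_s`.
#' * `"depth_profile"`: per-cell depths below the tissue surface (um):
#'   a fraction `fracDeep` of cells lie beyond `threshold` (depth =
#'   `threshold + Exp(mean = meanExcess)`), the rest uniformly within
#'   `[0, shallowMax]`. Columns: `cell`, `depth_um`.
#' * `"bleb_trace"` / `"ruffle_trace"`: a length-vs-time trace growing
#'   linearly to `maxLength` over `growTime` s, then retracting at
#'   `retractSpeed` um/s to zero, sampled every `dt` s with additive
#'   Gaussian noise `noiseSd` (clamped at 0). Columns: `t_s`,
#'   `length_um`; the generator parameters are attached as attribute
#'   `"groundTruth"`.
#'
#' @param kind table kind, see above.
#' @param params named list overriding the per-kind defaults listed
#'   above.
#' @param seed RNG seed.
#' @return data.frame (see the per-kind columns above).
#' @examples
#' genEventTable("adhesion_events", list(nVessels = 2), seed = 1)[1:3, ]
#' @export
genEventTable <- function(kind, params = list(), seed = 1) {
  kinds <- c("podosome_movie", "adhesion_events", "depth_profile",
             "bleb_trace", "ruffle_trace")
  if (!kind %in% kinds)
    stop("unknown kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  p <- function(defaults) {
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown))
      stop("unknown parameter(s) for ", kind, ": ",
           paste(unknown, collapse = ", "))
    modifyList(defaults, params)
  }
  withSeed(seed, switch(kind,
    podosome_movie = {
      pp <- p(list(n0 = 30, birthRate = 3, deathRate = 0.1, nFrames = 4,
                   dtMin = 1, fov = 20, jitterSd = 0.05))
      pts <- cbind(runif(pp$n0, 0, pp$fov), runif(pp$n0, 0, pp$fov))
      res <- list(data.frame(frame = 1L,
                             x_um = pts[, 1][seq_len(nrow(pts))],
                             y_um = pts[, 2][seq_len(nrow(pts))]))
      surv <- exp(-pp$deathRate * pp$dtMin)
      for (f in seq_len(pp$nFrames - 1L) + 1L) {
        keep <- runif(nrow(pts)) < surv
        pts <- pts[keep, , drop = FALSE]
        if (nrow(pts))
          pts <- pts + matrix(rnorm(2L * nrow(pts), sd = pp$jitterSd), ncol = 2)
        nb <- rpois(1, pp$birthRate * pp$dtMin)
        if (nb > 0)
          pts <- rbind(pts, cbind(runif(nb, 0, pp$fov), runif(nb, 0, pp$fov)))
        res[[f]] <- if (nrow(pts))
          data.frame(frame = f, x_um = pts[, 1], y_um = pts[, 2])
        else data.frame(frame = integer(), x_um = numeric(), y_um = numeric())
      }
      do.call(rbind, res)
    },
    adhesion_events = {
      pp <- p(list(nVessels = 5, flux = 100, rollingFrac = 0.2,
                   stickFrac = 0.25, stickThreshold = 30))
      rate <- -log(pp$stickFrac) / pp$stickThreshold
      res <- lapply(seq_len(pp$nVessels), function(vs) {
        n <- rpois(1, pp$flux)
        rolling <- runif(n) < pp$rollingFrac
        dur <- ifelse(rolling, stats::rexp(n, rate = rate), 0)
        data.frame(vessel = vs, cell = seq_len(n), rolling = rolling,
                   adhesion_s = dur)
      })
      do.call(rbind, res)
    },
    depth_profile = {
      pp <- p(list(nCells = 100, fracDeep = 0.6, threshold = 10,
                   shallowMax = 10, meanExcess = 30))
      deep <- runif(pp$nCells) < pp$fracDeep
      depth <- ifelse(deep,
                      pp$threshold + stats::rexp(pp$nCells, 1 / pp$meanExcess),
                      runif(pp$nCells, 0, pp$shallowMax))
      data.frame(cell = seq_len(pp$nCells), depth_um = depth)
    },
    {
      # bleb_trace / ruffle_trace
      pp <- p(list(maxLength = 4, growTime = 60, retractSpeed = 0.1,
                   dt = 10, noiseSd = 0, tail = 3))
      tRetract <- pp$maxLength / pp$retractSpeed
      tEnd <- pp$growTime + tRetract + pp$tail * pp$dt
      t <- seq(0, tEnd, by = pp$dt)
      len <- ifelse(t <= pp$growTime, pp$maxLength * t / pp$growTime,
                    pmax(pp$maxLength - pp$retractSpeed * (t - pp$growTime), 0))
      if (pp$noiseSd > 0)
        len <- pmax(len + rnorm(length(len), sd = pp$noiseSd), 0)
      tr <- data.frame(t_s = t, length_um = len)
      attr(tr, "groundTruth") <- pp
      tr
    }
  ))
}
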