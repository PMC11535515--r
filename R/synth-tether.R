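#' Simulate a dynamic tether-pulling dataset
#'
#' For each cell x pulling velocity, a break force is drawn around the
#' Brochard-Wyart prediction [bwForce()] with multiplicative log-normal
#' noise of unit mean and coefficient of variation `forceNoiseCv`
#' (forces stay positive; `forceNoiseCv = 0` reproduces the model
#' exactly). The per-velocity summary (mean, SEM, n) is what the
#' Monte-Carlo fitter consumes. Optionally, full synthetic
#' force-vs-height retraction traces are generated for each pull: a
#' constant tether plateau at `-f` that steps to the zero baseline at a
#' random break height, sampled at `samplingRate` with additive white
#' force noise.
#'
#' @param alpha true MCA parameter (pN^3 s/um).
#' @param f0 true static tether force (pN).
#' @param velocities pulling velocities (um/s).
#' @param nCells cells per velocity.
#' @param forceNoiseCv fractional (multiplicative) break-force noise.
#' @param seed RNG seed.
#' @param traces logical; also return per-pull [ForceCurve-class]
#'   objects.
#' @param samplingRate trace sampling rate (Hz).
#' @param traceSpan retraction span rendered in each trace (um).
#' @param traceNoise additive white noise SD on the trace (pN).
#' @return A [TetherDataset-class]; when `traces = TRUE` the returned
#'   object's `groundTruth$traces` holds the list of force curves and
#'   `groundTruth$break_forces` the true per-pull break forces.
#' @examples
#' ds <- genTetherDataset(alpha = 50, f0 = 10, seed = 42)
#' tetherSummary(ds)
#' @export
genTetherDataset <- function(alpha = 50, f0 = 10,
                             velocities = c(2, 5, 10, 30), nCells = 16,
                             forceNoiseCv = 0.04, seed = 1, traces = FALSE,
                             samplingRate = 2000, traceSpan = 10,
                             traceNoise = 0.5) {
  stopIfNot(alpha > 0, "alpha must be > 0")
  stopIfNot(f0 >= 0, "f0 must be >= 0")
  stopIfNot(all(velocities > 0), "velocities must be > 0")
  stopIfNot(nCells >= 1, "nCells must be >= 1")
  stopIfNot(forceNoiseCv >= 0, "forceNoiseCv must be >= 0")
  pulls <- expand.grid(cell = seq_len(nCells), velocity_um_s = velocities,
                       KEEP.OUT.ATTRS = FALSE)
  fPred <- bwForce(pulls$velocity_um_s, alpha = alpha, f0 = f0)
  out <- withSeed(seed, {
    if (forceNoiseCv > 0) {
      sdlog <- sqrt(log(1 + forceNoiseCv^2))
      fObs <- fPred * rlnorm(nrow(pulls), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else fObs <- fPred
    trs <- NULL
    if (traces) {
      zBreak <- runif(nrow(pulls), 0.3, 0.8) * traceSpan
      trs <- lapply(seq_len(nrow(pulls)), function(i) {
        v <- pulls$velocity_um_s[i]
        n <- max(10L, ceiling(traceSpan / v * samplingRate))
        t <- seq_len(n) / samplingRate
        z <- v * t
        f <- ifelse(z < zBreak[i], -fObs[i], 0) +
          rnorm(n, sd = traceNoise)
        new("ForceCurve", data = data.frame(t_s = t, z_um = z, f_pN = f),
            samplingRate = samplingRate, pullVelocity = v)
      })
    }
    list(fObs = fObs, trs = trs)
  })
  pulls$force_pN <- out$fObs
  agg <- lapply(split(pulls, pulls$velocity_um_s), function(g) {
    data.frame(velocity_um_s = g$velocity_um_s[1],
               mean_force_pN = mean(g$force_pN),
               sem_pN = if (nrow(g) > 1L) sd(g$force_pN) / sqrt(nrow(g)) else 0,
               n = nrow(g))
  })
  summ <- do.call(rbind, agg)
  summ <- summ[order(summ$velocity_um_s), , drop = FALSE]
  rownames(summ) <- NULL
  gt <- list(alpha = alpha, f0 = f0, velocities = velocities,
             nCells = nCells, forceNoiseCv = forceNoiseCv, seed = seed,
             traces = out$trs, break_forces = pulls$force_pN)
  new("TetherDataset",
      summary = summ,
      forces = pulls[, c("velocity_um_s", "cell", "force_pN")],
      groundTruth = gt)
}
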