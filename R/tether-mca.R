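#' Brochard-Wyart tether force at a given pulling velocity
#'
#' The dynamic tether force f(v) is the unique root f >= f0 of the cubic
#' `f * (f^2 - f0^2) = alpha * v`, where `f0` is the static tether force
#' and `alpha` the membrane-to-cortex attachment (MCA) parameter, which
#' absorbs the binder density and the effective membrane viscosity.
#' Solved in closed form (trigonometric/Cardano branches) with a Newton
#' polish to machine precision; continuous and strictly increasing in v.
#'
#' @param v pulling velocity (um/s), vectorized, >= 0.
#' @param alpha MCA parameter (pN^3 s/um), > 0.
#' @param f0 static tether force (pN), >= 0.
#' @return Tether force (pN).
#' @examples
#' bwForce(0, alpha = 50, f0 = 10)   # f0
#' bwForce(8, alpha = 1, f0 = 0)     # 2
#' @export
bwForce <- function(v, alpha, f0) {
  stopIfNot(alpha > 0, "alpha must be > 0")
  stopIfNot(f0 >= 0, "f0 must be >= 0")
  stopIfNot(all(v >= 0), "v must be >= 0")
  q <- alpha * v
  f <- numeric(length(v))
  if (f0 == 0) {
    f <- q^(1/3)
  } else {
    disc <- (q / 2)^2 - (f0^2 / 3)^3    # = (q/2)^2 + (p/3)^3, p = -f0^2
    three <- disc <= 0
    if (any(three)) {
      # three real roots; the largest is the physical branch (>= f0)
      th <- acos(pmin(pmax(q[three] / 2 * (3 / f0^2)^1.5, -1), 1))
      f[three] <- 2 * f0 / sqrt(3) * cos((th - 2 * pi) / 3 + 2 * pi / 3)
    }
    if (any(!three)) {
      s <- sqrt(disc[!three])
      f[!three] <- (q[!three] / 2 + s)^(1/3) +
        sign(q[!three] / 2 - s) * abs(q[!three] / 2 - s)^(1/3)
    }
  }
  # Newton polish
  for (i in 1:3) {
    g <- f * (f^2 - f0^2) - q
    dg <- 3 * f^2 - f0^2
    stp <- ifelse(dg > 0, g / dg, 0)
    f <- f - stp
  }
  f[v == 0] <- f0
  f
}

#' Detect the tether break force in a retraction force curve
#'
#' Locates force steps on the (median-filtered) retraction trace with a
#' robust derivative threshold (`k` times the MAD of the frame-to-frame
#' force increments) and reads the break force as the difference between
#' the last plateau level and the post-break baseline. Curves with more
#' than one detected rupture step are flagged "multi-tether"; curves
#' with none return an `NA` force with flag "no-tether".
#'
#' @param curve a [ForceCurve-class] (retraction segment).
#' @param k derivative threshold in MADs (default 6).
#' @param medianWindow odd width of the median prefilter (samples).
#' @param useLastStep policy for multi-tether curves: if `TRUE`
#'   (default) the last step is still used, with the flag set.
#' @return list with `force_pN`, `flag` ("ok", "multi-tether" or
#'   "no-tether") and `nSteps`.
#' @export
detectTetherBreak <- function(curve, k = 6, medianWindow = 21,
                              useLastStep = TRUE) {
  f <- curve@data$f_pN
  if (length(f) < 3 * medianWindow)
    medianWindow <- max(3L, 2L * (length(f) %/% 6L) + 1L)
  fs <- stats::runmed(f, medianWindow)
  # lagged difference over one filter width: a rupture step reaches its
  # full amplitude here even when the filter smears it over a few
  # samples. The noise scale comes from the raw increments (the
  # filtered derivative is mostly exactly zero, so its MAD degenerates).
  L <- medianWindow
  n <- length(f)
  d <- fs[(1L + L):n] - fs[seq_len(n - L)]
  s <- mad(diff(f))
  thr <- if (s > 0) k * s else k * .Machine$double.eps * max(1, max(abs(f)))
  big <- abs(d) > thr
  if (!any(big)) return(list(force_pN = NA_real_, flag = "no-tether", nSteps = 0L))
  runs <- rle(big)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  stepRuns <- which(runs$values)
  nSteps <- length(stepRuns)
  last <- stepRuns[nSteps]
  i0 <- starts[last]; i1 <- ends[last]
  guard <- medianWindow
  plateauIdx <- max(1L, (if (nSteps > 1L)
    ends[stepRuns[nSteps - 1L]] + L + guard else 1L)):max(1L, i0 - guard)
  baseIdx <- min(n, i1 + L + guard):n
  plateau <- median(f[plateauIdx])
  baseline <- median(f[baseIdx])
  flag <- if (nSteps > 1L) "multi-tether" else "ok"
  if (nSteps > 1L && !useLastStep)
    return(list(force_pN = NA_real_, flag = flag, nSteps = nSteps))
  list(force_pN = abs(plateau - baseline), flag = flag, nSteps = nSteps)
}

#' Monte-Carlo fit of the MCA parameter Alpha
#'
#' Fits the Brochard-Wyart force-velocity relation to per-velocity mean
#' break forces by least squares over `(alpha, f0)` (with `f0`
#' bounded below at 0), and propagates the measurement uncertainty by a
#' Monte-Carlo scheme: each draw perturbs every velocity's mean force by
#' `Normal(0, SEM)` and refits; the reported Alpha is the mean +/- SD
#' over draws. With all SEMs at zero every draw is identical and the SD
#' is 0. Because each SEM is itself estimated from finitely many pulls,
#' the default additionally rescales every draw's perturbation SD by the
#' chi-distributed uncertainty of the sample SD
#' (`sqrt((n-1)/chisq(n-1))`, a Student-type correction); set
#' `studentize = FALSE` for the plain Gaussian scheme.
#'
#' @param data a [TetherDataset-class] or a data.frame with columns
#'   `velocity_um_s`, `mean_force_pN`, `sem_pN`, `n`.
#' @param nSim number of Monte-Carlo draws (the original workflow uses
#'   ~5000).
#' @param seed RNG seed (same seed and data give an identical fit).
#' @param perturb "sem" (Gaussian perturbation of the per-velocity means
#'   by their SEM; the default, matching mean +/- SEM summaries) or
#'   "cells" (bootstrap over individual pulls; requires the dataset's
#'   `forces` table).
#' @param studentize logical; apply the finite-sample SEM correction
#'   described above (default TRUE, "sem" scheme only).
#' @return A [BWFit-class].
#' @examples
#' ds <- genTetherDataset(alpha = 50, f0 = 10, forceNoiseCv = 0, seed = 1)
#' fitAlphaMC(ds, nSim = 10, seed = 1)  # alphaMean = 50, alphaSd = 0
#' @export
fitAlphaMC <- function(data, nSim = 5000, seed = 1,
                       perturb = c("sem", "cells"), studentize = TRUE) {
  perturb <- match.arg(perturb)
  s <- if (is(data, "TetherDataset")) tetherSummary(data) else data
  stopIfNot(nrow(s) >= 2, "need at least 2 velocities")
  nSim <- as.integer(nSim)
  v <- s$velocity_um_s
  fm <- s$mean_force_pN
  failedFit <- new("BWFit", alphaMean = NA_real_, alphaSd = NA_real_,
                   f0 = NA_real_, nSim = nSim, seed = as.integer(seed),
                   ok = FALSE, draws = numeric(0))
  if (diff(range(fm)) <= .Machine$double.eps * max(abs(fm), 1)) {
    warning("degenerate data: forces identical across velocities; fit failed")
    return(failedFit)
  }
  fitOnce <- function(fv) {
    # Levenberg-Marquardt with the analytic Jacobian of the implicit
    # root f(v; alpha, f0): df/dalpha = v/(3f^2 - f0^2),
    # df/df0 = 2 f0 f / (3f^2 - f0^2)
    resid <- function(par) fv - bwForce(v, alpha = par[1], f0 = par[2])
    jac <- function(par) {
      f <- bwForce(v, alpha = par[1], f0 = par[2])
      den <- 3 * f^2 - par[2]^2
      -cbind(v / den, 2 * par[2] * f / den)
    }
    f0Start <- max(0, min(fv)) * 0.8
    fmax <- max(max(fv), f0Start + 1e-6)
    aStart <- max(fmax * max(fmax^2 - f0Start^2, 1e-6) / max(v), 1e-6)
    fit <- minpack.lm::nls.lm(
      par = c(aStart, f0Start), fn = resid, jac = jac,
      lower = c(1e-12, 0), upper = c(Inf, max(fv) * (1 - 1e-12)),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 200))
    c(alpha = fit$par[1], f0 = fit$par[2])
  }
  base <- tryCatch(fitOnce(fm), error = function(e) NULL)
  if (is.null(base)) return(failedFit)
  if (perturb == "cells" && !nrow(data@forces))
    stop("perturb = 'cells' requires individual forces in the dataset")
  draws <- withSeed(seed, vapply(seq_len(nSim), function(i) {
    fv <- if (perturb == "sem") {
      scale <- if (studentize && all(s$n > 1))
        sqrt((s$n - 1) / stats::rchisq(length(fm), s$n - 1)) else 1
      fm + rnorm(length(fm), 0, s$sem_pN * scale)
    } else {
      fo <- data@forces
      vapply(v, function(vel) {
        x <- fo$force_pN[fo$velocity_um_s == vel]
        mean(x[sample.int(length(x), replace = TRUE)])
      }, numeric(1))
    }
    out <- tryCatch(fitOnce(fv)[["alpha"]], error = function(e) NA_real_)
    out
  }, numeric(1)))
  draws <- draws[is.finite(draws)]
  if (!length(draws)) return(failedFit)
  new("BWFit", alphaMean = mean(draws),
      alphaSd = if (length(draws) > 1L) sd(draws) else 0,
      f0 = unname(base[["f0"]]), nSim = nSim, seed = as.integer(seed),
      ok = TRUE, draws = draws)
}

#' Z-test comparison of two MCA fits
#'
#' `Z = |alpha_a - alpha_b| / sqrt(sd_a^2 + sd_b^2)` with a two-sided
#' p-value from the standard normal.
#'
#' @param a,b [BWFit-class] objects (both successful).
#' @return list with `Z` and `p`.
#' @examples
#' # a separation of 0.215 pooled SDs gives p ~ 0.83
#' 2 * (1 - pnorm(0.215))
#' @export
compareAlpha <- function(a, b) {
  stopIfNot(isTRUE(a@ok) && isTRUE(b@ok), "both fits must have succeeded")
  pooled <- sqrt(a@alphaSd^2 + b@alphaSd^2)
  dAlpha <- abs(a@alphaMean - b@alphaMean)
  if (pooled == 0) {
    if (dAlpha == 0) return(list(Z = 0, p = 1))
    stop("zero pooled SD with unequal means")
  }
  Z <- dAlpha / pooled
  list(Z = Z, p = 2 * (1 - pnorm(Z)))
}
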