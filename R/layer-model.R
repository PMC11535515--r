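#' Thin-layer contact model of the pinched cortex
#'
#' The compressed cortex is treated as a thin elastic layer of resting
#' thickness `h0` squeezed between a rigid sphere of radius `R` and a
#' plane-like counter-surface. The contact (mean) stress over the
#' Hertz-like contact area pi*R*delta is
#' `sigma = F / (pi * R * delta)` and the strain is `eps = delta / h0`.
#' The constitutive law of the layer is linear, `sigma = E * eps`; it is
#' isolated in [layerStress()] so a different thin-layer relation can be
#' substituted without touching the generators or the analyzers.
#'
#' @param F force (pN).
#' @param R indenting bead radius (um).
#' @param delta indentation (nm).
#' @return [contactStress()] returns the stress (Pa).
#' @name layerModel
NULL

#' @rdname layerModel
#' @export
contactStress <- function(F, R, delta) {
  # pN / (um * nm) -> Pa : 1e-12 N / (1e-6 m * 1e-9 m) = 1e3 Pa
  F / (pi * R * delta) * 1e3
}

#' @rdname layerModel
#' @param eps strain (dimensionless).
#' @param E elastic modulus (Pa).
#' @export
layerStress <- function(eps, E) E * eps

#' Indentation of the layer under a prescribed dipole force
#'
#' Solves, by bisection on delta in (0, h0), the self-consistent
#' equilibrium of the forward model: the dipole force at bead separation
#' D(delta) = beadDiameter + (h0 - delta) must equal the elastic reaction
#' of the layer, pi*R*delta*layerStress(delta/h0, E). Frames whose peak
#' force would fully compress the layer (delta >= h0) are reported via a
#' "full-compression" warning and returned as `NA`.
#'
#' @param m magnetic moment (A m^2) per frame (vectorized).
#' @param h0 resting thickness (nm).
#' @param E elastic modulus (Pa).
#' @param R bead radius (um).
#' @param beadDiameter bead diameter (um).
#' @param tol bisection tolerance on delta (nm).
#' @return list with `delta` (nm), `D` (um), `F` (pN) per frame.
#' @keywords internal
#' @export
solveIndentation <- function(m, h0, E, R, beadDiameter, tol = 1e-10) {
  dipole <- function(delta) {
    D <- beadDiameter + (h0 - delta) * 1e-3
    computePinchForce(D = D, m = m)
  }
  elastic <- function(delta)
    pi * R * delta * layerStress(delta / h0, E) * 1e-3  # back to pN
  lo <- rep(0, length(m))
  hi <- rep(h0, length(m))
  full <- dipole(hi) > elastic(hi)
  if (any(full))
    warning(sprintf("full-compression: delta >= h0 at %d frame(s)", sum(full)))
  # bisection, vectorized over frames
  for (i in seq_len(ceiling(log2(h0 / tol)) + 2L)) {
    mid <- (lo + hi) / 2
    up <- dipole(mid) > elastic(mid)  # force excess -> indent further
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  delta <- (lo + hi) / 2
  delta[full] <- NA_real_
  # fully compressed frames: beads in contact, thickness undefined
  D <- beadDiameter + ifelse(is.na(delta), 0, h0 - delta) * 1e-3
  list(delta = delta, D = D, F = computePinchForce(D = D, m = m))
}
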