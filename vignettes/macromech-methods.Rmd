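---
title: "Models and methods behind macromech"
author: "macromech authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind macromech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macromech)
```

macromech quantifies three aspects of macrophage surface mechanics and
behavior: the thickness and stiffness of the actomyosin cortex measured
with a magnetic pincher, the membrane-to-cortex attachment (MCA)
measured by AFM tether pulling, and migration/morphodynamics statistics
(2D and transwell migration, intravital adhesion, tissue infiltration,
podosome turnover, ruffle and bleb retraction). Every analyzer has a
matching synthetic-data generator with known ground truth, so the whole
pipeline is testable end to end without any external data. This
vignette explains the models, the defaults and why they were chosen,
and what the synthetic tests do and do not demonstrate.

## The magnetic pincher

Two superparamagnetic beads — one phagocytosed, one outside the cell —
align along a uniform magnetic field and squeeze the cortex between
them. The cortex thickness is simply the surface-to-surface gap,
`h = ||c1 - c2|| - d_bead`, which is why subpixel bead localization is
the critical measurement step.

**Force model.** The beads are treated as coaxial point dipoles aligned
with the field:

$$F = \frac{3\mu_0 m(B)^2}{2\pi D^4},$$

attractive and reported positive in pN. The bead magnetization follows
a saturating law $m(B) = m_{sat} B/(B + B_{1/2})$ with $B_{1/2}$ = 12 mT;
$m_{sat}$ is calibrated so that two touching 4.5-µm beads at the 5-mT
nominal field attract with ~100 pN, the typical holding force of the
protocol. This calibration is a configuration default, not a measured
property of any particular bead lot, and `magnetizationModel()` accepts
other parameters. Mutual-magnetization (image dipole) corrections are
omitted; at bead separations within a few hundred nm of contact this
underestimates the true force by a geometry-dependent factor, which is
a known limitation shared by the point-dipole approximation generally.

**Field protocol.** The default `genFieldProtocol()` reproduces the
compression scheme: hold at 5 mT, every 10 s dip to 1 mT, then ramp
linearly to 54 mT in 1.5 s, and return to nominal. Two timing choices
are the package's own:

* *Dip duration 0.5 s.* The dip supplies the reference frames from
  which the resting thickness of each cycle is estimated; a finite
  dwell (50 frames at the default rate) makes that reference robust to
  localization noise.
* *Acquisition rate 100 frames/s.* The stress window used for the
  modulus fit (150–350 Pa) is crossed early in the 1.5-s ramp — in a
  few tens of milliseconds for stiff, thin cortices. At 100 fps
  (the full-frame rate of the sCMOS camera used on such setups) the
  window contains enough frames for a slope to be defined in every
  regime the package is tested on; at video rate it does not.

**Forward model of the generator.** At each frame the generator solves,
by bisection on the indentation $\delta \in (0, h_0)$, the equilibrium
between the dipole force at separation $D(\delta)$ and the elastic
reaction of the layer, $\pi R \delta\, \sigma(\delta/h_0)$. The
constitutive law is the same one the analyzer inverts (see below), so
forward–inverse consistency is an exact, model-independent contract:
whatever thin-layer law is plugged into `layerStress()`, a noiseless
recording must round-trip. Parameter sets that would fully compress the
layer at peak force raise a "full-compression" warning and mark those
frames invalid rather than clipping silently. Localization noise is
isotropic Gaussian per axis and per bead, with separate XY and Z SDs
(defaults 15 and 40 nm — in-plane centroiding is more precise than
axial localization from the piezo/stack geometry).

**Thin-layer contact model.** The analyzer converts each compression
into strain and stress with the thin-layer (Chadwick-type) surrogate

$$\varepsilon = \delta/h_0, \qquad \sigma = \frac{F}{\pi R \delta},$$

i.e. the mean pressure over the Hertz-like contact area $\pi R \delta$.
The constitutive law is linear, $\sigma = E\varepsilon$. Both relations
are isolated in single functions (`contactStress()`, `layerStress()`)
so that an exact Chadwick (1988) expression, including any two-sphere
geometric prefactor, can be substituted without touching generators,
analyzers or tests — the tests rely only on forward–inverse
consistency, which such a substitution preserves.

**Reference-thickness correction.** The per-cycle reference `h0Ref` is
the median thickness over the low-field dip. The dip force is small
(a few pN) but not zero, so the dip thickness underestimates the
resting thickness by the pre-indentation
$\delta_{dip} = \sqrt{F_{dip} h_0 / (\pi R E)}$ — up to ~17 nm for a
soft 400-nm cortex — which, if ignored, biases the fitted modulus by
several percent. `analyzePinchRecording()` therefore iterates a fixed
point: fit the modulus with the current reference, recompute
$\delta_{dip}$ from the fit, update the reference, and repeat. On
noiseless data this converges to the exact forward model in two
iterations; on noisy data it converges because the correction is a
contraction (its derivative is of order $\delta_{dip}/2h_0 \ll 1$).

**Modulus estimators.** `fitTangentialModulus()` reports the tangent
$d\sigma/d\varepsilon$ inside a stress window (default 150–350 Pa, the
low-stress regime) with two methods:

* `method = "direct"` is the literal least-squares slope of $\sigma$ on
  $\varepsilon$ over the in-window points. It is exact on clean curves
  but ill-posed under realistic thickness noise: in the window the
  indentation is 10–20 nm for typical parameters, comparable to the
  noise SD, and $\sigma = F/(\pi R \delta)$ diverges as a noisy
  $\delta$ crosses zero.
* `method = "layer"` (default) reparameterizes the same fit. The
  product $\sigma\varepsilon = F/(\pi R h_0)$ contains no thickness
  noise because the force is computed from the known field. On the
  linear law, $\varepsilon = u/\sqrt{E}$ with $u = \sqrt{\sigma
  \varepsilon}$, so regressing strain on $u$ (with an intercept that
  absorbs residual reference error) puts all the noise on the response
  side, linearly and symmetrically. The fit pools every frame of the
  compression and the result *is* the window tangent — identically so
  for a linear layer, which is the regime the window is meant to
  capture. For a strain-stiffening material the two methods differ:
  "layer" returns a compression-wide effective modulus, "direct" a
  local slope; users fitting nonlinear cortices should prefer "direct"
  on low-noise data or swap in the appropriate law.

Per cell, the modulus is the median over cycles and the thickness
metric is the median thickness over all unflagged frames within
0.25 mT of the nominal field, matching the robustness conventions of
the measurement. Frames flagged (e.g. phagocytosis in progress) are
excluded throughout, and cycles whose dip or ramp is entirely flagged
are dropped.

**Bead detection and linking.** Coarse maxima above a robust threshold
are refined by a Gaussian-masked centroid whose mask re-centers on the
running estimate; at its fixed point the mask is concentric with a
symmetric spot, making the estimate unbiased, while the mask suppresses
far-field noise. Linking uses globally optimal per-frame-pair
assignment (a hand-written Jonker–Volgenant shortest-augmenting-path
solver, exact, tested against brute-force enumeration) with a maximum
per-frame displacement; unmatched detections start new trajectories
(never force-assigned), and trajectories survive configurable detection
gaps. Overlapping-bead frames (D below the bead diameter) are flagged
and excluded rather than clamped, since they indicate tracking error or
membrane wrap.

## Tether pulling and the MCA parameter

A membrane tether pulled at velocity $v$ exerts a force $f(v)$ given by
the Brochard–Wyart relation, used here in the cubic form

$$f\,(f^2 - f_0^2) = \alpha v,$$

where $f_0$ is the static tether force and $\alpha$ (pN³·s/µm) is the
MCA parameter, absorbing the binder density and effective membrane
viscosity. The unique physical root $f \ge f_0$ is evaluated in closed
form (trigonometric/Cardano branches) with a Newton polish; the
functional form is isolated in `bwForce()` so a different
parameterization can replace it without touching the fitter.

**Break detection.** On the retraction trace, rupture steps are found
on a lagged difference of the median-filtered force (lag = one filter
width, so a step reaches its full amplitude even when the filter smears
it), thresholded at *k* = 6 times the MAD of the raw increments. The
break force is the difference between the last plateau and the
post-break baseline medians. Curves with several steps are flagged
"multi-tether" (the last step is used by default); breaks smaller than
roughly $k\sqrt{2}$ times the per-sample noise are undetectable and
come back as "no-tether".

**Monte-Carlo fit.** `fitAlphaMC()` fits $(\alpha, f_0)$ to the
per-velocity mean forces by Levenberg–Marquardt with the analytic
Jacobian of the implicit root, $f_0$ bounded below at zero. Uncertainty
is propagated by perturbing each velocity's mean with Gaussian noise of
its SEM and refitting (~5000 draws in the original workflow; tests use
1000). Because each SEM is itself estimated from finitely many pulls
(16 cells per velocity by default), each draw's perturbation SD is
rescaled by the chi-distributed uncertainty of a sample SD — a
Student-type correction that measurably improves the calibration of the
reported mean ± SD without changing its center. The plain scheme is
available with `studentize = FALSE`, and a bootstrap over individual
pulls with `perturb = "cells"`. Two conditions are compared with a
Z-test on the fitted Alphas, $Z = |\alpha_a - \alpha_b| /
\sqrt{sd_a^2 + sd_b^2}$, two-sided normal p-value.

**Generator noise.** Break forces are drawn around the model prediction
with multiplicative log-normal noise of unit mean (forces stay
positive). The default coefficient of variation is 0.04 per pull: the
generator models break-force measurement repeatability only, not
cell-to-cell variability in MCA, and with 16 cells per velocity this
puts the SEM near 1% of the mean. A Fisher-information analysis of the
default truth ($\alpha = 50$, $f_0 = 10$, velocities 2/5/10/30 µm/s)
gives $SD(\hat\alpha) \approx 320\,cv/\sqrt{n_{cells}}$ — the
force–velocity curve is shallow, so $\alpha$ is intrinsically hard to
pin down, which is precisely why the Monte-Carlo uncertainty and the
Z-test matter in practice. Real datasets, with biological scatter on
top, will show proportionally wider Alpha distributions; the synthetic
recovery tests demonstrate correctness of the machinery, not the field
precision of the assay.

## Migration and morphodynamics statistics

**Track metrics.** Per track: instantaneous speeds from consecutive
samples (step length over the actual time step, in µm/min; gaps are
handled by the actual $\Delta t$), median speed, net and total
distances, and the confinement ratio net/total (0 for a motionless
track). "Directionality" is treated as a synonym of the confinement
ratio — the source conventions do not distinguish them. The forward
migration index (FMIx) projects the net displacement on the gradient
axis (+x by convention, configurable) and divides by the total path, so
$|FMI| \le CR$ always. The "longer than 1 h" track filter is a strict
inequality, read literally. Transwell migration counts cells in
z-layers at fixed intervals (default 30 µm): percent migration is the
in-matrix fraction, and each cell's migration distance is quantized to
its layer depth. Rolling fractions are per-vessel percentages of
rolling cells in the total flux; sticking fractions are the percentage
of rolling cells adhering at least 30 s, and are reported missing (not
zero) when no cell rolls. Infiltration applies a strict depth threshold
(default 10 µm below the tissue surface).

**Persistent random walk generator.** Cell velocity follows a discrete
Ornstein–Uhlenbeck process with correlation $e^{-\Delta t/P}$
(persistence time $P$, default 20 min) and a stationary per-axis SD set
so the mean speed equals the requested value (Rayleigh mean,
default 2 µm/min at 3-min sampling over 16 h, the 2D assay geometry).
Positions integrate the frame velocity, so the generated per-step speed
distribution has exactly the requested mean. Drift adds a constant
velocity along +x. The generator emulates track statistics only — no
cell shape, no contact interactions, no confinement — so passing tests
show the *statistics* are computed correctly, not that real macrophage
tracks follow an OU process.

**Podosome turnover.** Between consecutive frames (four frames at 1-min
intervals in the source assay), cores are matched one-to-one within a
radius (default 0.5 µm, the podosome core scale) by exact
minimum-total-distance assignment that first maximizes the number of
matches; matched cores are "maintained", the rest "appearing" or
"disappearing". Percentages are taken relative to the mean core count
across frames and averaged over intervals — this denominator is a
declared convention (configurable in effect through the returned
counts) since the original counting scheme is not fully specified.
The matcher is tested for exact agreement with brute-force enumeration.

**Ruffles and blebs.** A ruffle trace yields its maximal elongation,
the time from the maximum to the first sample at or below a
disappearance threshold (default 0, a configurable noise floor), and
their ratio as retraction speed. A bleb trace yields the maximum size
and the magnitude of the least-squares slope over the post-maximum
decreasing phase; the phase ends at the first near-zero sample (5% of
the maximum) so a flat post-collapse tail does not dilute the slope,
and a trace with no decreasing phase is an error, not a zero.

## Numerical and reproducibility choices

* Indentation bisection to 1e-10 nm; cubic roots polished by Newton to
  machine precision; Levenberg–Marquardt with `ftol = ptol = 1e-15`.
* Assignment ties are resolved deterministically by the solver's
  scan order (lowest index first).
* All generators take an explicit integer seed and restore the
  caller's RNG state; identical seeds give bit-identical outputs, and
  identical pipeline configurations give byte-identical JSON reports
  (reports carry the package version and no timestamps).
* Degenerate inputs fail loudly with named messages: empty frames,
  constant field traces, all-flagged cycles, zero total cell counts,
  velocity-independent tether forces, zero pooled SDs.

**Problem sizes in the test suite** (chosen to keep the default run in
the low minutes): pincher round trips use the full 8-cycle, 100-fps
protocol (~8800 frames per recording; 9 noiseless parameter
combinations and 50 noisy replicates); tether recovery uses 50
replicates of 16 cells x 4 velocities with 1000 Monte-Carlo draws;
track symmetry uses 500 sixteen-hour tracks; the matching oracle is
checked on 200 random frames of up to 6 points plus the linking cases.

## Limitations

* The dipole force model omits mutual magnetization and chain effects
  (two beads only, no multi-bead force models).
* The default magnetization curve is a calibration convention, not a
  measured M-450 curve; absolute moduli on real data inherit its
  accuracy, though ratios between conditions do not depend on it.
* The linear layer law is a surrogate for the exact thin-layer contact
  expression; the swap point is provided but the exact form is not
  bundled.
* Rendered bead images are symmetric Gaussian spots — no bright-field
  ring structure, no defocus; Z comes from stage metadata, not from
  image content.
* Synthetic tether data contain measurement noise only; biological
  cell-to-cell MCA variability is not modeled.
* No viscoelastic/creep analysis, no thickness-fluctuation spectra, no
  cell segmentation or tracking from raw movies of cells.
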