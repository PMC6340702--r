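---
title: "Bayesian inference of retinotopic maps: models, potentials, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian inference of retinotopic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retinomap)
```

# The problem

Visual cortex contains retinotopic maps: orderly projections of the visual
field onto the cortical surface.  Voxel-wise pRF fits measure these maps,
but the measurements are noisy, cover only the stimulus aperture,
systematically miss the vertical-meridian representations, and say nothing
about areal boundaries.  Atlases derived from anatomy alone are smooth and
complete but ignore individual differences in how function maps onto
anatomy.  `retinomap` combines the two: a 2D model of retinotopy acts as a
prior, a subject's noisy per-vertex measurements act as the observation,
and a topology-preserving mesh registration computes the maximum a
posteriori warp that reconciles them.  Every native vertex then inherits a
full-field prediction of polar angle, eccentricity, pRF size and
visual-area label.

# The registration potential

The subject's flattened map is a triangle mesh with reference coordinates
$x_0$, undirected edges $E$, corner triples $\Theta$, perimeter vertices
$P$ and anchors $\Phi$.  Registration minimizes

$$F(x) = F_e(x) + F_\theta(x) + F_p(x) + F_\varphi(x)$$

* $F_e = (H_e + G_e)/|E|$ penalizes edge-length changes: a harmonic part
  $H_e = \tfrac12\sum (r - r_0)^2$ and an infinite-well part $G_e$ that
  diverges as any edge length approaches the well bounds $(q_0, q_1)$.  By
  default $q_0 = 0$ and $q_1 = 2 r_0$ per edge: edges may shrink toward
  zero and at most double.
* $F_\theta = (H_\theta + G_\theta)/|\Theta|$ does the same for corner
  angles, with wells at $0$ and $\pi$.  Together the wells make face
  inversion impossible: a face can only invert by passing through a
  configuration of infinite cost.
* $F_p = \tfrac12 \sum_{u \in P} \|x_u - x_{0,u}\|^2$ pins the map
  perimeter.
* $F_\varphi = -\tfrac{1}{|\Phi|} \sum_{(u,y,\sigma,w)} w\,
  e^{-\|x_u - y\|^2/\sigma^2}$ is a sum of *inverted-Gaussian wells*: each
  measured vertex is attracted to the model position that represents its
  measured polar angle and eccentricity, once per modeled area.  The sign
  is negative so anchors are wells — the term decreases as a vertex
  approaches its anchor.

In Bayesian terms, $\exp(-(F_e + F_\theta + F_p))$ is the prior over warps
(zero prior probability for topology-violating configurations),
$\exp(-F_\varphi)$ is the likelihood of the measurements, and minimizing
$F$ maximizes the posterior; `posteriorDensity()` exposes $e^{-F}$.

## Anchors

For each vertex with variance explained $\omega \ge 0.1$ (exactly 0.1 is
retained), one anchor is placed per modeled area at the point where that
area represents the measured coordinates; areas that do not represent them
(for example a quarterfield band on the wrong side of the horizontal
meridian, or an eccentricity beyond the model range) contribute none.  The
well width $\sigma$ is the minimum distance from the anchor point to any
other anchor point of the same vertex, capped at $20\varepsilon$
($\varepsilon$ = mean edge length) and floored at $\varepsilon/2$ — a well
narrower than half an edge cannot be resolved by the mesh, and its
near-singular gradient would throttle the step size globally.  The base
weight is $\omega$, reduced by a factor 0.25 when the local field sign of
the data contradicts the target area's field sign, and by the log-normal
factor $\exp(-\ln^2(s_{obs}/s_{model}) / (2\ln^2 2))$ comparing the
measured pRF size to the model's linear size-vs-eccentricity function.
Both factors can be disabled.

## The minimizer

Gradient descent runs for a fixed 2500 steps.  Each vertex's displacement
per step is capped at $\varepsilon/50$; a global step scale is
warm-started and doubled after success, and each vertex's move is clipped
to the cap individually, so a few steep vertices cannot starve the rest.
Per-vertex multiplicative exponential noise (factor $1 + \lambda
\mathrm{Exp}(1)$, $\lambda = 0.7/\ln 2$ so the median factor is 1.7)
scales gradient magnitudes while preserving directions.  A step is
rejected — and retried at half size, up to 50 times — if it would cross an
edge-length or angle singularity, or if it would raise the potential by
more than the *injected-noise tolerance* (a relative slack of $10^{-3}$,
active only while noise is on; with `noiseScale = 0` descent is strictly
monotone).  The returned configuration is the best one visited.

The noise and its acceptance slack are not cosmetic.  The barrier terms
give the potential a stiffness about three orders of magnitude above the
anchor forces; strictly monotone descent is then curvature-limited to
steps far below the displacement cap and cannot traverse a realistic warp
in 2500 steps.  With noise and slack enabled, per-vertex steps stay near
the cap, the smooth warp mode is recovered within a few hundred steps, and
the stiff modes merely jitter at the cap scale — the noise speeds up
convergence substantially without changing the minimum.  Consequences: the
registered solution carries a jitter floor of roughly $\varepsilon/50$ map
units, and the potential trajectory is non-increasing only up to the
stated tolerance.

## Topology

At every accepted step all corner angles lie in $(0, \pi)$ and all edge
lengths in $(q_0, q_1)$; `RegistrationResult` records the extremes seen.
Mapping any closed region of the visual field through the inferred maps of
one area therefore yields a connected cortical patch: the predictions are
topologically smooth even where the data are not.

# Building models of retinotopy

A model is built from labeled boundary contours (foveal, peripheral,
upper/lower vertical meridian, horizontal meridian) snapped to mesh
vertices.  The label-implied scaled values ($\hat\theta = \mp 1$ at the
vertical meridians, $0$ at the horizontal; $\hat\rho = \mp 1$ at the
foveal/peripheral boundaries) are held fixed, and both fields are filled
in by minimizing

$$f(\theta, \rho) = (\theta \cdot \rho)^2 + \sum_{(u,v) \in E}
\frac{(\theta_u - \theta_v)^2 + (\rho_u - \rho_v)^2}{2\,\|x_u - x_v\|},$$

smoothness plus a soft orthogonality coupling.  Stationarity reads
$L\theta + d\rho = 0$, $L\rho + d\theta = 0$ on the free vertices with the
scalar $d = \theta\cdot\rho$; for fixed $d$ these are sparse linear
systems, so the solver iterates a secant root-find on $d$ with one direct
sparse solve of the stacked free fields per step, initialized at the
decoupled harmonic solution.  (Plain
alternating quadratic minimization is exact per sweep but contracts at a
spectral radius near one — its slow mode is $d$ itself — and can settle
into a two-point limit cycle; the secant formulation converges to a joint
gradient norm of $10^{-8}$ in a handful of solves.)  The recorded
objective trajectory is non-increasing.

Afterwards polar angle maps linearly to $[0°, 180°]$ and eccentricity
through the two-parameter exponential $\rho = a(e^{bs} - 1)$,
$s = (\hat\rho+1)/2$, with $(a, b)$ fitted so the minimum, median and
maximum hit the configured targets (default 0°, 3°, 90°).  A hemisphere's
model covers one hemifield; the contralateral sign lives in the hemisphere
flag, never in $\theta$.

# The synthetic generator

`syntheticConfig()` defines the study conditions; `makeDataset()` composes
a ground-truth model, a warped subject and noisy scans.

* **Model geometry.** A quarterfield band stack
  hV4 | V3v | V2v | V1 | V2d | V3d | V3a on a strip 1 map unit wide
  (eccentricity axis) and 8 tall, quarterfield height 1, lattice edge
  $\varepsilon = 1/40$ of it.  The ratio matters: the $20\varepsilon$ cap
  on anchor widths must stay well below the band height, or anchors in
  neighboring areas blur together; $1/40$ is the coarsest lattice that
  keeps the method in its intended regime while remaining registerable in
  tens of seconds on one CPU.  Outer bands flank V1–V3 so anchors from
  non-target areas exert realistic pull.  Eccentricity targets (0, 3, 90)°
  compress the fovea as real maps do.
* **Subject warp.** A sum of 12 Gaussian bumps of width 2.5 map units —
  deliberately low-dimensional, area-scale structure, which is both what
  individual differences in these maps look like and the regime the
  method is designed to capture.  The polar-angle axis dominates (axis
  weights 0.15 : 1, each axis RMS-normalized so chance cancellation in one
  cannot inflate the other); displacements taper smoothly to zero toward
  the map edges along their own axis (the rim is anatomically anchored and
  pinned by the perimeter term); a smooth tanh limiter at 1.75x the mean
  eliminates rare extreme displacements; and the result must keep every
  edge within 45% strain so the warp and its inverse stay strictly inside
  the registration wells.  The mean displacement equals the requested
  amplitude, by default $5\varepsilon$.
* **Measurement noise.** Per scan: Gaussian polar-angle noise (sd 20°),
  log-normal eccentricity noise (sd 0.1, keeping $\rho > 0$), Gaussian
  pRF-size noise (sd 0.2°, floored at 0.01°); variance explained is
  Beta(2.5, 3) (mean 0.45), crushed toward zero within 10° of the vertical
  meridians (meridian dropout), inside subject-level artifact blobs that
  also carry a coherent +25° angle offset, and beyond the 12° stimulus
  aperture.  Averaging $k$ scans shrinks noise as $1/\sqrt{k}$.  With all
  noise sds zero the generator is fully deterministic and variance
  explained sits at the Beta mean.

What the generator does *not* emulate: cortical folding and curvature,
spatially correlated (vessel-like) noise with high variance explained,
pRF-fit outliers with heavy tails, and imperfect anatomical alignment
(identity alignment is the default).  Passing tests therefore demonstrate
correct mechanics and the expected ordering of methods under controlled
conditions, not performance on real fMRI data.

# The scaled-down study

Ten seeded subjects are generated at the default conditions and each is
registered from a single noisy scan.  Predictions are compared against
ground truth on the V1–V3 region within 12° of eccentricity, weighted by
the variance explained of a held-out six-scan validation average, using
the eccentricity-scaled error (visual-field distance divided by the
validation eccentricity).  Three methods are compared: the measurements
alone, the prior alone (model lookup at the unregistered coordinates), and
the Bayesian inference.  At these noise levels the prior is already much
better than a single scan, and the Bayesian fit improves on the prior by a
small but systematic margin; by six averaged scans the data alone overtake
both — the same ordering and crossover the method was designed around.
The registration's correction is deliberately conservative: the elastic
prior resists deformation, so with weak data the posterior stays close to
the prior ("without observation, the prior remains the prediction" is the
limiting case, which holds bit-for-bit).

Known limitation: with perfect data on an unwarped subject the potential's
minimum is not exactly the identity — anchors in neighboring areas exert a
residual boundary-ward pull, and the minimizer's jitter floor is
$\varepsilon/50$ — so the fixed point holds to median sub-millidegree
precision, not machine precision.  The same mechanism means maps whose
true boundaries deviate from the model's meridian assumptions are pulled
toward the model, a bias inherited from the prior and shared with the
original method.

# Numerical choices

* Degenerate faces (area $\le 10^{-12}$) are excluded from corner triples
  and field-sign computation with a warning.
* Point-in-triangle queries on shared edges resolve to the lowest face
  index; location uses a uniform grid over face bounding boxes.
* Angular fields are always interpolated through their visual-field
  Cartesian embedding, never as raw angle numbers.
* Vertex surface area is one third of each incident face's area, which
  conserves total area exactly.
* The cortical magnification disk estimator uses $\alpha = \rho/3$ and
  inclusive membership ($\le \alpha$); its exact value on a
  complex-log map is $k^2/(\rho^2 - \alpha^2)$, the disk average of
  $k^2/r^2$, and tests compare against that closed form.
* pRF-size predictions are floored at 0.01° and fitted per area by
  weighted least squares of measured size on *inferred* eccentricity;
  areas with fewer than two usable vertices are left `NA`.
* All randomness is seeded; identical configurations reproduce
  byte-identical outputs.

# Problem sizes

The default synthetic model has about 15,000 vertices and 30,000 faces;
one full 2500-step registration takes tens of seconds on a single core.
The packaged study uses ten subjects for the recovery comparison, three
for the extrapolation analysis, and a coarse (1/10-resolution) variant for
structural unit tests.
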