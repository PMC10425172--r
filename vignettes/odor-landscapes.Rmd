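---
title: "Modeling, measuring, and navigating odor landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling, measuring, and navigating odor landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorscape)
```

# The system

A laminar flow chamber (15 cm wide, 1 cm deep, with 15 parallel inlet
tubes) carries odorized and clean humidified air over an agar arena at a
bulk speed of ~0.5 cm/s. Routing the odorized stream to different inlets
produces stationary landscapes — a central "cone", an "inverse cone" with
odor on both flanks, a "biased cone" offset 4 cm from the centerline. An
array of up to 112 metal-oxide gas sensors (7 bars of 16, in a staggered
triangular grid with 0.75 cm effective spanwise resolution) reads the
concentration field at 1 Hz, calibrated against a photo-ionization
detector (PID). Animals — *C. elegans* at ~0.1 mm/s or *Drosophila*
larvae at ~3 mm/s — crawl on the agar while the landscape is monitored
at its boundary.

This vignette documents the models the package implements, the defaults
and why they were chosen, what the synthetic data emulate, and the
numerical decisions a user should know about.

# Sensor calibration

Each metal-oxide sensor responds logarithmically over its useful range, so
the raw reading `r` maps to concentration as

$$\mathrm{ppm}(t) = A \exp\!\big(B\, r(t - \tau)\big),$$

with the transport delay $\tau$ between the sensor and the downstream PID.

**Delay estimation.** Both series are linearly resampled onto a common
grid at the coarser of the two rates and compared by *per-lag Pearson
correlation* with per-window standardization, with parabolic sub-sample
refinement of the peak. Two pitfalls drove this choice: an unnormalized
cross-correlation is biased toward zero lag because the overlap shrinks
with lag, and global (rather than per-window) mean subtraction distorts
the flat-topped correlation of slow calibration waveforms (500 s triangle
ramps). The default search window is a tenth of the overlap, which also
excludes the period alias of cyclic waveforms; a peak at the window edge
raises a warning rather than returning silently.

**Curve fitting.** The exponential is fit in log space — a linear
regression of $\log(\mathrm{ppm})$ on $r$, with the reference clipped at a
1e-3 ppm floor to stabilize logs — and the goodness of fit is reported in
linear ppm space. Log-space fitting makes the problem convex and
homoscedastic when the dominant noise is multiplicative, which is what
sensor and PID noise look like. A constant reference (or constant raw)
yields a flagged degenerate curve rather than an error. Validation refits
the curve on an independent replicate and reports the maximum fractional
change of predicted concentration over the common raw range; the pass
threshold is 10% of the concentration scale, the stability the instrument
itself achieves between recordings.

The PID's volts-to-ppm gain is a user-supplied constant (the detectors
come in 0–200 and 0–1000 ppm ranges); it is configuration, never inferred.
Curves are fit per sensor with no pooling.

# The steady plume

At the operating point the Péclet number $vL/D \approx 80$, so streamwise
transport is convective and spanwise transport diffusive. The steady
landscape obeys the boundary-layer balance

$$v\,\frac{\partial C}{\partial x} = D\,\frac{\partial^2 C}{\partial y^2},$$

which is a 1-D diffusion equation with $x/v$ playing the role of time:
cross-sections are Gaussians of variance $\sigma^2(x) = 2Dx/v$.
`steady_plume_field` marches this equation downstream from a top-hat
source at the inlet (width = one inlet-port spacing, 1 cm by default) with
no-flux side walls, refining the internal step below the explicit
stability limit. A grid coarser than a quarter of the plume width at the
first node is rejected rather than silently smoothed.

`fit_plume` recovers the effective diffusivity from a sensor snapshot by
minimizing the mean squared error over $D$, with the source amplitude and
spanwise position profiled out. Two modeling details matter:

* The closed form used for fitting conserves mass
  ($C \propto \sigma^{-1} e^{-(y-y_0)^2/2\sigma^2}$), with a free peak
  amplitude per fit. A printed steady solution with an error-function
  prefactor decaying in $x$ is not consistent with a sustained source;
  the marching solution with Gaussian cross-sections is the operative
  model throughout.
* The finite source footprint adds $w^2/12$ to every cross-section's
  variance. Ignoring it biases $\hat D$ upward by roughly
  $v\,w^2/(24\,\bar x)$ — ~40% at $D = 0.02$ cm²/s in this geometry — so
  the known footprint enters the fit as a fixed variance offset
  (`source_width`; set it to 0 for an ideal point source).

The dimensionless diagnostics are exact bookkeeping: bulk velocity = flow
rate / cross-section; $\mathrm{Re} = v\,\mathrm{depth}/\nu \approx 7.4$
per L/min with $\nu = 0.15$ cm²/s, far below the turbulence onset;
$\mathrm{Pe} = vL/D$ with the streamwise length of the measured arena
(~13 cm) as $L$, exposed as a parameter because the choice of $L$ is a
convention. The droplet calculations use the ideal gas law (molar volume
$RT/P$) and a spectral solution of diffusion in a closed box (products of
reflecting-wall Green's functions), which conserves mass exactly and
tends to the uniform equilibrium concentration.

# Odor–agar interaction and pre-equilibration

Butanone is highly water soluble, so the agar absorbs and re-emits it.
The package models this with a reaction–convection–diffusion system: the
airborne field $C$ obeys the convection–diffusion operator plus a sink
$-w\,\partial A/\partial t$, and the absorbed concentration $A$ (nonzero
only on the agar mask) follows saturable first-order kinetics

$$\frac{\partial A}{\partial t} = k_a C\left(1 - \frac{A}{M}\right) - k_d A.$$

**Key property.** At steady state $\partial A/\partial t = 0$, so the sink
vanishes and the airborne field equals the agar-free steady field — no
matter what $(w, k_a, k_d, M)$ are. This is why boundary measurements
suffice to infer the interior landscape at quasi-equilibrium, and the
package verifies it both for the non-spatial model (fixed point
$C^* = C_o$, $A^* = k_a C_o M/(k_a C_o + k_d M)$) and numerically for the
spatial solver.

**Defaults.** The kinetic constants are not measurable directly; the
defaults ($k_a = 0.05$ /s, $k_d = 0.001$ /s, $M = 2\times$ the target
source concentration, $w = 1$, $\tau$ = chamber volume / flow rate ≈ 34 s)
put the system in the strongly absorbing regime ($k_a \gg k_d$, target
$C_o < M$) where the phenomena of interest occur: a drastically depressed
downstream profile shortly after flow onset, a many-minute approach to
equilibrium under a constant source, and re-emission after shutoff. Only
regime-level behavior is asserted about them, never the values themselves.

**Numerics.** First-order upwind convection, explicit centered diffusion,
and a local reaction substep, with the time step at 80% of
$\min(dx/v,\ dx^2/4D,\ 1/10(k_a+k_d))$; the default grid is 2 mm. The
inlet column is a Dirichlet boundary (top-hat profile from the source
schedule), the outlet is zero-gradient, and the side walls are no-flux.
The per-step mass budget (interior air + $w\times$agar vs. influx −
outflux) closes to solver precision and is returned for inspection.
Upwind convection introduces numerical diffusion of order $v\,dx/2 =
0.05$ cm²/s streamwise; it does not affect the spanwise structure that
the analyses use, and the agar-free steady state agrees with the
marching closed form to well under 3% RMS.

**Pre-equilibration.** `design_preequilibration` simulates the bench
protocol: flow a boosted source concentration (typically above $M$),
monitor the mean concentration at downstream probe positions, and switch
to the target the first time the monitor reaches the agar-free steady
value for the target. The monitored probes default to three positions
just downstream of the agar on the plume axis, mirroring where boundary
sensor bars sit. Paired simulations confirm the protocol strictly
shortens the time to a stable target relative to a constant source, and
the post-switch field settles to within a few percent of the agar-free
landscape over the agar region.

`boundary_profiles` extracts the spanwise profiles where the boundary
sensor bars sit; by default 1 cm away from the agar edge. The offset
matters upstream: a perturbation propagates against the flow over the
length $D/v \approx 1.6$ mm, so the immediately adjacent grid row is
contaminated while 1 cm away it is not — and the physical sensor bars
cannot touch the agar anyway.

# Field reconstruction

The sparse array snapshot becomes a continuous field by thin-plate-spline
smoothing: the $r^2 \log r$ radial basis plus an affine part, coordinates
scaled by the spline length scale (default: the median inter-sensor
spacing, ~1 cm), and a dimensionless smoothing parameter $\lambda$
(default 1e-4) on the diagonal. With $\lambda = 0$ the surface
interpolates the sensors exactly; the default applies light smoothing
against sensor noise. The exact spline family behind the instrument's own
interpolation is not specified anywhere, so this choice is documented and
configurable: it reproduces constants exactly, is shift-equivariant, and
reconstructs a forward-modeled plume from 112 sensors to under 2% RMS of
the peak inside the sensor hull. Negative interpolant values are clipped
to zero with a logged count, and grid nodes outside the convex hull of
the sensors are flagged as extrapolated. Humidity sensors are carried in
layouts but excluded from concentration interpolation.

Gradients are centered finite differences after a Gaussian pre-smoothing
of the field ($\sigma = 0.5$ cm), one-sided at the edges. The smoothing
suppresses grid-scale noise that differencing would amplify; it leaves
constants and interior linear ramps exact. Bearings are undefined where
the gradient magnitude is below 1% of the field's maximum gradient —
below that floor the direction is noise — and such samples are excluded
from bearing-conditioned statistics.

# Navigation analysis

**Conventions.** The bearing $\theta$ is the signed angle from the local
gradient direction to the velocity direction, CCW-positive viewed from
above, in $(-180°, 180°]$: $0°$ is straight up-gradient, $\pm 180°$
straight down. All angle outputs are wrapped into this interval, and
means of heading changes use circular statistics (so the mean of
$\{+179°, -179°\}$ is $\pm 180°$, not 0). With this convention a
weathervaning navigator has mean run curvature $\approx -g\,\sin\theta$
(CCW-positive curvature): at $\theta = +90°$ the gradient lies clockwise
of the heading, so turning toward it is negative curvature. Where a
single "toward the gradient" axis is more informative — the
perpendicular bearing class of the curvature distributions — the
curvature sign is re-oriented so positive means toward the gradient.

**Pipeline.** Tracks are smoothed with a Savitzky–Golay filter (cubic,
0.5 s window — 7 samples at 14 Hz). This passes exactly 1/3 of
white-noise variance at its center, so the achievable RMS noise
reduction is 40–50%, while leaving straight and slowly curving paths
untouched. Tracks are kept only if observed for more than 60 s, with net
displacement above 3 mm, and starting below 70% of the field maximum
(strict inequalities); the last rule discards animals that had already
completed chemotaxis when tracking began.

**Turns.** A turn is an angle change larger than 60° between the
displacement vectors spanning consecutive 1 s windows. Candidate instants
are merged within a 1 s refractory window (keeping the largest angle) so
a slow continuous reorientation is counted once. This operator has a
small, known downward bias as a rate estimator — the refractory merge
absorbs true turns closer than 1 s apart and ~2% of the worm turn-magnitude
kernel falls below threshold — a few percent in the study conditions,
which the recovery tests bound at 10–15%. Turn-rate denominators include
all occupancy time, turn bouts included. Occupancy and events within
5 mm of the arena wall are excluded: a specular wall reflection flips the
heading and would otherwise masquerade as a bearing-correlated turn,
which is very visible at larval speeds.

**Statistics.** Turn rate is binned on $|\theta|$ (30° bins by default)
with counting errors $\sqrt{N}/T$. Curvature is sampled at 1 mm
arc-length steps (deg/mm, resampled along the path so pauses contribute
nothing) and summarized three ways: distributions per bearing quadrant
($|\theta| < 45°$, perpendicular, $|\theta| \ge 135°$) with pairwise
Kolmogorov–Smirnov tests (Bonferroni-flagged at $\alpha = 0.001$), the
mean-curvature-vs-bearing curve, and — for fitting the weathervane gain —
a run-curvature regression that excludes samples beyond 45 deg/mm, since
pirouette jumps (~120° at a vertex) would otherwise dominate the
variance. Drift velocity $V\cos\theta$ is binned by gradient magnitude
with quartiles, a t-test against zero, and two-sample tests against the
shallowest bin; because consecutive video-rate samples of one animal are
strongly autocorrelated (bearings decorrelate on the ~$1/\lambda_0$ turn
timescale), drift samples enter at a 30 s stride so the tests are
approximately independent. Larva statistics reuse the same 60°/1 s turn
operator on centroid heading — posture-based head-cast detection is out
of scope — and report the turn rate per quadrant plus the mean signed
bearing change across turns per pre-turn quadrant.

# The synthetic generator

The generator exists so every analysis can be validated by parameter
recovery; it is a model of the *statistics the analyses measure*, not of
worm or larva biomechanics. Agents run at constant speed (worm 0.1 mm/s,
larva 3 mm/s), fire turns as a Poisson process with hazard
$\lambda(\theta) = \lambda_0(1 - b\cos\theta)$, drift their heading at
$-g\sin\theta$ deg/mm plus Gaussian rotational noise (2 deg/√s), and draw
turn magnitudes from a wrapped-normal kernel (120° ± 30° for worms,
60° ± 20° for larvae), with the turn direction biased toward the gradient
with probability $(1 + \text{dir bias})/2$. Baseline rates
($\lambda_0 = 0.03$ /s worm, 0.05 /s larva) give turn counts of the same
order as real assays (hundreds of turns per ~60 larvae × 10 min). Starts
are sampled uniformly below 70% of the field maximum, mirroring the track
filter; walls reflect specularly. Integration is Euler at the 14 Hz
output rate, with a guard on $\lambda\,dt$.

What the generator does *not* emulate — body posture, reversals vs. omega
turns, sensory adaptation, odor-history dependence, anemotaxis — bounds
what passing tests show: they demonstrate that the estimators recover the
biases that generate the statistics, under realistic sampling noise and
geometry, not that real animals obey this parameterization.

Synthetic recordings pass the true ppm at each sensor position through
the inverse exponential response with multiplicative noise and a
transport delay, at the instrument's rates (sensors 1 Hz, PID up to
13 Hz); the reference series is the outlet mean concentration. A
calibration-style recording modulates a spatially uniform field with a
500 s triangle wave — as on the bench, where calibration always uses
uniform flow so every sensor sees the full dynamic range.

# Study sizes and determinism

Recovery tests use 200 agents × 20 min for worms (the scale at which the
binned estimators resolve 20% parameter changes) and 60 larvae × 10 min,
matching the corresponding assay scales; PDE comparisons run on 2 mm
grids in chambers up to 15 × 17 cm. Every stochastic step takes an
explicit seed and identical seeds give bit-identical outputs; the
pipeline writes provenance (package version, seed, config) next to its
outputs.

# Known limitations

* The plume model is depth-averaged; vertical structure and the
  developing velocity profile near the inlet are not modeled.
* The agar is a depth-integrated reservoir co-located with its mask; no
  lateral transport within the gel, no humidity or thermal coupling.
* The agar kinetic constants are effective parameters; only regime-level
  behavior should be read off simulations that use the defaults.
* The turn operator on centroid heading undercounts tightly spaced
  reorientations (refractory merging) and is blind to posture-defined
  events such as larval head casts.
* Thin-plate reconstruction degrades outside the sensor hull; the
  extrapolation flags should be honored when conditioning behavior on
  the field.
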