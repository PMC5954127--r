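---
title: "Collective gradient sensing: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective gradient sensing: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolsense)
```

## The scientific problem

Schooling fish confronted with a patchy, changing environment have two
sources of directional information: what their neighbours do (social
information) and what they can sense themselves (environmental
information).  A classic experimental paradigm projects a dynamic light
field onto a shallow tank — a dark spot that wanders at constant speed over
a noisy greyscale background — and asks how well a school tracks the dark
region.  Species that cannot sense the light gradient individually can
still track the spot collectively through a simple kinetic rule (swim
faster in bright water, slower in dark water), while species with genuine
individual gradient sensing track it more directly.  `schoolsense`
implements the full loop of that research programme in silico: the stimulus
generator, an agent-based school model in which the two information sources
are combined with a tunable weight, and the statistics used to compare
regimes.

## The dynamic light field

A frame of the stimulus is

$$L(\mathbf{x}) = \mathrm{clip}_{[0,1]}\!\big(L_{\rm spot}(\mathbf{x}) +
\eta\, n(\mathbf{x}, t)\big),$$

with the border band then forced to exactly white.  The components:

* **Dark spot.** $L_{\rm spot}(\mathbf{x}) = 1 - \exp(-|\mathbf{x} -
  \mathbf{c}|^2 / 2\ell^2)$ with length scale $\ell = 38.1$ cm, fully dark
  at the centre and white far away.  We read the quoted length scale as the
  Gaussian standard deviation; the form and scale are configuration fields,
  so an e-folding-radius reading is a one-line change.  The centre moves at
  a constant 5.7 cm/s; its heading receives a Gaussian turn each frame
  (sd 0.2 rad per frame at 30 Hz) and reflects off the arena walls.
  Re-entry from a random wall would be an alternative boundary rule; we
  chose reflection because it keeps the spot-centre track continuous, which
  the performance ceiling (`max_performance`) relies on.
* **Background noise.** Spatially smoothed white noise (Gaussian kernel,
  default scale 1.95 cm — 10 px at the native 940 x 540 resolution) evolved
  in time as a first-order autoregressive process with correlation time
  0.317 s (persistence 0.9 per frame at 30 Hz), standardised to zero mean
  and unit sd, scaled by 0.25 and clipped to $[-0.5, 0.5]$ so that the
  noise level $\eta$ multiplies a field of roughly unit peak-to-peak range.
  The published recipe for the experimental noise background is not
  reproduced here (it lives in unpublished supplementary material); these
  correlation scales are explicit, documented stand-ins and both are
  configuration fields.  This matters quantitatively — see *Limitations*.
* **Frame-rate invariance.** The spot turn sd scales as
  $\sqrt{30/\mathrm{frame\ rate}}$ and the noise persistence is
  parameterised by its correlation time, so a field generated at 8 Hz (one
  frame per model step) has the same physical statistics as one generated
  at 30 Hz.  This is what makes reduced-rate sweep stimuli legitimate.

Pixel centres sit at $((i-0.5)\Delta x, (j-0.5)\Delta y)$ with the origin
at the lower-left corner and x along the 183 cm axis.  `sample_light` is
bilinear in the grid; `field_gradient` applies central differences
(one-sided on the outermost ring) and interpolates them bilinearly, which
on a noise-free spot field matches the analytic gradient to well under 1%
at practical resolutions (this is tested).

## The school model

Each of $N$ agents carries a position (cm), a unit heading and a speed.
One synchronous time step of `dt = 0.125` s:

1. **Social direction** from the canonical zonal rules with the
   golden-shiner parameter set: repulsion within 0.5 BL (overrides
   everything, pointing away from the offenders), orientation over
   [0.5, 3) BL (mean neighbour heading), attraction over [3, 5.5) BL
   (mean direction toward neighbours), the orientation and attraction
   contributions normalised and summed with equal weight.  Neighbours in
   the rear $90^\circ$ blind wedge are invisible to all three zones, since
   the field of perception ($270^\circ$) is a single parameter of the
   canonical model.
2. **Environmental direction**: the unit vector along $-\nabla L$ at the
   agent's position, rotated by a Gaussian sensing error of sd
   $\sigma_w$.  Where $|\nabla L|$ falls below `gradient_zero_tol`
   ($10^{-6}$ /cm — deep inside the clipped dark core) the term is the zero
   vector and no error is drawn, so dark-region behaviour is purely social.
3. **Combination**: $\mathbf{d} = \hat{\mathbf{d}}_{\rm social} +
   w\,\hat{\mathbf{d}}_{\rm env}$; if both are zero the agent keeps its
   heading.  At $w = 0$ the model reduces bit-for-bit to the purely social
   (emergent-sensing) model — this equivalence is a test, enforced by
   drawing the sensing error only when the gradient term is actually used.
4. **Turn limit**: the heading rotates toward $\hat{\mathbf{d}}$ by at most
   $100^\circ/\mathrm{s} \times 0.125\,\mathrm{s} = 12.5^\circ$.  We read
   the quoted turning rate as per second (the canonical convention), and
   apply the limit to the combined direction rather than the social part
   alone, since the combined direction is what the agent wants to do.  An
   exactly antiparallel target breaks the tie counter-clockwise, a
   convention chosen so replays are deterministic.
5. **Social error**: a Gaussian heading rotation (sd 0.01 rad), applied
   after the turn limit so the realised heading always carries fresh noise
   (applying it before would let the limiter clip the noise).
6. **Speed and move**: $s = s_{\min} + L(s_{\max} - s_{\min})$ from the
   local light level, then $\mathbf{x} \leftarrow \mathbf{x} + s\,
   \hat{\mathbf{h}}\,dt$ with mirror reflection (position and heading) at
   the arena walls.

Zone radii, speeds and body length: radii are in body lengths, converted
through `body_length_cm` (default 3.4 cm, the rummy-nose tetra value).  The
speed range is not part of the published parameter set; the defaults
$s_{\min} = 0.5$ BL/s and $s_{\max} = 3.0$ BL/s are plausible cruising
speeds for small schooling fish and are flagged as model choices.  Shape
and ratio statements (sigmoidal performance curves, U-shaped cohesion) are
robust to them; absolute cohesion values are not (see *Limitations*).

Initial conditions (unstated in the source protocol): positions uniform in
the central quarter-area box, headings uniform on the circle, all drawn
from the run's seed.  The field advances at its own frame rate and each
model step uses the frame nearest in time (held, not interpolated).

## Metrics

* **Tracking performance.** $\psi = \langle\langle 1 - L
  \rangle_{\rm fish}\rangle_t$ averages darkness over fish within a frame,
  then over frames; $\psi_{\rm null}$ repeats this with $L$ sampled from
  the temporal average of the field; $\Psi = \psi/\psi_{\rm null}$.  On a
  static field $\Psi \equiv 1$ for any trajectory (exact, tested), so
  $\Psi > 1$ certifies genuine tracking of the *moving* dark region.
* **Performance ceiling.** `max_performance` evaluates the single point
  that sits at the spot centre in every frame.  Since the spot centre is
  where darkness is deepest and the temporal average along its own track is
  what the null sees, this maximises $\Psi$ and gives the ceiling
  $\Psi_{\max}$ for a body-less tracker.
* **Cohesion.** `nearest_neighbour_distance` averages each agent's distance
  to its closest neighbour, per recorded frame, then over frames.  All
  recorded frames enter the trial mean (no post-transient window): the
  time-resolved diagnostic in our development runs showed the statistic is
  stationary after the first ~quarter of a run, and a windowing rule would
  add a free parameter.
* **Group geometry.** `group_area_density` uses the convex hull for
  $A_{\rm group}$ and $\rho = A_{\rm group}/(N\,BL^2)$.  The hull is a
  definition choice (the source never defines the group area), so density
  comparisons against published values are qualitative only.
* **Sweep derivatives.** $\Delta\Psi = \max_w \bar\Psi(w) - \bar\Psi(w_{\rm
  min\ grid})$, with the smallest grid weight standing in for $w = 0$
  because the log grid excludes zero; $w_0$ is the first upward crossing of
  $\bar\Psi(w_{\rm min\ grid}) + \Delta\Psi/2$, interpolated log-linearly
  in $w$ (the interpolation rule is unstated in the source; log-linear
  matches the grid's geometry).  `select_w_min` returns the grid weight
  minimising $\sum_N \big(\bar d_{nn}(w, N) - \min_{w'} \bar d_{nn}(w',
  N)\big)^2$ — the squared *excess* above each size's own minimum, our
  reading of "sum of squared differences"; the objective sits behind a
  single function so alternative readings can be swapped in, and it is
  invariant to adding a constant to any one size's curve (tested).
* **Cue correlations.** `cue_vectors` pairs the Gaussian-kernel
  acceleration with the social vector $\mathbf{S}_i = \sum_{j \in r_s}
  (\mathbf{x}_j - \mathbf{x}_i)/|\mathbf{x}_j - \mathbf{x}_i|$ (range 7 BL)
  and the environmental vector $\mathbf{G}_i = -\nabla L|_{\mathbf{x}_i}$;
  `binned_correlation` bins $\hat{\mathbf S}\cdot\hat{\mathbf a}$ or
  $\hat{\mathbf G}\cdot\hat{\mathbf a}$ by cue magnitude (default 12
  equal-width bins over the central 98% of magnitudes — the bin layout is a
  package choice).  Magnitude thresholds such as $|\mathbf{S}| > 3$ are on
  the raw sum of unit vectors, as the definition is written.  Records are
  pooled across group sizes by default.

### Differentiation kernels

Velocity and acceleration come from convolving position series with first
and second derivatives of a Gaussian (sd 1.5 frames, 11-frame support).
The kernels are moment-normalised: the derivative kernel has zero sum (DC
rejection) and unit first moment, the curvature kernel zero 0th and 1st
moments and unit second moment, so linear motion differentiates to its
exact slope and quadratic motion to its exact curvature — this pins the
normalisation that a citation-only method description leaves open.  Edge
frames without full support are dropped rather than padded.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates two quantities from scratch:

* the spot-tracker ceiling $\Psi_{\max}$, averaged over five 300 s fields
  at $\eta = 0.25$ with distinct seeds;
* the cohesion-optimal weight from a sweep at $\eta = 0.25$ over a
  16-point log-spaced grid $w \in [10^{-2}, 10^3]$ for $N = 16, 32, 64,
  128$, 5 replicates, 2000 steps.

Problem sizes were fixed once for a single-CPU workflow: fields are
generated on a 5x reduced grid (188 x 108 px; the spot spans ~20 px and the
noise kernel ~1 px there, and halving the reduction changes the one-seed
$\Psi_{\max}$ by well under the between-seed spread — the chunk below
performs that check), sweeps use one field per replicate shared across all
$(w, N)$ cells so conditions are compared on identical stimuli, and the
16-point grid has spacing $10^{1/3}$ in $w$.

```{r convergence, eval = FALSE}
# grid-resolution check for the performance ceiling (a few minutes)
psi_at <- function(factor) {
  fs <- field_sequence(reduce_field_config(field_config(seed = 1), factor),
                       keep_frames = FALSE)
  max_performance(fs)$Psi
}
c(coarse = psi_at(5), finer = psi_at(2.5))
```

## What the generator does and does not emulate

The synthetic stimulus reproduces the documented geometry exactly (arena,
resolution, border, spot shape, spot speed, noise level) and gives the
noise the qualitative structure the paradigm needs: spatial smoothness,
temporal persistence, zero mean, amplitude controlled by $\eta$.  It does
**not** reproduce the exact experimental noise recipe, whose correlation
scales were never published.  Consequently:

* Quantities dominated by the spot and its motion — the tracking
  performance $\Psi$, its ceiling $\Psi_{\max}$, the sigmoidal rise of
  $\Psi(w)$, the degradation with $\sigma_w$, the qualitative U-shape of
  $d_{nn}(w)$ — are robust to the noise dialect and are covered by tests.
* The *location* of the cohesion-optimal weight is **not** robust: it is
  set by the competition between social attraction and noise-gradient
  chasing, i.e. precisely by the noise correlation scales and the swim
  speeds.  Under this package's default dialect the selected weight is of
  order 1, and our diagnostics show it moves with the noise scales and
  speed range.  Passing shape tests therefore do not certify that the
  default stimulus matches any particular experimental stimulus at the
  level of optimal-weight selection.

## Numerical choices and degenerate inputs

* Clipping happens after the $\eta$-weighted sum and before the border is
  imposed, so the border is exactly white.
* `gradient_zero_tol` ($10^{-6}$/cm) realises "the gradient is zero inside
  the dark region" robustly in floating point.
* Coincident agents are skipped (with a warning in the user-facing
  functions) wherever a unit separation vector is undefined.
* Collinear groups get zero hull area with a warning, not an error.
* All randomness — field synthesis, initial conditions, sensing and social
  errors — flows through R's global RNG, so a seed plus a configuration
  determines every output bit-for-bit; per-cell sweep seeds derive
  deterministically from the master seed.
* The all-pairs neighbour search is exact; at the sweep sizes used here
  ($N \le 256$) it outperforms grid acceleration in practice and leaves no
  room for binning artefacts.

## Known limitations

* The noise-field recipe is a stand-in (above); optimal-weight selection is
  dialect-sensitive.
* Swim speeds are model choices, not measured values; absolute $d_{nn}$
  levels shift with them.
* At the default `dt`, very dense schools ($N \ge 128$ crowded into the
  dark core) can compress below 0.5 BL spacing because repulsion acts once
  per 0.125 s; a shorter step would enforce a harder floor.
* The model is two-dimensional and ignores body shape, occlusion and
  hydrodynamics; experimental trajectory tables can be ingested, but
  detection and tracking from video are out of scope.
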