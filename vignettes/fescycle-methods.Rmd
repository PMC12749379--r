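---
title: "Kinematic modelling and FES pattern design for rat cycling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic modelling and FES pattern design for rat cycling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fescycle)
```

## The model

A rat pedaling a stationary bicycle with a fixed hip and its paw fixed to
the pedal forms a closed planar kinematic chain with a single degree of
freedom: the crank angle $q$ measured by an encoder.  The chain runs hip →
knee → ankle → pedal → crank axle → hip, with eight fixed lengths: thigh
$l_t$, shank $l_l$, crank $l_c$, the ankle-to-pedal offsets $l_h, l_v$ in
the foot frame, the hip position $(l_x, l_y)$ relative to the crank axle
($l_x$ signed; the body-position scenarios use $l_x = \pm 10$ mm), and the
horizontal distance $d$ from the axle to the mounting point of the rod that
keeps the pedal oriented.

Because the pedal rod constrains the pedal's orientation, the ankle angle
has a closed form,
$$q_a(q) = -\arctan\!\frac{l_c \cos u}{l_c \sin u + d},$$
defined for every crank angle because $d > l_c$ (the constructor rejects
geometries violating this), where $u$ is the internal chain parameter
described under *Conventions*.  Substituting $q_a$ into the loop-closure
equations leaves two unknowns.  Writing the point the thigh–shank pair must
reach as $(A_x, A_y)$,
$$l_t \sin q_h + l_l \sin q_k = A_x, \qquad
  l_t \cos q_h + l_l \cos q_k = A_y,$$
the hip angle follows from the standard two-link elimination
($\cos(q_h - \alpha) = c/r$ with $\alpha = \operatorname{atan2}(A_x, A_y)$,
$r^2 = A_x^2 + A_y^2$, $c = (r^2 + l_t^2 - l_l^2)/(2 l_t)$).  The two
arccosine branches correspond to the two mirror configurations of the knee;
the branch corresponding to hip hyperextension is physically impossible on
the bicycle and is discarded.  The knee angle then comes from the remaining
closure components through a two-argument arctangent, so quadrants are
resolved correctly everywhere.  Every solution is verifiable by
substitution: `chain_residual()` evaluates the loop and the suite requires
the residual norm to stay below $10^{-6} \, l_c$ over a 1° grid.

Differentiating the closure with respect to $q$ gives the dimensionless
joint-velocity transforms $S_a, S_h, S_k$ (each equal to
$\mathrm{d}q_j/\mathrm{d}q$), whose $2\times2$ linear system has
determinant proportional to $\sin(q_k - q_h)$: it vanishes exactly at full
limb extension, which the bicycle must be adjusted to avoid.  By the
principle of virtual work, the torque-transfer ratios mapping active joint
torque to crank torque are
$$T_\mathrm{hip} = S_h, \qquad T_\mathrm{knee} = -S_h + S_k, \qquad
  T_\mathrm{ankle} = S_h - S_k + S_a,$$
which imply the identity
$T_\mathrm{hip} + T_\mathrm{knee} + T_\mathrm{ankle} = S_h + S_a$, tested
to $10^{-12}$.  The transforms themselves are tested against central finite
differences of the angle solutions — an oracle independent of the printed
formulas.

## Conventions

* **Units.** Degrees at every public interface, radians internally; all
  arcs and crank angles normalised to $[0, 360)$.
* **Encoder convention.** Increasing $q$ is clockwise-forward pedaling as
  viewed from the animal's right, and `q = crank_zero_offset_deg` (default
  0) puts the pedal at bottom dead centre.  Internally the chain is
  evaluated at $u = (180° - (q - \text{offset})) \bmod 360°$, and the
  public velocity transforms are $-\mathrm{d}q_j/\mathrm{d}u$.  This
  orientation was fixed once, at design time, as the one under which the
  derived two-nerve pattern has the femoral arc followed by the sciatic
  arc around the forward direction — the qualitative layout of the
  reference pattern figures; the mirrored reading of the same equations
  reverses that order.  Users whose encoder zero differs only need the
  offset; users whose encoder counts the other way can negate their angle
  stream.
* **Arcs.** Regions on the crank circle are unions of half-open arcs
  $[\text{start}, \text{end})$, stored split at the $0/360$ seam.
  Half-openness makes adjacent regions tile the circle without double
  counting, so the four confusion measures always sum to exactly 360°.

## Default geometry

The reference analysis used average limb lengths of 4-month-old male rats
without stating them, so the package ships a clearly labelled
representative default and parameterises everything by a geometry file:

```{r}
default_geometry()
```

Thigh and shank of 40 mm are plausible adult Sprague-Dawley segment
lengths; the 25 mm crank and 60 mm pedal-rod distance are scaled to the
rodent bicycle; the hip sits centred 50 mm above the axle.  The hip height
was chosen (together with $d$) so that the configuration is reachable over
the whole cycle for hip shifts up to $\pm 10$ mm *and* stays clear of full
extension (minimum $|\sin(q_k - q_h)| \approx 0.4$): a taller hip position
of 60 mm, for example, would put the bottom of the pedal circle outside
the 80 mm reach of the thigh–shank pair.  Reachability is checked at
construction over a 1° grid so impossible geometries fail fast rather than
mid-computation.

## From torque transfer to stimulation regions

Stimulation of a target is useful only where its evoked torque drives the
crank in the commanded direction with sufficient leverage.  With a
user-selected threshold $\epsilon > 0$ per target, the clockwise regions
are
$$\mathcal{Q}_\mathrm{GM} = \{q : T_\mathrm{hip} > \epsilon\},\quad
  \mathcal{Q}_\mathrm{QM} = \{q : -T_\mathrm{knee} > \epsilon\},\quad
  \mathcal{Q}_\mathrm{HM} = \{q : T_\mathrm{knee} > \epsilon\},\quad
  \mathcal{Q}_\mathrm{PFM} = \{q : T_\mathrm{ankle} > \epsilon\}$$
(version A, four muscle groups), and for the two-nerve model (version B)
$$\mathcal{Q}_\mathrm{fn} = \{q : -T_\mathrm{knee} > \epsilon_\mathrm{fn}\},
  \qquad
  \mathcal{Q}_\mathrm{sn} = \{q : a_1 T_\mathrm{hip} + a_2 T_\mathrm{knee}
  + a_3 T_\mathrm{ankle} > \epsilon_\mathrm{sn}\}.$$
Counterclockwise patterns apply the same inequalities to the negated
ratios: that is the only sign-consistent reading of the virtual-work
derivation (a target useful clockwise at $q$ is exactly as counterproductive
counterclockwise there).

Design choices at points the source analysis left open:

* **Thresholds.**  Only the feasibility bound
  $\epsilon < \max_q |T|$ is stated; numeric values are not.  The default
  is 10 % of the cycle maximum of each target's signal, configurable
  per target; an infeasible threshold raises a classed error at build
  time rather than returning an empty region.
* **Crank weights.**  $a_1, a_2, a_3$ are "known constants" without
  printed values; the default is $a_1 = a_2 = a_3 = 1$.
* **Overlap removal.**  The two-nerve model forbids simultaneous femoral
  and sciatic stimulation (antagonist co-contraction) but does not say how
  the overlap is resolved.  The default `femoral_priority` subtracts the
  overlap from the sciatic region (the femoral region is the sharper,
  single-muscle-group prediction); `sciatic_priority` and `split_midpoint`
  are provided as alternatives, and all three leave the union of
  stimulated angles unchanged.
* **Boundary refinement.**  Regions are thresholded on a 0.1° grid and
  every boundary is refined by bisection on the sign of
  $T - \epsilon$ to $10^{-4}$°, so the exported arcs are grid-independent
  and reproducible.
* **Left leg.**  The left crank arm is mounted 180° out of phase, so the
  left pattern is the right pattern rotated by 180°.

With the default geometry the gluteal and quadriceps clockwise regions
overlap substantially but not almost-completely
(`pattern_overlap_diagnostic()` reports the relative symmetric difference,
about 0.77 here); the strength of that overlap depends on the unreleased
geometry and thresholds, which is why it is a reported diagnostic rather
than an asserted invariant.

## RoA estimation and agreement scoring

Experimentally, a region of activity is "the region capturing 95 % of
observations in which stimulation produced motion (≥ 10° crank deviation in
the commanded direction, at the 100 Hz operating point)".  For discrete
grid data that phrase is ill-posed, so the estimator is made explicit:
the **shortest contiguous circular arc** containing at least
$\lceil 0.95\, n \rceil$ of the motion-positive start angles, anchored on
observed angles (every optimal arc can be shrunk until both ends touch
observations), with ties broken by larger contained count, then by
smallest start angle.  The arc is expanded by 7.5° — half the 15°
acquisition grid — on each end, so a single observed grid angle
contributes one full grid cell; the padding is configurable and 0 is
allowed.  The implementation scans the $n$ consecutive-observation
windows; the test suite compares it against exhaustive search over all
$n^2$ observation-anchored arcs.

Agreement between a model region and an experimental RoA is scored on
angular measure, not trial counts: TP is the measure of their
intersection, TN of the complement of their union, FP model-only, FN
experiment-only; TP + TN + FP + FN = 360° exactly.  Sensitivity,
specificity, PPV and NPV are the usual ratios.  A ratio with a zero
denominator (an empty region is legitimate under an extreme threshold) is
undefined and propagates as `NA`, never silently as 0; aggregation
excludes such entries pairwise and reports how many were dropped.
Aggregation uses the sample ($n-1$) standard deviation, which is the
convention that reproduces the reported summary values from the reported
per-condition cells.  Whether coverage is computed per condition or pooled
per nerve is not stated in the source; the package computes one RoA per
(nerve × shift × direction) condition, matching the layout of the reported
table.

## The synthetic-trial generator

No animal data are distributed, so the generator emulates the mapping
protocol's statistical structure to make the whole pipeline testable:
start angles on a 15° grid in seeded random order, repeated stimulations,
a primary 100 Hz frequency plus an attenuated secondary one (the actual
non-primary frequencies are not stated; 40 Hz is a labelled stand-in),
hip shifts of ±1 cm, the stimulus operating point fixed at 125 µs and
4 mA, and 60 s rests carried as inert metadata.  Inside a ground-truth
region a trial produces motion with probability 0.95 at 100 Hz; outside,
with probability 0.02; motion deviations are proportional to the relevant
normalised torque-transfer ratio at the start angle
(scale 120°, Gaussian noise SD 8°, floored at the 10° motion threshold and
signed by direction), giving the generator mechanistic structure that
exercises the kinematics–validation interface.  These defaults are the
study conditions, chosen once as a realistic emulation of robust
anesthetized-preparation responses.

`default_study_design()` sizes the campaign like the real one: the centred
hip position carries both directions at 3 repetitions per angle and both
frequencies (576 rows), the backward and forward shifts are smaller
clockwise-only blocks (96 and 48 rows), for 720 expected trials — within
ten percent of the 743-trial campaign, centred-heavy like it, with the
truth regions taken from the two-nerve model itself.

What the generator does **not** model: electrode placement variability
across sessions, recruitment curves, fatigue dynamics, anesthesia depth,
or any true biomechanics of the deviation magnitude.  Passing the
parameter-recovery tests therefore demonstrates that the estimation and
scoring chain is correct and well-calibrated for data with this structure;
it does not validate the kinematic model against animals.

## Numerical choices and degenerate inputs

* Chain closure residual tolerance $10^{-6} l_c$; achieved residuals are
  near machine precision ($\sim 10^{-14}$ mm).
* The hip-branch arccosine argument is clipped to $[-1, 1]$ within a
  $10^{-9}$ tolerance; beyond that the pose is genuinely unreachable and a
  classed error (`fescycle_unreachable_pose`) names the crank angle —
  a configuration problem, not a numerical one.
* The velocity transforms refuse to evaluate within $10^{-8}$ of
  $\sin(q_k - q_h) = 0$ (`fescycle_singular_pose`).  The denominators of
  the printed hip/knee transforms involve $\sin(q_k - q_h)$, so the guard
  is implemented on that quantity.
* Arc endpoints merge within $10^{-9}$°; measures and complements are
  exact to that tolerance.
* Equal-length shortest-arc candidates are resolved deterministically
  (count, then start angle), so RoA estimates are reproducible across
  platforms.
* `estimate_roa()` with all observations identical and zero padding
  returns a zero-measure region; with the default padding it returns the
  point's 15° grid cell.

## Problem sizes

The test suite and the acceptance script run at deliberately modest,
fixed sizes chosen to exercise every code path with dense oracles: 1°
grids for closure and derivative checks, 0.01° membership grids for the
region-algebra oracle (200 random arc-set pairs), 100 random instances of
up to 50 observations for the estimator-equivalence check, and synthetic
campaigns of roughly 700–1000 trials.  All randomness is seeded
explicitly; the same seed reproduces every table byte for byte.

## Known limitations

* The model is kinematic only: no muscle forces, activation dynamics, or
  fatigue — the ratios say where torque helps, not how much torque is
  available.
* The reported wedge boundaries (femoral ≈ 30°–140°, sciatic ≈
  160°–280°) depend on the unreleased limb lengths, thresholds and crank
  weights and therefore cannot be reproduced bit-exactly; the package
  treats them as qualitative shape expectations, which the default
  geometry satisfies.
* Left/right asymmetric geometries are out of scope (the left side is the
  right side offset by 180°).
* The generator's dead zones and spurious-motion model are Bernoulli
  per-trial; real spurious motion is likely correlated within sessions.
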