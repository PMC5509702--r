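---
title: "Shock-induced cavitation collapse and polymer damage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shock-induced cavitation collapse and polymer damage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavijet)
```

## The scientific question

When a shock wave passes through a fluid containing a cavitation bubble, the
post-shock pressure collapses the bubble asymmetrically: the upstream wall
accelerates into the void, overshoots, and emerges as a narrow,
high-velocity, one-directional jet — the *water hammer*. In the brain's
extracellular matrix, the perineuronal net (PNN) that wraps neurons is built
on long hyaluronan (HA) filaments, and there is reason to suspect that
blast-induced cavitation jets can tear them. `cavijet` provides two
complementary tools for studying this mechanism:

1. an exact analytic scaling law for the jet's kinetic energy per frontal
   area, with the associated nine-case reference grid and the ~40 N/m
   rupture threshold, and
2. a desk-scale particle simulator (2D by default, 3D capable) that
   reproduces the mechanism end to end — shock generation by momentum
   mirror, bubble collapse, jet formation, and rupture of a breakable
   bead-spring polymer — together with the binned continuum-field analysis
   used to characterise it.

The simulator is deliberately *not* an atomistic reproduction: reactive
force fields, hydrogen bonding, counter-ions and absolute km/s scales are
out of its scope. It reproduces the phenomenology (front, collapse, jet,
rupture ordering) in reduced Lennard-Jones units, where properties can be
asserted and tested quickly and deterministically.

## The analytic scaling law

The collapse converts the work done by the post-shock pressure $p_p$ over
the bubble volume into jet kinetic energy, so for a bubble of diameter $D$:

$$E_k \propto D^3\,p_p.$$

The proportionality constant is fixed at 1 in this package and the result
is documented as an energy *scale*, not an absolute energy, because no
constant is available for it. After impact the jet disperses radially from
a frontal patch of side $D + 2d$, where $d$ is the gap between the bubble
surface and the filament, giving an energy per frontal area

$$\frac{E_k}{(D+2d)^2} = \frac{D^3}{(D+2d)^2}\,p_p
\quad\text{[N/m]},$$

which is the package's first-order damage metric. With $d = 1$ nm and the
three post-shock pressures 2.65, 7.97 and 16.2 GPa (carried as reference
constants; they correspond to shock speeds of 3.60, 5.35 and 7.20 km/s in
water) the nine cases evaluate to:

```{r}
classify_damage(generate_table1(d_nm = 1), threshold = 40)
```

Rupture is predicted above 40 N/m; the comparison is strict (`>`) because
the threshold is stated as an energy the damage must *exceed*. Exactly five
of the nine cases exceed it. All computation is internal in SI units; the
nm/GPa interface converts on entry, which keeps the N/m output honest.

The Young–Laplace pressure $2\gamma/r$ (`laplace_pressure()`) quantifies
why nanometre bubbles are intrinsically unstable: at $r = 2.5$ nm in water
($\gamma = 0.072$ N/m) the surface-tension pressure is already ~58 MPa.

## The desk-scale simulator

### Model

* **Fluid** — a dense 2D Lennard-Jones liquid (number density 0.8,
  temperature 1.0 reduced). The pair potential is the 12-6 form truncated
  at $2.5\sigma$ with *both* energy and force shifted to zero at the
  cutoff. The force shift matters: the plain truncated-shifted form has a
  force discontinuity at the cutoff that dominates NVE energy drift and
  would mask integration errors.
* **Boundaries** — periodic laterally, elastic reflective walls on the
  shock axis (the last coordinate, "z").
* **Shock** — the reflective-boundary (momentum-mirror) method: every
  particle receives a piston velocity $v_p$ toward the +z wall; the
  reflected layer piles up into a compression front that travels in $-z$,
  i.e. the shock runs from +z toward $-z$, encountering first the bubble
  and then the filament. Propagation is strictly NVE.
* **Bubble** — a void carved from the equilibrated fluid (particles within
  $D/2$ of the centre removed). The void holds no gas: at this scale a
  real cavity contains too few molecules to affect the collapse.
* **Polymer** — a 12-bead bead-spring chain with harmonic bonds that break
  irreversibly beyond a critical extension, inserted with its axis
  perpendicular to the shock axis a gap $d$ below the bubble surface, so
  the jet lands on it. A perfectly straight chain is invariant under
  rotation about its own axis, so the beads carry a shallow helical
  transverse offset whose *phase* is the rotation angle; replicate builds
  rotate by 90° each, which changes the local geometry (as rotating a real
  helical filament does) while a 360° rotation reproduces the 0° build
  exactly.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| box | 30 × 60 | $\sigma$ | aspect 2 along the shock axis; ~1400 particles/run |
| density | 0.8 | $\sigma^{-2}$ | dense liquid, supports sharp fronts |
| $v_p$ grid | 1.5, 2.25, 3.0 | reduced velocity | see calibration below |
| $D$ grid | 0, 8, 11, 14 | $\sigma$ | no-bubble control + three sizes |
| bond stiffness $k$ | 80 | $\varepsilon/\sigma^2$ | with break extension sets the rupture threshold |
| break extension | 1.7 × rest length | — | calibrated once, see below |
| bead mass | 3 | fluid mass | damps brief impulse noise relative to the sustained jet |
| timestep | 0.001 (grid runs), 0.00025 (conservation benchmark) | reduced time | validated by the NVE drift property |
| bin side $h$ | 2 | $\sigma$ | a 1-$\sigma$ bin holds < 1 particle at density 0.8; 2-$\sigma$ bins hold ~3, matching the minimum-occupancy rule |

### Calibration of the study grid

The desk grid was calibrated once so that the qualitative contrast of the
reference experiment appears, and then frozen:

* **Piston velocities.** The 2D liquid's sound speed is ≈ 8 reduced units,
  so pistons below $v_p \approx 1.5$ produce compression jumps of only a
  few percent of the ambient density — undetectable against counting noise
  in desk-scale slabs. The grid {1.5, 2.25, 3.0} spans weak-but-trackable
  to strongly driven fronts (measured $v_s \approx$ 11–16, always
  supersonic relative to the piston and increasing with it).
* **Run length.** Runs last 5.5 reduced time units: long enough for the
  front (lab speed ≈ 9–13) to traverse the bubble, collapse it, and land
  the jet on the chain, but short enough that the front has not yet
  reflected from the far wall. Longer runs let the reflected shock and the
  mirror-wall stagnation layer re-hit the chain — a finite-tube artifact
  with no analogue in the half-space geometry the model emulates.
* **Chain strength.** The break extension (1.7 × rest length at $k = 80$,
  bead mass 3) was set so that the planar shock alone — including the
  strongest piston — never ruptures the chain in any replicate, while the
  collapse jets of the larger bubbles do. With weaker bonds the no-bubble
  control ruptures sporadically; with stronger ones even the largest
  bubble's jet cannot break the chain. The fluid-exclusion radius around
  the chain is 1.0 $\sigma$, the distance at which the fluid-bead pair
  energy is exactly zero: a smaller radius would insert boundary fluid on
  the steep repulsive wall and detonate an artificial hammer around the
  chain (an effect that dominated damage statistics until it was removed).

### Measurements

* **Continuum fields** (`bin_fields()`): half-open cubic bins, mass
  density and mass-weighted mean velocity per bin; empty bins are flagged
  `NA`, never zero-velocity. Binning conserves mass and momentum exactly
  and is tested against a per-particle oracle.
* **Jet report** (`max_local_velocity_series()`): per frame, the maximum
  over bins of the mean-velocity magnitude, ignoring bins under a minimum
  occupancy (3) that would otherwise contribute single-particle spikes.
  For scenario summaries the peak is additionally restricted to times
  after the front reaches the bubble: before that, the series only
  measures piston drift plus thermal extremes. The collapse-completion
  time reported per run is the first time the *smoothed* (five-frame
  running mean) series reaches 90% of its maximum — jet formation. The
  unsmoothed maximum can land on a late single-frame extreme of a sparse
  fast bin (measurement noise), and the post-impact plateau drags a raw
  argmax late.
* **Shock-front speed** (`measure_shock_speed()`): the front is tracked as
  the half-amplitude crossing of the *axial mean-velocity* step in the
  pre-bubble window (unshocked fluid drifts at $v_p$; shocked fluid is at
  rest in the mirror frame), sequentially (monotone advance, tracking
  stops when the front exits the window), and fitted by least squares.
  The velocity step has amplitude $v_p \gg$ slab noise, whereas the
  density jump of these moderately strong shocks is comparable to slab
  counting noise; a density-based half-max tracker was evaluated first
  and discarded for exactly that reason. Reported $v_s$ is the front
  speed relative to the unshocked fluid (lab speed + $v_p$), i.e. the
  Hugoniot shock speed.
* **Damage** (`damage_report()`, `classify_outcome()`): broken bonds with
  times, normalized break sites, fragments as connected components of the
  residual bond graph (breadth-first traversal, cross-checked against an
  independent graph library in the tests), and the ruptured vs
  deformed-intact outcome with the maximum transverse deflection.

### What the synthetic conditions do and do not show

The generator emulates: a thermalised dense fluid slab, a vacuum void, a
breakable filament at a controlled gap, replicate variation through chain
rotation and velocity seeds. It does not emulate: chemistry (glucoside
bonds vs ring opening), hydrogen-bond dynamics, ions, 3D helical HA
structure, or water's absolute Hugoniot. Consequently a passing test suite
shows that the *mechanism* — supersonic front, collapse faster than the
front, jet amplification growing with bubble size, rupture confined to an
upper-right region of the (D, v_p) grid — is reproduced and measured
correctly; it does not validate absolute damage thresholds for real
tissue, which come from the analytic module's N/m scale instead.

## Numerical choices

* Velocity-Verlet, with bond-break checks once per step after the move;
  all bonds past their break extension break in the same step
  (determinism under ties). The elastic energy a bond holds at the break
  instant moves to an explicit energy sink so that total-energy
  bookkeeping stays closed; NVE drift on a full ~20,000-particle shock
  run is below $10^{-4}$ relative (tested).
* Cell lists are rebuilt every step; periodic axes need at least three
  cells, otherwise the evaluation falls back to all-pairs (exact on tiny
  boxes). The cell path is continuously validated against the all-pairs
  oracle.
* Pair separations below 0.3σ raise an overlap error naming the pair;
  per-step displacements above half the cutoff raise an instability error
  advising a smaller timestep.
* Weak-coupling (Berendsen-style) velocity rescaling is used only for
  equilibration, never during shock propagation; the scale factor is
  clamped to [0.9, 1.1] per step.
* Equilibration declares success when the mean temperature over the last
  10% of steps is within 5% of target; small systems fluctuate by
  $\sigma_T/T \approx \sqrt{2/(N\,d)}$, which for a few hundred particles
  approaches that band — a miss is therefore a warning, not an error.
* Ties in binning: bins are half-open $[ih, (i+1)h)$; particles exactly on
  the upper box edge fold into the last bin, so the tiling is exact.
* The bubble–chain gap is enforced exactly at build time; replicate
  rotation never changes the particle count because fluid exclusion uses
  the rotation-independent capsule around the chain axis.

## Known limitations

* 2D collapse produces cylindrical (line-like) jets; amplification ratios
  are not transferable to 3D spherical collapse, only their ordering.
* The momentum-mirror tube is finite: after the front reflects from the
  far wall the state no longer models a travelling shock (runs end before
  that).
* The measured $v_s(v_p)$ mapping is specific to the reduced-unit liquid;
  only its qualitative shape (supersonic, monotone) mirrors water's.
* The no-target acceptance quantities written by `scripts/acceptance.R`
  use three replicates per scenario; rupture fractions at the boundary of
  the damage region are inherently stochastic at that sample size.

## Reproducing the grid

```{r, eval = FALSE}
cfg <- load_config(list(seed = 1))
summary <- run_grid(cfg, outdir = "runs")   # 36 runs, resumable
aggregate(cbind(peak_jet_speed, broken) ~ D + v_p, summary, mean)
```

Problem sizes used throughout the package's own validation: ~1,400
particles per grid run (36 runs), and a single ~20,000-particle run for
the energy-conservation check.
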