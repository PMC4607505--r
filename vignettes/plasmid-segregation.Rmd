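---
title: "Modelling asymmetric plasmid segregation in dividing yeast nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling asymmetric plasmid segregation in dividing yeast nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Autonomously replicating plasmids (ARS plasmids, ERCs) are inherited
asymmetrically in budding yeast: daughters receive far fewer copies than a
volume split would predict, and this asymmetry contributes to replicative
aging. One proposed explanation requires an active diffusion barrier at the
bud neck; the competing morpho-kinetic hypothesis holds that passive
diffusion inside the *changing* nuclear geometry, over the *finite* duration
of anaphase, is sufficient. `plasmidsim` implements the simulation machinery
needed to interrogate the second hypothesis quantitatively: a single plasmid
modelled as a Brownian particle — optionally with excluded volume — confined
to a moving nuclear envelope reconstructed from microscopy measurements, or
emulated by a synthetic generator.

## Geometry model

The dividing nucleus is idealised as **two prolate spheroids joined by a
cylindrical bridge**, all rotationally symmetric about the division axis
(the x axis):

* the mother lobe sits at negative x, the daughter at positive x;
* the bridge cylinder spans `[-h, h]` and its midpoint `x = 0` defines the
  mother/daughter boundary (a particle exactly at `x = 0` is counted as
  mother — a measure-zero tie that must be fixed for determinism);
* spheroid tips touch the cylinder ends (*tip contact*), so lobe centres are
  derived quantities, not inputs.

Measurements supply full extents (lengths, widths, a bridge length and
width) per 30-s frame; these are halved into semi-axes and radii on load.
Bridge length is interpreted tip-to-tip, the natural reading of an
on-image measurement; centre-to-centre is the alternative we rejected.
Between frames every scalar parameter is linearly interpolated and centres
re-derived, so the envelope moves smoothly. To guarantee the union stays
connected across the zero-measure tip junctions, the cylinder is extended
into each lobe by 1% of its half-length; whether the original study's code
treated this junction volume explicitly is not recoverable, and at these
dimensions the effect on volumes is far below Monte-Carlo resolution.

Prolateness is *intended* but not enforced: measured widths occasionally
exceed lengths transiently, and the machinery is agnostic.

## Volume exclusion

A plasmid of radius `r` is admissible at a centre position when a sphere of
radius `r` fits **entirely within at least one primitive** — the union of
per-primitive erosions. True erosion of a non-convex union has no closed
form; our approximation is slightly conservative near the junctions (it
marginally under-permits passage), and it is this definition — not exact
union erosion — that the brute-force oracle in the test-suite certifies.
Each eroded primitive is convex, which is what makes closest-point
remapping exact: the projection onto a union of convex sets is the best
per-set projection.

Spheroid erosion is *not* a spheroid (shrinking semi-axes by `r` errs by up
to O(r²/a)), so membership and remapping go through the true surface
distance: by rotational symmetry every query reduces to a 2D
point-to-ellipse problem, solved by a bracketed Newton iteration on the
standard Lagrange parameter to below 1e-9 um. A cheap two-sided gradient
bound — `(1 - q) min(a,b) <= dist <= (1 - q) max(a,b)` where `q` is the
normalised elliptic radius — answers most containment queries without the
Newton solve. Remapping uses the foot-point-normal construction with a
constrained fallback scan for the rare near-tip cusp cases where the inward
offset leaves the erosion.

## Stochastic dynamics

Free diffusion with coefficient `D` gives a per-axis mean-squared
displacement `2 D t`, so a target spatial resolution `s_res` motivates the
fixed time step

```
dt = s_res^2 / (m * D)
```

with divisor `m >= 1` tightening the step so that boundary motion per step
(linear in `dt`, since parameters are interpolated linearly) stays
negligible against diffusive motion (proportional to `sqrt(dt)`). Defaults
mirror the published protocol: `s_res = 0.025` um (an order of magnitude
below confocal resolution), `m = 4`, `D = 0.0027` um²/s (the mean measured
plasmid diffusion coefficient), occupancy recorded every 30 s. The
time-step study (`timestep_study()`) repeats an ensemble across
`m in {1,2,4,8}` at the worst case `D = 0.001` um²/s; in our tests at 5000
repeats the final proportions are statistically indistinguishable, the
expected signature of a converged scheme.

Each step of `simulate_particle()`:

1. advances the clock and re-interpolates the geometry; if the moving
   boundary has overtaken the particle it is remapped to the closest
   admissible point (the published description orders remapping only after
   propagation; remapping after boundary motion as well keeps the state
   valid at every instant, and both orderings agree as `dt -> 0`);
2. adds independent Gaussian increments of variance `2 D dt` per axis (the
   final step is truncated to the last frame time with correspondingly
   reduced variance);
3. remaps again if the step left the domain.

The initial position is uniform over the admissible volume of the first
frame (mother and daughter both possible); the transmission readout is the
compartment label at the last frame time, i.e. immediately preceding
karyofission — no post-division dynamics are modelled. One plasmid per run;
plasmid-plasmid and plasmid-chromosome crowding are treated as folded into
the *effective* measured `D`.

## Random numbers

The stepping kernel draws from its own counter-seeded generator
(xoshiro256++ seeded through splitmix64, Box-Muller normals). Every repeat
of an ensemble receives a seed derived by an affine hash of the root seed
and the repeat index (`derive_seed()`), so ensembles are reproducible,
order-independent, and independent of R's global RNG; Monte-Carlo volume
estimates run on their own derived streams for the same reason. Identical
(seed, configuration, geometry) triples give bit-identical label sequences.
Collisions between derived streams of different ensembles are theoretically
possible but carry no statistical weight at these ensemble sizes.

## Estimators

* `estimate_diffusion()`: `D = <x^2> / (2 d dt)` from squared jump
  magnitudes at fixed sampling interval; planar tracking (`d = 2`) of an
  isotropic walk is unbiased, which the tests verify by comparing 3D and
  projected-2D analyses of the same increments. Jumps recorded against the
  nuclear membrane must be excluded upstream — the estimator targets a free
  diffusion coefficient.
* `freedman_diaconis_width()`: `2 IQR n^(-1/3)` with the IQR from
  linear-interpolation quantiles (R type 7); the rule is
  convention-sensitive, so the convention is pinned.
* `mitotic_stability()`: selective / non-selective colony ratio; ratios
  above 1 are counting noise and warn rather than error.
* `plasmid_loss_rate()`: `1 - (T1/T0)^(1/n)`; monotone in `T1` and exactly
  invertible — applying the per-generation retention `n` times returns
  `T1/T0`.
* `binomial_ci()`: normal-approximation interval clipped to [0, 1], chosen
  over Wilson/Clopper-Pearson to match the "assuming binomial samples"
  convention of the transmission traces; it degenerates to zero width at
  observed proportions of 0 or 1, which is documented behaviour.

## The synthetic geometry generator

No generative model of nuclear shape was published, so
`generate_geometry_series()` is an **emulation, not an inference**: smooth
monotone trajectories (smoothstep daughter growth from 15% of final size,
linear bridge elongation, smoothstep bridge width change, a 5% mother
narrowing) between endpoints sampled uniformly from configurable ranges.
The final daughter extents are rescaled so closed-form spheroid volumes hit
a target daughter volume fraction drawn from the empirically motivated
33-48% interval, with bounded resampling of infeasible draws. Default
ranges (mother 2.2-3.0 x 1.6-2.2 um, daughter 1.6-2.4 x 1.3-1.9 um, bridge
reaching 2.0-3.5 um at 0.25-0.45 um final width, anaphase 480-900 s at 30-s
frames) were chosen once as morphologically plausible for budding yeast
anaphase. Two presets bracket the observed cell-to-cell contrast:
`"narrow_bridge"` (a persistently narrow neck from early anaphase, which
suppresses transmission of sizeable plasmids regardless of `D`) and
`"wide_bridge"` (the most `D`-sensitive morphology).

What passing tests on synthetic geometries do **not** show: quantitative
agreement with any particular measured cell. Transmission percentages are
sensitive to morphological details — joint correlations among the nine
summary metrics, exact bridge-width trajectories — that the generator's
independent uniform ranges deliberately do not model. The generator's
role is to provide valid, reproducible, structurally realistic inputs for
verifying the *mechanics* (containment, remapping, equilibration,
monotone trends in `D` and particle radius, the mother-biased asymmetry
under a narrowing bridge), all of which are morphology-robust.

The colony-count generator draws binomial selective counts against a fixed
non-selective plating depth. Recovery of a loss rate is only identifiable
when `T0 (1 - rate)^n x plated` leaves a countable number of selective
colonies; the recovery checks therefore use few generations at deep plating
(n = 3, 1e5 plated) with a wild-type-like truth of 0.37/generation.

## Numerical and design choices, collected

* Coordinate convention: division axis = x, bridge midpoint at the origin,
  mother negative. Nothing upstream fixes axes; one convention had to be
  chosen and is used everywhere, including the CSV dialects.
* `x = 0` labels as mother (deterministic tie-break).
* Point-to-ellipse tolerance 1e-9 um; remapped points are nudged 1e-7 um
  into the admissible set so containment re-checks cannot flicker on
  solver noise.
* Uniform positions by rejection from the bounding box; an acceptance rate
  below 1e-4 raises a degenerate-geometry error rather than looping.
* Occupancy is recorded at the first step boundary at or after each record
  time; with `dt` two to three orders of magnitude below the 30-s record
  interval the induced lag is negligible.
* Geometries too narrow for the requested particle radius raise an error
  naming the simulation time at which no primitive admits the particle.

## Problem sizes

The test-suite runs everything at desk scale, chosen to keep the full suite
around five minutes while leaving comfortable statistical margins: oracle
agreement on 3 frames x 1000 random points x radii {0, 0.05, 0.1} um
against densely sampled boundaries; equilibration of 5000 point particles
in a static asymmetric nucleus over ~10 diffusive mixing times; 5000-repeat
blocking and time-step studies; 1000-repeat, two-cell trend sweeps over
`D in {0.001, 0.005, 0.009}` um²/s and radii up to 100 nm. The acceptance
script simulates a 10-cell synthetic ensemble at 300 repeats per cell and
radius, the published per-cell ensemble size.

## Limitations

* Plasmids are hard spheres; a flexible-polymer representation (and
  time-varying effective volumes) is out of scope — the sphere brackets a
  polymer's behaviour between the point-particle and large-sphere limits.
* Single plasmid per run: no clumping, copy-number dynamics, or
  plasmid-plasmid interactions.
* No nuclear-pore tethering or explicit diffusion-barrier models; the
  package exists to quantify how much asymmetry arises *without* them.
* Arbitrary meshes, curved bridges and membrane fluctuations are not
  representable; the composite-of-revolution geometry is the model.
* The synthetic generator approximates marginal ranges of the morphology
  metrics, not their joint distribution.
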