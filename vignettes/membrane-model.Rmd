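---
title: "The coarse-grained red-cell membrane model in rbcshape"
author: "rbcshape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coarse-grained red-cell membrane model in rbcshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rbcshape)
```

## The model

A red blood cell has no internal structure; its shape is set by the
membrane. `rbcshape` represents that membrane as a closed triangulated
surface whose `nV` vertices stand for actin junctional complexes, whose
`nS` edges stand for spectrin links, and whose `nT` triangles tile the
lipid bilayer. The equilibrium cell shape is the minimiser of a Helmholtz
free energy with six components:

* **Stretching** - each spectrin link carries a worm-like-chain (WLC)
  attraction plus a power-law repulsion,
  `E_WLC(l) = (kBT lmax / 4p) (3x^2 - 2x^3)/(1 - x)` with `x = l/lmax`, and
  `E_POW(l) = kp / ((m-1) l^(m-1))`. The two balance at the rest length
  `l0 = x0 lmax`, giving the network its shear rigidity.
* **Bending** - a discrete Helfrich energy at zero spontaneous curvature,
  `E_Bend = 2 kappa sum_j M_j^2 / dA_j`, built from the per-edge curvature
  `M_j = l_j theta_j / 2` (signed dihedral angle `theta_j` between outward
  triangle normals) and the edge-associated area `dA_j = (A_T1 + A_T2)/3`.
* **Area and volume constraints** - quadratic penalties on the total area
  (`kA`), each triangle's area (`ka`, the bilayer is anchored to the
  cytoskeleton and lipid flow over the surface is restricted), and the
  enclosed volume (`kv`).
* **Bilayer-coupling constraints** - the leaflet area difference
  `dA = 2 D0 sum_j M_j` is held near a reference `dA0` with coefficient
  `kad` (energy `(pi kad / 2 D0^2)(dA - dA0)^2 / A`); a companion penalty
  with coefficient `kC` holds the *total membrane curvature*
  `C = 2 D0 sum_j |M_j|` near `C0`. The second constraint removes the
  degeneracy of the first: many convex/concave arrangements share one
  `dA`, and `C0` selects among them.

The two leaflets of the bilayer stay coupled (the bilayer-couple
hypothesis): relative expansion of the outer leaflet drives convex texture
(spicules, echinocytes), relative expansion of the inner leaflet drives
concave texture (cups and invaginations, stomatocytes). In the
bilayer-coupling regime `kad >> kappa` (the defaults give `kad/kappa =
300`, equivalent non-local modulus ~ `4 kad`), so the equilibrium leaflet
area difference actually reaches its reference - which is what makes
quantitative comparison with measured cells possible.

### Sign convention

`theta_j > 0` (hence `M_j > 0`) where the surface is locally **convex seen
from outside**; a sphere is positive everywhere, spicule tips strongly
positive, dimples and invaginations negative. This convention makes the
sphere's leaflet area difference positive (`dA = 8 pi R D0`, i.e.
`dA/A = 2 D0 / R` = 0.12 % for the physiological cell - inside the sweep
window below), which is the physically required sign: a sphere's outer
leaflet is the larger one. The per-vertex curvature field
`CV_i = sum M_j / sum dA_j` (sums over the links at vertex i) then
converges to the mean curvature, `+1/R` on a sphere; a variant without the
area normalisation is available for sensitivity checks but scales with
vertex valence.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `A0` | 140 | um^2 | reference membrane area (sets `R_RBC` = 3.34 um) |
| `V0` | 93.48 | um^3 | reference volume, `nu` = 0.6 of the equal-area sphere |
| `kappa` | 2.5e-19 | N m | bending modulus |
| `kA`, `ka` | 1e-3, 5e-5 | N/m | total/local area coefficients |
| `kv` | 100 | N/m^2 | volume coefficient |
| `kad`, `kC` | 7.5e-17, 2.5e-17 | N m | leaflet-difference / total-curvature coefficients |
| `D0` | 2 | nm | monolayer thickness |
| `mu0` | 4.0 | uN/m | membrane shear modulus |
| `T`, `x0`, `m` | 296.15 K, 0.45, 2 | - | WLC calibration constants |
| `dA0/A0` | 0.05-0.30 | % | swept; low = stomatocytes, high = echinocytes |
| `C0/A0` | 0.30-0.90 | % | swept alongside `dA0/A0` |

The elastic length scale `Lambda_el = sqrt(kappa/mu0)` (0.25 um at the
defaults) measures the bending-shear competition that controls spicule
sharpness; the length-scale study varies `mu0` by factors 5, 2, 1, 0.5,
0.2, giving 0.11-0.56 um.

### Spectrin calibration

`calibrateSpectrin()` solves for the persistence length `p` and repulsion
coefficient `kp` from two conditions: zero net link force at `l0`, and the
coarse-grained shear-modulus relation evaluated at the mean `l0` equal to
`mu0`. We use the relation in its triangulated-network literature form
(with its `sqrt(3)` prefactors); a variant without them is selectable, and
either choice is self-consistent because calibration and evaluation share
one expression. With the force balance substituted the relation is exactly
linear in `1/p`, so the solve is closed-form and deterministic; a test
verifies it against a dense grid search. Because rest lengths vary per
edge in a non-spherical reference state, `kp` is set per edge from the
force balance at that edge's own `l0` (a single global `kp` cannot make
every link force-free at its rest length); `p` remains global.

## The cytoskeletal reference state

The stress-free geometry of the spectrin network is taken to be an oblate
spheroid at `nuCyto = 0.94` of the equal-area sphere volume.
`generateReference()` relaxes a cytoskeleton-only membrane - strong
bending (`kappa` = 5e-18 N m) to keep it smooth, no leaflet constraints -
to that spheroid and reads the converged edge lengths back as the per-link
`l0`, so the reference is exactly stress-free. Two implementation choices
matter here:

* **Warm start.** Gradient descent from a perfect icosphere cannot reach
  the spheroid: the flattening mode has zero gradient by symmetry, and the
  sphere-like state is a genuine stationary point. The relaxation
  therefore starts from the analytic oblate spheroid of matching area and
  volume (a sphere start with volume ramping remains available).
* **Constraint stiffness.** With the strong reference-generation bending
  modulus, volume and area penalties at the main-model coefficients are
  soft by comparison: the minimum of the oblate family then sits near
  `nu = 0.96` regardless of the 0.94 target (the volume release from
  sphere to 0.94-spheroid, ~2.2e-17 J, barely exceeds the +14 % spheroid
  bending cost). Because `nuCyto` *defines* the reference state, the
  generator defaults to `kv = 1e4` N/m^2 and `kA = 1e-2` N/m during
  reference generation only; the relaxed state is stress-free regardless,
  and the main model keeps the standard coefficients.

## Relaxation dynamics

Forces are the exact analytic gradient of the total energy (the dihedral
gradient is the standard hinge formula, regression-tested against central
finite differences at relative 1e-5). The default integrator is
overdamped first-order descent, `x += (F/c) dt`: the equilibrium is
independent of the damping `c` and particle mass, which only set the
approach speed. An `"as-printed"` mode that updates velocities with a
multiplicative damping factor is kept for comparison; both modes reach the
same equilibria within 0.5 % in the shape descriptors.

Numerical choices:

* **Time step.** `dt` is fixed from the force scale at the end of the
  constraint ramp (displacement of the strongest-pulled vertex =
  `dtSafety` x the minimum edge length, `dtSafety` = 0.05), then adapted:
  halved whenever a step would raise the energy (the step is rejected),
  grown by 2 % per accepted step. No vertex ever moves more than a
  quarter edge length per step. After the ramp the total energy is
  monotone non-increasing by construction.
* **Constraint ramping.** `V0`, `dA0` and `C0` are interpolated linearly
  from the starting mesh's own values to their targets over the first 10 %
  of the iteration budget; jumping a sphere straight to `nu = 0.6` can
  invert mesh elements.
* **Symmetry breaking.** A seeded radial perturbation (amplitude 1e-3 of
  the equal-area sphere radius, uniform per-vertex factors) is applied to
  the start so that spicule/dimple nucleation is reproducible. Where the
  constrained minimum is unique (mild targets), equilibria are identical
  across seeds, damping, particle mass and integrator mode to numerical
  precision. Deep in the SDE sweep the bilayer-coupling landscape is
  genuinely multistable - different seeds can select differently arranged
  dimple/spicule patterns whose descriptors differ by a few percent -
  which is a property of the model, not of the integrator.
* **Convergence.** Every `checkInterval` iterations each of the six energy
  components is compared with its previous value; the state is converged
  when all change by less than `convergenceTol = 1e-7` relative over two
  consecutive checks. Components below 1e-25 J, or below a millionth of
  the total, cannot block convergence (a pure relative rule is ill-posed
  at zero, and such components are immaterial to the minimiser).
* **Degeneracies.** Triangle areas below 1e-12 um^2 raise an error rather
  than produce NaN normals; a spectrin link at `lmax` makes the step
  backtrack (the WLC energy diverges there); self-intersection is
  monitored by no mechanism - it is outside the model's scope.

## What the experiments show

`runPoint()` builds the constraints from `(nu, dA0/A0, C0/A0)`, calibrates
spectrin on the reference state, relaxes a perturbed icosphere, and
measures the result. Across the transect of the `(dA0/A0, C0/A0)` plane at
`nu = 0.6` the relaxed shapes run through the
stomatocyte-discocyte-echinocyte (SDE) ladder: deep negative vertex
curvature and an invagination at the low end, the biconcave discocyte in
the interior (lowest shape factor `SF = H1/sqrt(H2 H3)` - the
deformability proxy), and increasingly many convex spicules toward the
high end. Raising `nu` at fixed targets makes every stage more spherical
(SF grows); raising `Lambda_el` smooths the extremes of the vertex
curvature field.

Morphometry follows the rigid-body convention: the inertia tensor of the
surface treated as a uniform thin shell (area-weighted, exact per-triangle
quadrature - the membrane is a surface, not a solid), peak-to-peak vertex
extents `H1 <= H2 <= H3` along the principal axes, `Hx = H3/R*`,
`Hz = H1/R*`, `SF` as above. `measureExternal()` applies the same pipeline
to any closed triangle mesh read from OFF/PLY/VTK, so confocal-derived
surfaces can be compared with model output via `compareShapes()`
(percentage errors in `Hx`, `Hz`, `SF`).

## Problem sizes

The mesh resolution used for full-fidelity prediction is subdivision
level 4 (2,562 vertices, 5,120 triangles, 7,680 links), where area,
volume, integrated curvature and bending energy of the sphere are all
within 1 % of closed forms. The package's test-suite experiments run at
level 3 (642 vertices) with iteration budgets around 2e5, which resolves
the SDE ladder and keeps a full transect in minutes; level is a parameter
everywhere and recorded in every output.

## What the synthetic fixtures do and do not show

All tests run on programmatically built surfaces: icospheres, ellipsoids,
jittered spheres, dented octahedra, dimpled spheres. These exercise the
geometry, energetics and dynamics exactly (closed forms exist), but they
are idealisations: real confocal-derived cell surfaces carry segmentation
noise, uneven triangle quality and possible near-self-intersections that
the fixtures do not emulate. Passing tests therefore validate the model
and its implementation, not the robustness of morphometry to imaging
artefacts; the reader feeding external meshes should check triangle
quality (`meshQuality()`) first.

## Known limitations

* Genus-0 closed surfaces only; no remeshing, edge flips or
  self-intersection handling. Vesiculation (bud detachment) is outside the
  model.
* The classifier behind `classifyShape()`/`countProtrusions()` is a
  labelled heuristic for ranking sweep output, not a validated stage
  assignment.
* The `C0` target interacts with shape at fixed `dA0`: very high `C0/A0`
  at low `dA0/A0` forces mixed-sign texture on shapes that would otherwise
  be smooth. The sweep ranges quoted above are where the SDE
  interpretation is meaningful.
* With the default coefficients the total-curvature constraint is
  effectively hard: the equilibrium integrated |curvature| reaches `C0`
  for every elastic length scale. Softening the network then
  redistributes that fixed curvature budget onto fewer, broader
  protrusions (the spicule count falls sharply with `Lambda_el`), but the
  pointwise curvature extreme does not fall with it at the test
  resolution - spicule-tip radii at the elastic length scale (0.1-0.6 um)
  lie at or below the level-3 edge length (~0.5 um). Resolving the
  tip-sharpness dependence on `Lambda_el` requires level-4 meshes and
  correspondingly longer relaxations.
* Thermal fluctuations, spectrin-network remodelling and hydrodynamics are
  absent by construction; the dynamics is a minimisation device, not a
  kinetic model.
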