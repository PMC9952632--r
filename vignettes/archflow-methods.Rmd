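---
title: "archflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{archflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`archflow` is a desk-scale pipeline for studying how stent-graft remodeling
of the aortic arch reshapes the intraluminal flow field and the wall shear
stress (WSS) environment. This vignette is the package's own account of the
science and the numerics: what is modeled, what the tunable parameters mean,
which choices were genuinely open and how they were settled, and what the
passing test suite does and does not establish.

## The physical model

Blood is modeled as an incompressible Newtonian fluid (density
$\rho = 1060$ kg m$^{-3}$, dynamic viscosity $\mu = 0.0035$ Pa s) in a
rigid-walled lumen, governed by the laminar Navier–Stokes equations. The
laminar assumption is deliberate: the high pulsatility of aortic flow
suppresses sustained turbulence, and with adequately fine near-wall
resolution a laminar model captures the main flow patterns that drive the
WSS indices. Wall compliance, stent mechanics and fluid–structure
interaction are out of scope; the walls are rigid and no-slip.

Boundary conditions over the 1-s cardiac cycle:

* **Inlet** (ascending aorta): a prescribed cross-section-mean velocity
  $v(t)$, a three-piece cosine that rises from 0.295 m/s at end diastole to
  1.06 m/s at peak systole ($t = 0.15$ s) and decays through two diastolic
  pieces. The printed angular coefficients 6.6667$\pi$ and 3.3333$\pi$ are
  implemented as the exact rationals $20\pi/3$ and $10\pi/3$; with those
  values both internal junctions and the cycle closure are continuous to
  machine precision, which strongly suggests the rounded decimals are
  typographic. The spatial profile (plug by default, parabolic optional) is
  a modeling choice because the source signal is a cross-section mean; the
  5-diameter flow extensions make the arch-region solution insensitive to
  it.
* **Outlets** (descending aorta and each supra-aortic branch): one shared
  pulsatile pressure signal, 90 mmHg at end diastole to 140 mmHg at peak
  systole, imposed weakly as a normal traction. The diastolic piece of the
  printed pressure expression is typographically garbled in the source; the
  package adopts the reading
  $p(t) = (p(0.35) - 90)\cos(0.7692\pi(t-0.35) + \pi - 1.5) + p(0.35)$,
  selected because $0.7692\pi \times 0.65 \approx \pi/2$ restores
  periodicity ($p(1) - p(0^+) \approx 0.1$ mmHg). The residual jump of
  about 2.3 mmHg at $t = 0.35$ s is a property of that source signal; it is
  measured and reported by `waveform_diagnostics()` rather than hidden. The
  interpretation is a named, swappable policy in
  `outlet_pressure_waveform()`.
* Because every outlet carries the same pressure, the flow split between
  branches is resistance/geometry-driven, which is exactly the quantity the
  cross-case comparison tracks.

## Geometry: four parametric stages

No imaging data underlies the package; the geometries are parametric
idealizations that encode the morphological differences between the four
stages of stent-graft remodeling:

| stage | aneurysm | LSA | IA/LCCA ostia | arch curvature radius |
|---|---|---|---|---|
| normal | absent | open | on the arch | 32 mm |
| preop | saccular pouch, distal arch | open | on the arch | 32 mm |
| postop1w | excluded | occluded | proximal ascending | 25 mm |
| postop6m | excluded | occluded | proximal ascending | 29 mm |

All absolute dimensions (lumen radius 12.5 mm, ascending/descending lengths
60/100 mm, branch radii 6/4/4 mm for IA/LCCA/LSA, IA bifurcating into RSA
and RCCA after 20 mm, sac depth 20 mm with a 20 mm neck) are adult-aortic
presets chosen once for plausibility; none is a measurement. What the
presets *do* preserve are the qualitative orderings the comparison module
tests: curvature dip at 1 week with partial recovery at 6 months,
strictly proximal postoperative ostia, LSA occlusion, and sac exclusion.

The production meshes are planar (2-D): the trunk is a mapped
channel (straight–toroidal–straight) with six graded boundary layers
(ratio 1.2) on both walls, branches are conforming channel patches on the
outer wall, and every open end carries a 5-diameter flow extension tagged
separately so that area statistics can exclude it. A 3-D tetrahedral sweep
mode (`mode = "tube3d"`, boundary-layer-graded disc swept along the trunk
centerline) exists for branch-free geometries and carries the quantitative
Poiseuille verification; conforming 3-D junction meshing of the supra-aortic
branches was judged out of desk-scale scope, so the four-case comparison is
explicitly a planar-model result. Meshing is deterministic: identical specs
produce bitwise-identical nodes.

The aneurysm is built as a genuine *side pouch*: a cavity patch on the outer
arch wall, open to the lumen across its neck and closed elsewhere, with a
tapered dome. An earlier construction that widened the channel smoothly (a
diffuser) produced no recirculation at desk-scale resolution — attached
diffuser flow and shear-driven cavity flow are qualitatively different
regimes, and only the pouch reproduces the retrograde sac flow that the
comparison module probes. Cavity recirculation is driven by the shear of
the main stream across the neck and is robust across Reynolds numbers,
which makes it an honest qualitative observable at coarse resolution.

## Discretization and solver

The spatial discretization is stabilized equal-order linear finite elements
(P1–P1): SUPG/PSPG with a grad-div term, assembled in C++ (Rcpp). The
stabilization parameter uses two element lengths: the streamwise length
$h_{ugn} = 2|a| / \sum_b |a\cdot\nabla\phi_b|$ for the advective limit and
the *shortest* edge for the viscous/PSPG limit,
$\tau = \big((2/\Delta t)^2 + (2|a|/h_{ugn})^2 + (12\nu/h_{min}^2)^2\big)^{-1/2}$.
The second choice matters: with the conventional longest-edge length, the
pressure stabilization in the strongly anisotropic boundary-layer cells
perturbs the near-wall momentum balance enough to bias the computed wall
shear by several percent; with the shortest edge the steady Poiseuille WSS
oracle converges cleanly (see below).

Time stepping is a $\theta$-scheme with semi-implicit (Picard-linearized)
convection: $\theta = 1$ (backward Euler) is the robust default for the
four-case runs, $\theta = 0.5$ (Crank–Nicolson) is used where second-order
temporal accuracy is needed (the oscillatory-channel oracle, where
first-order damping would otherwise dominate the error). The time step is
fixed (2 ms package default; the coarse comparison tier uses 4 ms) rather
than adaptive, so snapshot times are reproducible for the index quadrature.
Two cycles are simulated and the first is discarded as the impulsive-start
transient; the stored cycle closes on itself (first and last snapshot one
period apart).

Each step solves the linearized stabilized system by defect correction
against a frozen, factorized reference operator (sparse LU from the Matrix
package, cached): outer sweeps reassemble at the current iterate (Picard),
inner sweeps are residual + triangular-solve corrections, and the reference
is refactorized only when the inner iteration stops contracting. This keeps
the per-step cost at one assembly plus a few triangular solves, with
factorizations amortized over many steps. A step is accepted when the
relative change between Picard iterates falls below the nonlinear tolerance
(0.005 by default), the same relative-error criterion the adaptive
commercial solve would apply between iterations; the inner linear tolerance
is 10× tighter, which is what keeps the global flux imbalance near machine
precision (summing the discrete continuity rows telescopes the PSPG terms
away, so the boundary fluxes balance exactly at convergence).

Outlet backflow stabilization ($\tfrac{\rho}{2}(u\cdot n)_-\, u$ penalty)
is enabled for the arch runs, where diastolic branch backflow would
otherwise destabilize the traction outlets, and disabled for verification
problems driven by reversing cap pressures, where it would bias the
effective traction (it is a `solver_config()` switch).

## Wall shear stress and the indices

WSS is stored per wall facet. The velocity gradient at the facet midpoint
is reconstructed by quadratic patch recovery (least-squares fit over the
node patch around the wall-adjacent cell; exact for quadratic profiles,
hence for Poiseuille flow) with the piecewise-constant cell gradient as the
first-order fallback and as an explicit `method = "cell"` option (exact for
linear fields; used by the refinement-monotonicity test because its error
scales cleanly with the first-layer thickness). The full viscous traction
$\mu(\nabla u + \nabla u^\top)n$ is projected tangentially, so the tangency
invariant $|\tau\cdot n| \le 10^{-8}|\tau|$ holds by construction.

TAWSS, $\tau_{mean}$, OSI and RRT follow the standard definitions
(composite trapezoid in time with periodic closure; the integration rule is
a package choice). Degenerate cases are flagged, not silently patched:
facets with TAWSS below $10^{-12}$ Pa get OSI 0 plus a warning count, and
RRT at OSI $\to$ 0.5 is capped at $10^6$ Pa$^{-1}$ with the infinite flag
preserved and counted as exceeding the RRT threshold in the risk report.
Risk thresholds (TAWSS < 0.4 Pa, OSI > 0.25, RRT > 5 Pa$^{-1}$) use strict
inequalities, and the threshold triple is self-consistent: a facet at
TAWSS = 0.4 Pa and OSI = 0.25 has RRT exactly 5 Pa$^{-1}$. Area statistics
run on wall facets only and exclude the flow extensions.

## Verification: what the tests establish

* **Steady Poiseuille tube** (3-D, R = 5 mm, Re = 100): facet-averaged
  $|\tau_w|$ against $4\mu Q/\pi R^3$ at two resolutions (core size 2.6 mm
  / 1.3 mm, about 840 and 3800 nodes); patch-recovery errors are a few
  tenths of a percent, cell-gradient errors fall from ~3.4% to ~0.9%
  monotonically. Centerline-to-mean velocity ratio converges to 2.
* **Oscillatory channel** (2-D, half-height 1 mm, Womersley number
  $\alpha \approx 1.4$): velocity profiles against the analytic
  Stokes-layer series, relative $L^2$ error ≈ 2%; mid-channel wall OSI
  within $10^{-4}$ of 0.5 for the zero-mean forcing.
* **Index quadrature**: on 100 seeded smooth random traction series, the
  trapezoid indices match a 100×-oversampled oracle to better than
  $10^{-4}$ relative, and the bounds $0 \le \mathrm{OSI} \le 0.5$,
  $\tau_{mean} \le \tau_{abs}$, $\mathrm{RRT} \ge 1/\mathrm{TAWSS}$ hold.
* **Conservation**: the maximum cyclic flux imbalance of every converged
  run is far below the 1% reporting threshold (near machine precision, by
  the telescoping argument above).
* **Morphometry**: the circumscribed-circle curvature estimator is exact on
  circles, rigid-motion invariant, and recovers helix curvature within 2%.

The four-case comparison, by contrast, is *qualitative by design*: a planar
model at coarse resolution cannot reproduce patient-specific perfusion bars
or risk-area magnitudes, and the package claims none. What the passing
orderings show is that the implemented morphological changes produce the
expected directional hemodynamic responses (sac recirculation, zero LSA
perfusion, curvature dip and recovery, enlarged low-TAWSS burden with an
aneurysm). They do not validate the model against clinical data, secondary
or helical flow structures (inherently 3-D), or non-Newtonian effects.

## Problem sizes and runtime envelope

Chosen once as the package's desk-scale operating point: coarse tier
meshes ≈ 4–5k triangles per case (4 mm core elements), 4 ms steps, 2
cycles, snapshots every 20 ms; the full four-case comparison then runs in
roughly 5 minutes on a single CPU and the whole verification battery
(`scripts/acceptance.R`) in roughly 15. The medium/fine tiers (2 mm / 1 mm)
exist for convergence studies and are not exercised by the default test
suite.

## Known limitations

* Planar production geometry: no secondary/helical flow, torsion, or
  out-of-plane curvature; per-unit-depth fluxes and areas.
* One shared outlet pressure: no peripheral impedance models, so absolute
  branch perfusion fractions reflect geometry only.
* Rigid walls, Newtonian rheology, laminar model: standard for this class
  of comparison, but all three are simplifications.
* The diastolic pressure piece rests on a documented typographic
  interpretation; anyone with access to the original measurement should
  re-derive it.
* First-order elements: index *maps* are facet-piecewise-constant; isolated
  facet values should not be over-interpreted at coarse resolution.
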