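# archflow

Desk-scale computational hemodynamics of aortic-arch stent-graft
remodeling, in R.

Endovascular repair of aortic-arch disease with a modular inner branched
stent-graft (MIBSG) reshapes the vessel: the aneurysm sac is excluded, the
left subclavian artery (LSA) is occluded, the supra-aortic ostia move to the
proximal ascending aorta, and the arch curvature radius first tightens and
then partially recovers as the vessel remodels. Each of those morphological
changes alters the blood flow field and hence the wall shear stress (WSS)
environment that drives further remodeling. `archflow` lets you study that
interplay on idealized, fully parametric geometries: it generates lumen
meshes for four morphological stages (normal, preoperative with a saccular
arch aneurysm, 1 week postoperative, 6 months postoperative), solves
pulsatile laminar incompressible Newtonian flow over the cardiac cycle, and
post-processes the wall shear stress into the standard risk indices.

The package is aimed at biofluid-mechanics researchers and students who want
a transparent, scriptable, dependency-light pipeline for qualitative
hemodynamic comparisons — not at patient-specific clinical prediction.

## The model

Blood is treated as incompressible and Newtonian (density 1060 kg/m³,
dynamic viscosity 0.0035 Pa·s) in rigid-walled lumens, governed by the
laminar Navier–Stokes equations

ρ(∂u/∂t + u·∇u) = −∇p + μΔu,  ∇·u = 0,

discretized with stabilized linear finite elements (SUPG/PSPG with grad-div,
semi-implicit convection, θ time stepping) on structured simplex meshes with
six graded near-wall boundary layers. The inlet carries a pulsatile
cross-section-mean velocity waveform (period 1 s, 0.295 m/s at end
diastole, 1.06 m/s at peak systole, t = 0.15 s); every outlet carries a
pulsatile pressure waveform (90–140 mmHg) imposed weakly as a normal
traction. Inlets and outlets are extruded by five local diameters so the
flow develops before entering the region of interest.

From the solved cycle the wall shear stress vector τ_w is extracted per wall
facet and reduced to the standard indices:

- TAWSS = (1/T) ∫₀ᵀ |τ_w| dt — time-averaged wall shear stress (Pa);
- τ_mean = |(1/T) ∫₀ᵀ τ_w dt| — magnitude of the time-averaged vector;
- OSI = ½(1 − τ_mean/TAWSS) — oscillatory shear index, 0 (unidirectional)
  to 0.5 (fully reversing);
- RRT = 1/(TAWSS·(1 − 2·OSI)) — relative residence time (Pa⁻¹).

Wall regions with TAWSS < 0.4 Pa, OSI > 0.25 or RRT > 5 Pa⁻¹ are classified
as atherosclerosis-prone and reported as areas and wall fractions, broken
down by anatomical region. Per-outlet perfusion (cycle-averaged flux) and
centerline curvature morphometry complete the comparison.

## A worked example

Solve the preoperative (aneurysmal) case at the coarse tier and look at the
risk regions:

```r
library(archflow)

cfg <- pipeline_config(cases = "preop", tier = "coarse")
b   <- run_pipeline(cfg)$preop

b$risk
#> Risk-region report (wall area 7762 cm^2)
#>  criterion threshold area_cm2  fraction
#>  tawss_low      0.40 1934.640 0.2492574
#>   osi_high      0.25 2127.344 0.2740852
#>   rrt_high      5.00 2205.795 0.2841928

b$perfusion
#> Perfusion summary (inlet mean flow 742962 mL/min)
#>      outlet  mean_flow mean_flow_ml_min  fraction present
#>  descending  0.0075324           451947  0.608304    TRUE
#>         RSA -0.0001168            -7009 -0.009434    TRUE
#>        RCCA  0.0012363            74179  0.099843    TRUE
#>        LCCA  0.0020396           122379  0.164717    TRUE
#>         LSA  0.0016911           101466  0.136570    TRUE
```

(Planar production geometry: areas and flows are per unit out-of-plane
depth.) About a quarter of the wall — dominated by the aneurysm sac and the
inner curvature of the descending aorta — sits below the 0.4 Pa TAWSS
threshold; the descending aorta carries ~61% of the mean inflow and the
supra-aortic branches the rest, with the small retrograde RSA mean flow
reflecting its cycle-averaged backflow in this geometry. Comparing all four
stages:

```r
bundles <- run_pipeline(pipeline_config(tier = "coarse"))
compare_cases(bundles)
```

prints one row of headline metrics per case (risk areas, minimum arch
curvature radius, LSA perfusion fraction, mass-conservation diagnostic) and
the qualitative remodeling flags: the preoperative low-TAWSS area at least
matches the normal model, postoperative LSA perfusion is exactly zero, the
arch curvature radius dips at 1 week and partially recovers by 6 months,
and retrograde flow appears inside the preoperative sac at peak systole.

A thin command-line wrapper with `run-all` / `run` / `compare` / `geometry`
/ `waveforms` subcommands is installed at `inst/cli/archflow.R`.

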