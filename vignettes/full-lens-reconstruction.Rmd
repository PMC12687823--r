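---
title: "Full-shape crystalline lens reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-shape crystalline lens reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(lensrecon)
```

This vignette is the package's account of the science it implements: the
measurement model, the algorithms, the tunable parameters and the choices
made where the design was genuinely open. The README shows the user-facing
workflow; here we explain *why* each stage looks the way it does.

## The measurement problem

Anterior-segment OCT records, for each A-scan, the cumulative *optical path
length* (OPL) to each interface along a ray that is bent at every preceding
refractive surface. Two consequences follow. First, raw OCT geometry is
distorted: deeper surfaces appear displaced both axially (OPL exceeds
geometric distance by the group index) and laterally (the ray is not where
the A-scan says it is). Second, the iris occludes everything lateral to the
pupil, so a single on-axis acquisition can never see the lens equator.
Imaging the eye from eight gaze directions exposes different parts of the
lens periphery through the pupil; undistorting each view, expressing all
views in one coordinate system, and fusing them yields the complete lens.

## Coordinate conventions

Right-handed instrument frame, Z positive from the instrument into the eye,
millimetres everywhere after calibration. A meridian (radial B-scan) at
angle $\theta \in [0, \pi)$ contributes points
$(\ell\cos\theta, \ell\sin\theta, z)$, where $\ell$ is the signed lateral
position; the scan-direction flag mirrors $\ell$ for scans acquired from
the opposite quadrant, and an angle of exactly $\pi$ is normalized to $0$
with the flag flipped. The central A-scan (index $(N-1)/2$ of $N = 256$)
maps to $\ell = 0$; the lateral pitch is 14 mm / 256 A-scans, a protocol
value kept configurable because instrument lateral calibration is nominal.
Axially, 1 pixel = 9.2 µm of optical path.

## The eye phantom and the forward model

`make_phantom()` builds an analytic eye: conicoid anterior/posterior
cornea, a crystalline lens of two conicoid caps closed at an equatorial
contour, and a flat iris annulus. The default lens construction takes the
equatorial diameter, the thickness and the anterior share of the thickness
(`lens_split`) and derives *vertical-tangent* caps — ellipsoids whose
tangent planes are axial at the equator — so the closed profile is
C1-smooth there, as in vivo lens equators are. A sharp equatorial wedge
(which generic cap pairs produce) is both anatomically wrong and badly
representable on a finite polar grid or in a low-rank shape basis; the
smooth construction removes that artefact at its source. Explicit cap
radii/conics remain available for test geometries such as spherical caps,
and the `"spherical"` preset (diameter = thickness) is an exact sphere with
closed-form volume and area.

Default geometry ("young_adult"): cornea 7.8 / 6.5 mm apex radii with mild
prolate conics and 0.55 mm central thickness; anterior chamber depth
3.6 mm; lens 9.2 mm diameter, 3.8 mm thickness, anterior split 0.45; iris
plane at 3.5 mm with a 3.6 mm pupil radius emulating pharmacological
mydriasis; group indices 1.385 (cornea), 1.345 (aqueous), 1.417 (lens).
These are literature-plausible values for a young adult dilated eye and are
fixed once; the resulting volume (~168 mm³) and surface area (~171 mm²)
sit inside the range such eyes show.

`forward_simulate()` rotates the whole phantom rigidly about the
iris-circle centre by the gaze angle (no cyclotorsion — the registration
model only undoes rigid motion, so simulating torsion would change the
problem, not test it better) and traces one telecentric ray per A-scan per
meridian: closed-form conicoid intersections, vector-Snell refraction at
each interface, OPL accumulated as geometric segment times group index,
each crossing recorded at the A-scan's lateral pixel and the cumulative
OPL / 9.2 µm axial pixel. Rays crossing the iris annulus are blocked (iris
sample recorded, lens samples missing); rays that miss a surface are
missing, and total internal reflection drops the sample with a counter.
Gaussian iid pixel noise is added to axial coordinates only — axial
localization dominates real segmentation error, and lateral positions are
defined by the scan, not detected. A single index per medium is used for
both ray bending and OPL conversion; the simulator would accept distinct
phase/group sets, but they default equal since the distinction is beyond
the fidelity of everything else here.

What the phantom does *not* emulate: speckle or intensity images (only
segmented coordinates), eyelid/motion artifacts beyond iid noise, gradient
refractive index in the lens (a constant 1.417; the `index_sensitivity()`
sweep across 1.40/1.417/1.44 quantifies the consequence), accommodation
dynamics, and cyclotorsion. Passing the round-trip tests therefore shows
the pipeline inverts its own physics faithfully — not that real
segmentation noise, motion or GRIN effects are conquered.

## Surface fitting

Each surface is fitted with 15 Zernike terms (OSA/ANSI single-index
ordering, unit-variance normalization — the most common convention; the
count corresponds to radial orders up to 4) by least squares over a disc
whose radius is the maximal lateral data radius times 1.001 about the
lateral midrange of the data. The 1.001 inflation keeps rim samples
strictly inside the unit disc; midrange centring keeps partial (off-axis)
domains well conditioned. The design matrix is solved by QR; an
ill-conditioning warning fires at a condition number of 1e8.

One choice matters more than any other here: **the fit frame**. At 45°
gaze the surfaces are tilted 45° in the instrument frame, and the sag of a
tilted conicoid carries high-order content that 15 terms cannot absorb —
residuals of tens of microns, which refraction normals then amplify. Each
incidence therefore gets a *de-tilt rotation*, estimated from its raw iris
plane, stored with every fit; points are rotated into the surface's own
frame before fitting, and the evaluation/normal helpers apply the rotation
transparently. The expansion stays at 15 terms; only the frame changes.
With it, corrected surfaces land within a few microns of truth at every
gaze angle.

Evaluation outside the data support is refused rather than extrapolated: a
rasterized polar occupancy mask (16 radial x 36 angular bins, dilated by
one bin) plays the role of a concave support hull. A true alpha-shape
would serve the same purpose; the raster is dependency-free and its
granularity (about 0.3 mm at a 5 mm radius) matches the data density.

## Distortion correction

For each A-scan ray: refract $(0,0,1)$ at the anterior cornea (air →
cornea) using the fitted CA normal at the measured point; advance by
$\mathrm{OPL}_{CA\to CP}/n_{cornea}$ to place the posterior cornea; refit
CP; refract (cornea → aqueous); advance by
$\mathrm{OPL}_{CP\to LA}/n_{aqueous}$; refit LA; refract (aqueous → lens);
advance by $\mathrm{OPL}_{LA\to LP}/n_{lens}$. Iris points are corrected
through the cornea only (CA and CP refractions plus an aqueous
propagation): the iris is the registration reference, and correcting it
through a surface it sits on would be circular. Surfaces are corrected
raw → fit → correct → refit, in physical order; requesting them out of
order is an error. Rays whose CA crossing falls outside the corneal data
support lose their deeper samples — a corneal region that was not imaged
makes the lens below it unrecoverable, so silence there would fabricate
geometry.

The vector Snell step conserves the tangential component of $n\,\hat d$
exactly and signals total internal reflection with `NA`, never a silent
reflection. Ray/fitted-surface intersection (used by tests and available
for fan-beam variants) brackets the first sign change of
$z_{ray}(t) - z_{surf}(x(t), y(t))$ by marching and polishes by bisection
to 1e-10 mm; telecentric A-scan rays never need it in the standard chain
because the measured crossing *is* the intersection.

## Registration

The iris is the only structure visible in nearly every meridian of every
view, so it anchors the initial alignment: a total-least-squares plane
(smallest principal direction), its normal oriented toward the instrument;
the minimal rotation carrying that normal onto the axis; then a circle fit
in the plane — Taubin's algebraic fit polished by Gauss-Newton, a standard
pairing that is bias-free at this noise level — whose centre is translated
to the origin. Trimmed point-to-point ICP (gate 0.5 mm, trim fraction 0.2,
tolerance 1e-8 mm², at most 100 iterations; Kabsch closed-form update)
then refines each view against the union of already-registered *lens*
surfaces, in order of increasing gaze angle so overlap with the growing
reference is maximal. Only lens surfaces feed ICP: the lens is the rigid
structure shared across gaze-rotated views, while the cornea moves with
the gaze. All of the gate/trim/tolerance values are conventional ICP
settings, config-exposed; pairwise overlap RMS between registered views is
reported as a redundancy audit.

## The eigenlens representation

The merged lens cloud is centred laterally under the anterior-surface apex
(the maximum-elevation point of a smooth fit) and axially midway between
the anterior and posterior apex depths; radial elevations
$I(\theta_i, \phi_j)$ — distances from this origin — are then interpolated
onto the fixed grid of $P = 100$ equidistant elevations $[0, \pi]$
(anterior pole to posterior pole) by $Q = 100$ equidistant azimuths. Node
values come from local weighted-*quadratic* regression in the tangent
plane of each node direction (Gaussian weights, 0.06 rad support radius,
bucketed neighbour search): a linear local model leaves a curvature bias
of order 1e-3 mm on lens-like surfaces, the quadratic is curvature-exact.
Nodes without sufficient support are missing, to be completed by the
basis; an excessive radial spread within a neighbourhood (evidence against
star-convexity about the origin) is counted and warned about.

The shape basis is built from a synthetic training population of 80
two-cap lenses — diameter uniform on 8–10.5 mm, thickness on 3.2–4.8 mm,
anterior split on 0.38–0.52, plus a small random elliptical lateral
scaling for azimuthal variety — sampled analytically on the grid, with a
fixed seed so the basis is a reproducible package constant. The mean lens
$\bar I$ and the first $K = 6$ right singular vectors of the centred
training matrix form the basis (columns orthonormal, eigenvalue-ordered).
For complete grids the coefficients are the exact inner products
$a = M^{\mathsf T}(I - \bar I)$; with missing nodes the normal equations
restricted to observed rows are solved instead — the linear-algebra
reading of "fill the unrecovered portion from the basis". Reconstruction
$\hat I = \bar I + \sum_k a_k e_k$ is defined on the whole grid; because
the population spans only anatomical shapes, the projection also filters
node noise by roughly $\sqrt{K/M}$.

The real training population for such a basis is ex vivo full-lens data;
it is not distributable here, so the synthetic family stands in. The
basis file format (`write_basis()`/`read_basis()`, JSON with a checksum)
accepts a drop-in replacement.

## Morphometry

All three parameters are computed from the closed grid shape. DIA is the
maximal through-axis caliper: per azimuth, the maximal lateral radius
$I\sin\theta$ along elevation (with three-point parabolic refinement of
the grid maximum), then the maximum of opposite-azimuth sums. VOL splits
the shape at the equatorial contour (the locus of those per-azimuth
maxima) and integrates the axial gap over the equatorial disc, evaluated
per azimuth as a 1-D trapezoid along the elevation parameter — smooth in
that parameterization, so the sphere's rim singularity costs nothing and
convergence is second order. LSA triangulates the parameter plane — on
the fixed regular grid the Delaunay triangulation reduces to two
triangles per cell with azimuthal wrap, and pole rows collapse to fans —
and sums 3-D triangle areas; as an inscribed mesh it converges to the true
area from below for convex shapes. At the default 100 x 100 grid the
sphere limits are reproduced to well under 0.1 %.

## Statistics

`coefficient_of_variation()` is 100 x sample SD (n−1) over the mean — the
convention that reproduces published repeatability CVs of repeated ocular
biometry from their printed measurement triplets. `spearman_rank()` uses
midranks for ties and, for n ≤ 9, an exact two-sided permutation p-value
by full enumeration (the t-approximation otherwise) — cohort sizes in
this field are small enough that asymptotics are not defensible.
`bland_altman()` returns MD ± 1.96 SD limits of agreement, and
`normality_gate()` (Shapiro-Wilk) routes variables to non-parametric
summaries, as lens volume typically requires in vivo.

## Numerical and design notes

- **Degenerate inputs** error early with named diagnostics: non-intersecting
  lens caps, pupils wider than the lens, collinear iris points, all-removed
  traces, missing anterior cornea, out-of-order correction, incomplete
  grids passed to the morphometry.
- **Artifact rejection** defaults to polynomial order 4 (captures corneal
  sagitta across 14 mm without chasing spikes) with the 3-SD threshold and
  at most 10 passes, the SD recomputed after every pass. Heavily
  contaminated traces can mask moderate spikes at 3 SD — an inherent
  property of the rule, visible in the tests, not a bug to engineer away.
- **Manual densification** uses a C2 cubic spline with FMM end conditions.
  A shape-preserving monotone cubic was considered and rejected: its
  limiter costs an order of accuracy exactly at curvature extrema (the
  surface apex), where it matters most; overshoot of the plain spline
  between smooth anatomical clicks is bounded by the interpolation error.
- **Determinism**: all randomness (simulation noise, training draws) flows
  through explicit seeds; identical seeds give byte-identical acquisition
  files.
- **Problem sizes**: the full protocol is 8 incidences x 65 meridians x
  256 A-scans; the test suite exercises the complete pipeline at this size
  once and uses a coarser 33 x 128 protocol for structural tests, with
  training populations of 12–80 lenses depending on what the test probes.

## Known limitations

The pipeline assumes rigid eye motion between acquisitions (no
accommodation drift or cyclotorsion), a constant lens index, telecentric
scanning (a fan-beam flag exists in the simulator's design space but the
correction chain assumes parallel A-scan rays), and a star-convex lens
about its centre. The eigenlens basis is synthetic: absolute coefficient
values are not comparable to bases trained on ex vivo populations, though
the algebra and the completion behaviour are identical. Registration
accuracy degrades if fewer than about three well-separated gaze directions
are available, since the equatorial band then constrains the projection
only weakly.
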