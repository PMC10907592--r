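---
title: "Modelling the cornea as a curved biaxial birefringent shell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cornea as a curved biaxial birefringent shell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneabiref)
```

## The model

The corneal stroma is a stack of collagen lamellae whose aggregate optical
effect is that of a linear birefringent medium. `corneabiref` represents the
whole cornea as a *single* anisotropic layer bounded by two aspheric surfaces
of revolution, with three principal refractive indices $(n_x, n_y, n_z)$
attached to a local frame at every point: the local $x$ axis is the surface
normal, and the two transverse axes are the projections of the global
horizontal and vertical directions onto the tangent plane. In this frame the
(optical-frequency) permittivity tensor is diagonal,
$\varepsilon = \mathrm{diag}(n_x^2, n_y^2, n_z^2)$.

For a plane wave with unit wave normal $\hat s = (s_x, s_y, s_z)$ the two
admissible refractive indices solve the wave-normal biquadratic

$$ n^4 - p\,n^2 + q = 0, \qquad
p = \frac{\sum_i s_i^2 \varepsilon_i (\varepsilon_j + \varepsilon_k)}
         {\sum_i s_i^2 \varepsilon_i}, \qquad
q = \frac{\varepsilon_x \varepsilon_y \varepsilon_z}
         {\sum_i s_i^2 \varepsilon_i}, $$

with $(i, j, k)$ cyclic. The birefringence is
$\Delta n(\hat s) = n_\text{slow} - n_\text{fast}$. When all three principal
indices differ the medium is biaxial: there are exactly two wave normals —
the binormal (optic) axes — along which $\Delta n = 0$. They lie in the plane
spanned by the principal axes of the smallest and largest index, at an angle
$V$ from the largest-index axis with

$$ \cos^2 V = \frac{n_\text{mid}^{-2} - n_\text{max}^{-2}}
                   {n_\text{min}^{-2} - n_\text{max}^{-2}} . $$

`binormal_axes()` reports the *acute* angle $\beta$ between the two axis
lines together with the bisecting principal axis. For the central index
column $(1.3764, 1.3776, 1.3775)$ this gives $\beta = 33.54°$ bisected by
the surface normal (the axes straddle the normal in the normal–horizontal
plane); for the peripheral column $(1.3770, 1.3776, 1.3765)$,
$\beta = 84.82°$ with both axes in the corneal (tangent) plane, bisected by
the horizontal axis. In-vivo polarimetry of human corneas reports a central
binormal angle of about 35° and a paracentral/peripheral angle of about
83.7°; the closed-form values for the printed index columns land within
1.5° of those figures, and the acute-angle convention is what makes the
central value comparable (the raw opening between the axis vectors about
the largest-index axis is its supplement).

### Radial index blending

The indices change smoothly from the central to the peripheral column with a
weight given by the complementary standard-normal CDF of the normalized
radius $r/r_0$ ($r_0 = 6$ mm, half the corneal diameter):

$$ P(r) = 1 - \Phi\!\left(\frac{r/r_0 - \mu}{\sigma}\right), \qquad
n_i(r) = P(r)\, n_{i,\text{central}} + (1 - P(r))\, n_{i,\text{peripheral}},$$

with $\mu = 0.45$ and $\sigma = 0.1$, so the transition is centred at
2.7 mm and essentially complete within $\pm 1.2$ mm of it. A CDF-shaped
weight is the only monotone reading of a "normal-distribution" transition
that runs from 1 at the apex to 0 at the limbus; a density-shaped weight
would be non-monotone and make the apex peripheral. Radii beyond $r_0$
clamp to the peripheral column, keeping the blend a convex combination.
Along the way the order of the indices flips once, from
$n_x < n_z < n_y$ centrally to $n_z < n_x < n_y$ peripherally; near the
crossing radius ($\approx 3$ mm) the medium passes through a uniaxial state.
The mean of the three blended indices is *not* exactly the bulk value
1.3777 used for refraction: the two columns have means 1.377167 and
1.377033, so the mean drifts by about $1.3\times10^{-4}$ across the disc.
The columns are used verbatim; no renormalization is applied.

### Geometry and ray tracing

The shell is bounded by two conicoids $x = h^2 / \big(R\,(1 +
\sqrt{1 - (1+k)h^2/R^2})\big)$ with the published eye-model constants
(anterior $R_1 = 7.76$ mm, $k_1 = -0.10$; posterior $R_2 = 6.52$ mm,
$k_2 = -0.30$; central thickness 0.55 mm; diameter 12 mm). Two light-source
models are provided. The default places a point source on axis 650 mm in
front of the cornea — effectively a plane wave; each ray refracts at the
anterior surface by the vector Snell law with the mean bulk index 1.3777 and
then runs straight to the posterior surface (the cornea–aqueous refraction
is an order of magnitude weaker and is neglected). The alternative
`iris_plane` source represents light scattered from the iris, 3.5 mm behind
the anterior vertex; those rays enter the posterior surface without
refraction (the corneal and aqueous indices nearly match) and traverse to
the anterior surface.

A ray is *not* split into its two eigenwaves geometrically: the fast/slow
distinction enters only through the two wave indices. For a ray with entry
point $A$ and exit point $B$ the retardation of one traversal is

$$ R = \overline{\Delta n}\, d, \qquad
\overline{\Delta n} = \tfrac12 (\Delta n_A + \Delta n_B), \qquad
d = |B - A|, $$

where $\Delta n_A$ and $\Delta n_B$ evaluate the same inside direction in
the local frames of the two surfaces, with indices taken at each point's
radial height (the abscissa used for the registration maps). The phase
difference at wavelength $\lambda$ is $\delta = 360° \cdot R/\lambda$, with
$\lambda = 660$ nm by default. The on-axis ray gives the model's anchor
values: $d = 0.55$ mm, $\Delta n = |n_y - n_z| = 10^{-4}$ centrally, hence
$R = 55$ nm and $\delta = 30°$. A `double_pass` flag doubles $R$ for
comparison with reflective instruments; the default is single-pass, which
matches the ~800 nm limbal retardation scale the maps produce.

Maps are computed on a regular $Y$–$Z$ grid over the 12 mm disc (default
$301 \times 301$; grid sizes are forced odd so the apex is an exact sample)
by tracing one ray per cell; meridional profiles are evaluated with
dedicated rays at 0.02 mm steps rather than by grid interpolation. The
azimuth map reports the orientation of the slow transverse eigenpolarization
($D$ field) at the entry surface, projected on the registration plane, in
$[0°, 180°)$ with 0° horizontal.

## What the simulated maps do and do not show

The generator's defaults *are* the published corneal model: all inputs are
printed constants and the simulation is deterministic — there is no sampling
noise, and identical configurations yield byte-identical artifacts. The maps
therefore demonstrate the mechanism of the model, not inter-subject
variability. Known deliberate omissions: nasal–temporal asymmetry (the model
is rotationally symmetric by construction), stress birefringence from
extraocular muscle tension, wavelength dispersion (monochromatic 660 nm;
white-light isochrome colours are out of scope), retinal reflection, and
depth-resolved stromal structure (a single equivalent layer).

Two model behaviours deserve explicit mention because they differ from
qualitative expectations one might bring to the maps:

* **Resultant minima separation.** The central-regime component has its
  retardation minima where the refracted ray aligns with the tilted binormal
  axes, at $\pm 2.6$ mm on the horizontal meridian. In the blended model the
  peripheral regime — whose in-plane index split of $1.1\times10^{-3}$
  produces ~600 nm of retardation even at normal incidence — begins to
  contribute well inside the transition radius, and the resultant minima
  move inward to $\pm 1.2$ mm (separation 2.41 mm, computed by
  `profile_metrics()`). A separation of ~4 mm would require the transition
  centred near $\mu \approx 0.6$ instead of 0.45; the package keeps the
  stated parameters. The birefringence profile, by contrast, peaks at
  4.16 mm from the centre, in line with the reported ~4 mm.
* **Azimuth radiality.** The often-described radial appearance of the
  corneal azimuth is the projection of the tilted local frames, and it is
  exact here when the two in-plane indices are equal (the distinct fast axis
  is the surface normal, so the slow axis is tangential and the azimuth
  equals the polar angle mod 90°). With the peripheral column's in-plane
  split, however, the transverse eigen-axes lock to the horizontal/vertical
  directions near the diagonals, so the blended azimuth map is radial on the
  meridians but Cartesian in between.

Similarly, the two source models agree on the minima separation to 0.18 mm,
but their pointwise retardation differs by ~14% RMS over the central 8 mm:
the 3.5 mm iris-plane point source is strongly divergent, so its inside-ray
directions deviate from the collimated external case by tens of degrees
toward the periphery.

## Numerical choices

* **Root splitting near the optic axes.** The textbook discriminant
  $p^2 - 4q$ cancels to rounding noise ($\sim 10^{-14}$ absolute, i.e.
  $\Delta n$ noise $\sim 5\times10^{-8}$) near a binormal axis. The solver
  instead uses the exact factored identity
  $1/n_\text{fast}^2 - 1/n_\text{slow}^2 = (\varepsilon_\text{min}^{-1} -
  \varepsilon_\text{max}^{-1}) \sin\theta_1 \sin\theta_2$, with $\theta_{1,2}$
  the angles between $\hat s$ and the two optic axes, together with the
  projected-operator trace for the sum of the reciprocal squares. Both parts
  are cancellation-free, the discriminant is nonnegative by construction
  (no clamping needed), and the returned roots satisfy the biquadratic to
  $\sim 10^{-15}$. $\Delta n$ along a returned binormal axis evaluates below
  $10^{-12}$.
* **Axis search.** The binormal axes are found by a 1° scan of the min–max
  principal plane (they provably lie there for an orthorhombic medium)
  followed by Brent refinement to $10^{-10}$ degrees, and cross-checked in
  the tests against the closed-form $\cos^2 V$ expression to 0.1°. Two
  indices equal within $10^{-12}$ switch to the uniaxial branch; an
  isotropic medium is rejected.
* **Ray–conicoid intersection.** Closed-form quadratic with the numerically
  stable root form $q = -(B + \mathrm{sign}(B)\sqrt{B^2-4AC})/2$ — a 650 mm
  origin would otherwise cost ~$10^{-10}$ mm of cancellation. Surface
  membership is tested at $10^{-9}$ mm, far below geometric relevance but
  well above double-precision noise.
* **Eigenpolarization.** The azimuth uses the eigenvector of the
  2×2 inverse-permittivity form restricted to the plane transverse to
  $\hat s$, choosing the better-conditioned component expression; degenerate
  cells ($\Delta n$ below $10^{-14}$) report `NA` (azimuth indeterminate).
* **Profile metrics.** Interior extrema are located by three-point
  comparison with parabolic sub-sample refinement; the reported separation
  pairs the two interior minima most symmetric about the apex. Monotone
  profiles report `minima-not-found` rather than failing.
* **Problem sizes.** Production maps default to $301 \times 301$ cells
  (sub-second on one core); the test suite uses 41–61 cell grids and 0.02 mm
  meridional sampling, which resolves the reported metrics to ±0.02 mm.

## The six-state measurement model

The experimental azimuth/phase maps this model is compared against come from
a six-state polarimeter (four linear probes at 0°, 45°, 90°, 135° and two
circular). The package simulates the simplified single-pass version: each
state is generated, passed through the linear retarder
$M(\theta, \delta)$, and analyzed with the same state. Those six intensities
determine only $\cos 4\theta$ and $\cos\delta$, so `six_state_roundtrip()`
returns the equivalence-class representative with $\theta \in [0°, 45°]$
and $\delta \in [0°, 180°]$, which reproduces the six intensities exactly.
An instrument whose data reduction also wraps $\delta$ into $[0°, 90°)$ is
using additional phase information (e.g. a double-pass geometry) that this
simplified forward model does not carry; the wrap implemented here is the
one its own intensities support. A crossed circular polariscope image is
simulated as $I = \sin^2(\delta/2)$, azimuth-independent, so its level sets
are the isochromes.

## Reproducibility

Every quantity in `summary.json` — the two binormal angles, the
minima separation, the birefringence peak radius and the maximum
retardation — is recomputed from the configuration at run time;
`scripts/acceptance.R` does the same from a fresh session. The pipeline is
deterministic: the only stochastic elements anywhere are the random media
used by the property tests, which are seeded.
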