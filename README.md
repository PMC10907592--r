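# corneabiref

The human cornea behaves like a curved, weakly birefringent crystal plate:
viewed between polarizers it shows dark isogyres and concentric isochromes,
and polarimeters measure a retardation that is minimal near the apex and
grows toward the limbus. `corneabiref` is a forward model of that behaviour
for people working in ocular biophysics and polarimetric imaging. It treats
the cornea as a single biaxial linear birefringent layer between two
aspheric surfaces, with principal refractive indices that blend smoothly
from a central to a peripheral regime, and produces retardation,
birefringence, phase-difference and azimuth maps over the corneal disc,
binormal (optic) axis directions, and simulated circular-polariscope
images.

## The model in brief

At every surface point a local frame carries the principal indices
(n_x, n_y, n_z): x is the surface normal, y and z the projected horizontal
and vertical directions. For a wave normal ŝ the two wave indices solve the
anisotropic wave-normal biquadratic

    n⁴ − p n² + q = 0,
    p = Σᵢ sᵢ² εᵢ (εⱼ + εₖ) / Σᵢ sᵢ² εᵢ,   q = εx εy εz / Σᵢ sᵢ² εᵢ,

with εᵢ = nᵢ², and the birefringence is Δn = n_slow − n_fast. A biaxial
medium has two zero-Δn propagation directions (the binormal axes) in the
plane of the smallest and largest principal index, at

    cos²V = (n_mid⁻² − n_max⁻²) / (n_min⁻² − n_max⁻²)

from the largest-index axis. The indices blend radially with a
complementary normal-CDF weight P(r) = 1 − Φ((r/6 mm − 0.45)/0.1), rays
from a 650 mm on-axis point source refract at the anterior conicoid
(R₁ = 7.76 mm, k₁ = −0.10) via the vector Snell law with bulk index 1.3777,
run straight to the posterior conicoid (R₂ = 6.52 mm, k₂ = −0.30), and each
ray reports R = ½(Δn_A + Δn_B)·|B − A| and δ = 360°·R/λ at λ = 660 nm.
The methods vignette (`vignettes/corneal-birefringence.Rmd`) derives all of
this and records the numerical choices.

## Worked example

```r
library(corneabiref)

# binormal axes of the central-cornea index column
binormal_axes(principal_indices(1.3764, 1.3776, 1.3775))
#> binormal axes: beta = 33.5366 deg, bisectrix = x, plane = x-y
#>   axis 1: (+0.957479, +0.288502, +0.000000)
#>   axis 2: (+0.957479, -0.288502, +0.000000)

# the on-axis ray through the shell, pure central regime
shell <- corneal_shell()
path  <- trace_ray(light_source("external"), c(0, 0), shell)
ray_retardation(path, index_profile(), shell, regime = "central")
#> retardation sample: R = 55.000 nm, delta = 30.000 deg, d = 0.5500 mm
#>   dn_A = 0.0001, dn_B = 0.0001, mean = 0.0001, azimuth = 0.00 deg

# full default run: maps, profiles, isochromes image, summary
summary <- run_simulation(run_config(output_dir = "run"), quiet = TRUE)
str(summary)
#> List of 7
#>  $ beta_central_deg             : num 33.5
#>  $ beta_peripheral_deg          : num 84.8
#>  $ minima_separation_mm         : num 2.41
#>  $ minima_positions_mm          : num [1:2] -1.2 1.2
#>  $ birefringence_max_position_mm: num 4.16
#>  $ retardation_max_nm           : num 813
#>  $ metrics_status               : chr "ok"
```

Reading the numbers: the central medium's optic axes straddle the surface
normal at an acute 33.5°, and the peripheral medium's axes lie in the
corneal plane 84.8° apart — the biaxial structure flips from
normal-straddling to in-plane across the blend. The axial ray accumulates
55 nm of retardation (30° of phase at 660 nm) from the 10⁻⁴ central index
split over 0.55 mm. The blended model's horizontal retardation profile has
two shallow interior minima at ±1.2 mm, its birefringence peaks 4.16 mm
from the centre, and the limbal retardation reaches ~810 nm — the same
scale polarimetric measurements report. The vignette discusses why the
minima sit closer to the apex than the peripheral birefringence peak.

A thin command-line front end is installed with the package
(`system.file("cli", "corneasim", package = "corneabiref")`) with
subcommands `simulate`, `axes`, `sphere`, `profile`, `render` and `wrap`.

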