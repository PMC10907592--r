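Package: corneabiref
Title: The Human Cornea as a Curved Biaxial Birefringent Shell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward model of corneal birefringence. The cornea is treated as
    a single anisotropic layer between two aspheric surfaces of revolution,
    with principal refractive indices blending smoothly from a central to a
    peripheral regime. Rays from a point source are traced through the shell,
    the anisotropic wave-normal (biquadratic) equation is solved at entry and
    exit, and retardation, birefringence, phase-difference and azimuth maps
    are produced over the corneal disc, together with binormal (optic) axis
    directions and simulated circular-polariscope images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
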