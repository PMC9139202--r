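Package: aneuflow
Title: Volume-Penalized Hemodynamics and Microfluidic Shear Design for
    Aneurysm-on-a-Chip Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline linking intracranial-aneurysm
    hemodynamics to microfluidic endothelial-culture conditions. Generates
    parametric vessel and sidewall-aneurysm occupancy masks on uniform
    Cartesian grids (or voxelizes watertight STL surfaces), solves the
    incompressible Navier-Stokes equations with a Brinkman volume-penalization
    immersed boundary on a staggered (MAC) grid with a pressure-projection
    fractional step, extracts wall shear stress on the immersed boundary,
    identifies low- and high-shear wall sites, and converts their shear-stress
    values into parallel-plate microfluidic channel operating points (shear
    rate and volumetric flow rate) for organ-on-chip perfusion experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
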