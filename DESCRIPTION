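Package: nematicdefects
Title: Kinematics of Half-Integer Defects in Active Nematic Films with
    Spatially Varying Activity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the hydrodynamic kinematics of isolated +1/2 and -1/2
    topological defects in two-dimensional active nematic films on a
    substrate, when the activity varies in space.  Builds quasi-static
    Q-tensor defect textures and the active force fields they induce under
    uniform, linear-gradient and sharp-step (active/passive interface)
    activity profiles; evaluates defect self-propulsion velocities and core
    vorticities as screened-Stokes Green's function (Bessel K0 kernel)
    integrals, including the closed-form gradient torque and the four
    interface profile functions; provides friction-limit vorticity maps with
    vortex-multiplet counting, a stream-function/vorticity solver for the
    screened Stokes flow in a no-slip disc, and ODE integration of the
    vorticity-driven defect polarization and wall-distance dynamics with
    fixed-point classification.  Fields, curves and kinematic reports are
    written as CSV, legacy VTK and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
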