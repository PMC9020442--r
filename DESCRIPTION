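Package: chromocool
Title: Heating and Cooling Kinetics of Photoexcited Chromophores
Version: 0.1.0
Authors@R:
    person("chromocool", "maintainers", email = "maintainers@chromocool.org",
           role = c("aut", "cre"))
Description: Analytical energy-transfer model for the heating of a
    photoexcited chromophore by internal conversion and its subsequent
    cooling by heat transfer to the solvent. Given ensemble-averaged
    observables from nonadiabatic molecular dynamics (ground-state
    population and solute/solvent mean kinetic energies versus time),
    the package fits a multi-exponential pathway model under physical
    boundary conditions to extract the heating time (mean excited-state
    lifetime) and the cooling time constant. Includes a closed-form
    solution of the driven Newton-cooling equation, a numerical
    integrator used as an independent oracle, a synthetic
    surface-hopping-ensemble generator for validation, delimited-file
    readers/writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
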