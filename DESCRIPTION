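Package: aucsas
Title: Decomposition of Small-Angle Scattering Profiles with Analytical Ultracentrifugation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts single-component scattering profiles from small-angle
    X-ray or neutron scattering (SAXS/SANS) measurements of multi-component
    solutions, using component concentrations measured by analytical
    ultracentrifugation (AUC). Recovers the monomer profile from a solution
    contaminated by trace homo-oligomeric aggregates (via the forward-intensity
    fraction, Debye-model oligomer form factors, and a Guinier-anchored
    low-angle reconstruction with iterative extended-Guinier refinement), and
    the complex profile of an A + B <-> AB association-dissociation equilibrium
    (via sedimentation-equilibrium global fitting of the dissociation constant
    across rotor speeds and loading concentrations, mass-action concentrations,
    and subtraction decomposition). Includes synthetic generators for all input
    classes with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
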