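Package: tbinflam
Title: ODE Modeling of Acute Neuroinflammation After Severe Traumatic
    Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and fits a seven-state ordinary differential
    equation model of the acute (0-5 day) neuroinflammatory response to
    severe traumatic brain injury: M1- and M2-like microglia, the
    cytokines IL-1beta, IL-12, IL-10 and IL-4 measured in cerebrospinal
    fluid, and a qualitative secondary tissue damage variable. Provides
    moving-average binning of sparse longitudinal cytokine series,
    penalized Nelder-Mead estimation of the 45 rate/shape parameters and
    7 initial conditions, perturbed-restart ensembles of model fits,
    Bhattacharyya overlap/distance comparison of per-cluster parameter
    distributions with a normalized local sensitivity gate, and a
    synthetic cohort generator with three cluster archetypes for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
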