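Package: cecglead
Title: Capacitive ECG Lead Selection by Forward Modeling of the Thorax
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for selecting an optimal capacitive (non-contact) ECG
    lead on the back of a seated subject.  Solves the quasi-static forward
    electrocardiography problem on a synthetic multi-compartment thorax
    with a finite-element method, models the capacitive electrode as a
    coupling-capacitance-weighted surface average with motion-artifact
    sensitivities for gap and slide displacements, searches electrode-pair
    placements maximizing the R-wave lead voltage while penalizing
    tangential-field susceptibility, synthesizes capacitive ECG traces with
    noise and electrode-motion artifacts, and scores Pan-Tompkins QRS
    detection against ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
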