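Package: bcglut
Title: Kinetic Modelling of Glucose Transport and Phosphorylation in
    Pancreatic Beta Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of glucose entry into the human
    pancreatic beta cell and its phosphorylation by glucokinase.  Implements
    a reduced model of bidirectional facilitated diffusion through the
    GLUT-1 and GLUT-2 transporters (Michaelis-Menten) coupled to Hill-type
    glucokinase phosphorylation, a steady-state metabolic-threshold
    ("tipping point") analysis over transporter expression levels, a
    regulatory-network model of transporter expression (HNF1A/FOXA2
    transcription factors, promoter acetylation, GNT-4A-dependent
    N-glycosylation and lectin-mediated membrane residency), an algebraic
    calibration that reconstructs maximum rates from printed steady-state
    anchors, local sensitivity analysis of the glucokinase rate with
    respect to RNA abundances, and a synthetic glucose-uptake data
    generator with an expression-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
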