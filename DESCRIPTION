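Package: gidigest
Title: Reduced-Order Multiphase Simulation of Digestion in the Antroduodenal Tract
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quasi-1D finite-volume simulator of multiphase digestion in the
    antroduodenal portion of the gastrointestinal tract. The first phase is a
    ten-component fluid (water, hydrochloric acid, sodium bicarbonate, their
    reaction product, dissolved proteins, fats, carbohydrates, a trace chemical,
    pepsin and polypeptides); food particles are represented as five fixed-size
    bins that dissolve into the fluid under acid and cascade toward smaller
    sizes. The model couples acid, pepsin and bicarbonate secretion with
    Michaelis-Menten feedback, pH-modulated pepsin proteolysis, acid-bicarbonate
    neutralization, chemical absorption through the wall, drift-flux particle
    sedimentation with a Reynolds-corrected Stokes drag, peristaltic wall motion
    and periodic pyloric gating. Six functional-disorder scenarios (reduced acid
    or alkaline secretion, lowered particle density) are built in, together with
    a well-mixed batch-reactor mode, a command-line runner and plain-text
    configuration and geometry files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    yaml,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
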