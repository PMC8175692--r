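Package: condsim
Title: Event-Driven Simulation of the Human Cardiac Conduction System
Version: 0.1.0
Authors@R:
    person("Open", "Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic discrete-event simulator for a modular model of
    the human cardiac conduction system. The model chains three physiological
    components -- a refractory gate for the sinoatrial node, an escape
    pacemaker for the atrioventricular (AV) node, and a recovery-dependent AV
    conduction delay -- behind a small synchronous event kernel with
    zero-delay propagation and pre-event state semantics. The package also
    provides an extension with a ventricular refractory gate and a trigger
    input for premature ventricular contractions (PVCs), a scheduling-based
    monolithic reference implementation used as an equivalence oracle,
    stimulus-protocol generators (including an interval-switching sinus
    drive), interbeat-interval analysis, CSV trace input/output, a
    command-line interface, and DOT export of model wiring diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
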