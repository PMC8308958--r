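Package: rotapress
Title: Agent-Based Simulation of Rotary Tablet Press Direct Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven, agent-based simulation of a rotary tablet press for
    direct compression of two-component powder blends. Models material flow from
    the hopper through a plug-flow filling pipe (fast midstream plus outer ring)
    and a twelve-compartment feed frame acting as a cascade of continuous
    stirred tank reactors, into the dies. Per-tablet critical quality attributes
    (weight, composition with lot-level provenance, out-die porosity, tensile
    strength) are predicted from Kawakita compressibility with volume-additive
    mixing, a two-point elastic-recovery model, and the Ryshkewitch-Duckworth
    porosity-strength relation. Includes calibration routines for all
    sub-models, sensitivity sweeps over structural press parameters, a bundled
    dicalcium-phosphate material-changeover case study, and synthetic fixture
    generators for compaction datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
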