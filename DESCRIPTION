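Package: vsgating
Title: Voltage-Sensor Gating Analysis with Backbone-Ester Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for voltage-clamp studies of voltage-sensor
    gating in Shaker-type potassium channels, with explicit support for
    backbone amide-to-ester (alpha-hydroxy acid) substitutions. Simulates
    two-electrode voltage-clamp sweep families from Markov gating models
    with linear capacitance, leak and noise artifacts; performs P/N leak
    subtraction, tail- and chord-based conductance-voltage (G-V) analysis
    with Boltzmann fits and gating-perturbation free energies (delta-delta-G);
    isolates nonlinear gating charge from OFF-transient integration with
    linear-capacitance regression and fits double-Boltzmann Q-V curves;
    fits single-exponential deactivation kinetics; and classifies
    per-residue alpha/3-10/pi helical content from backbone hydrogen-bond
    patterns in multi-model PDB trajectories, including lost-donor ester
    semantics.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
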