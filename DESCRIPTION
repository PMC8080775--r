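Package: opticomb
Title: Comb-Based Analysis of Cardiac Optical Mapping Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated, script-driven analysis of cardiac optical mapping
    recordings (membrane potential or intracellular calcium movies). Detects
    action potentials and calcium transients with a comb algorithm that
    exploits the known pacing pattern, segments each pixel trace into single
    activations, and extracts per-beat baseline, amplitude, duration at a
    configurable recovery level, recovery time and activation time, yielding
    spatial feature maps synchronised by a global recording clock. Includes
    conduction-velocity estimation (point-to-point and local polynomial
    gradient vector fields), alternans mapping (large-to-small and symmetric
    ratio metrics), S1-S2 protocol support through custom combs, hybrid
    substack averaging, a synthetic fixture generator with exact ground
    truth, and a batch runner for whole experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    tiff,
    png,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'batch.R'
    'comb.R'
    'io.R'
    'opticomb-package.R'
    'postprocess.R'
    'recording.R'
    'synthetic.R'
    'trace.R'
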