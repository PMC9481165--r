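Package: mvcnet
Title: Connectome-Constrained Convolutional Network Models of Mouse Visual Cortex
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compiles quantitative mouse-brain anatomy (laminar excitatory
    neuron censuses, interlaminar connection statistics, and a voxel-level
    interareal connectome) into a fully specified sparse convolutional
    network with Gaussian-masked connections. Includes a flat-mapping
    pipeline for estimating interareal connection geometry from voxel
    connectomes, a pure-R masked-convolution runtime with a toy training
    harness, representational-similarity metrics (similarity of similarity
    matrices, split-half reliability and noise ceilings, lifetime
    sparseness, circular selectivity, Jensen-Shannon distances, MDS layout
    diversity), and synthetic data generators with known ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
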