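Package: larvaInject
Title: Decision Stack of an Automated Zebrafish-Larva Microinjection Robot
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hardware-free implementation of the image-analysis and
    decision-making pipeline of an automated microinjection robot for
    2-dpf zebrafish larvae. Provides tiled U-Net-style segmentation
    inference machinery (304-px tiles with 50-px overlap, nearest-center
    stitching, six-transform test-time-augmentation consensus, annotation
    overlap resolution), landmark-based skewed coordinate frames and
    site-specific needle targeting (duct of Cuvier, perivitelline space,
    hindbrain ventricle), frame-difference blood-flow mapping,
    variance-of-Laplacian autofocus with touchdown detection, anchor-point
    puncture detection, droplet volume calibration, and a macro-driven
    injection-session simulator with bookkeeping statistics. All inputs can
    be produced by a built-in synthetic fixture generator with exact ground
    truth, so the full pipeline is testable end to end without instrument
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'fixtures.R'
    'segmentation.R'
    'targeting.R'
    'bloodflow.R'
    'focus.R'
    'puncture.R'
    'droplet.R'
    'macro.R'
    'session.R'
    'io.R'
    'pipeline.R'
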