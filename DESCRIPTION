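Package: squareT1
Title: Surface Quadrupolar Relaxation T1 Mapping for Hyperpolarized 83Kr Lung MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for surface quadrupolar
    relaxation (SQUARE) contrast in hyperpolarized 83Kr lung MRI. Provides a
    digital lung phantom whose T1 field encodes surface-to-volume ratio, a
    variable-flip-angle FLASH acquisition simulator producing T1-weighted
    delay-series k-space frames, magnitude-image reconstruction (sine-bell
    squared apodization, centred zero filling, unitary Fourier transform),
    pixel-wise mono-exponential T1 mapping with physical-range and
    region-of-interest filters, bimodal Gaussian decomposition of T1
    histograms into fast (alveolar) and slow (airway) modes, and group-level
    comparison of the resulting biomarkers between control and
    elastase-treated lungs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    EBImage,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, MagneticResonanceImaging, Visualization, Pulmonology
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'fft-utils.R'
    'phantom.R'
    'recon.R'
    't1map.R'
    'histogram.R'
    'groupstats.R'
    'io.R'
    'pipeline.R'
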