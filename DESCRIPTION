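Package: secsaxstda
Title: Automated SEC-SAXS and Triple-Detector-Array Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated processing of size-exclusion-chromatography-coupled
    small-angle X-ray scattering (SEC-SAXS) runs acquired in parallel with a
    triple detector array (right-angle light scattering, refractive index and
    UV absorbance). Provides per-frame normalization, buffer-frame
    identification and background subtraction, automatic Guinier analysis
    (Rg and I(0) traces), detector calibration against a protein standard,
    refractive-index-based concentration and light-scattering molecular
    weights, column-calibration molecular weights, concentration-normalized
    component scattering curves with a three-way molecular-weight consistency
    check, and constrained mixture decomposition of scattering curves into
    oligomeric volume fractions. Includes a synthetic-run simulator with
    known ground truth so every stage is testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'scattering-curve.R'
    'io-dat.R'
    'io-chromatogram.R'
    'io-manifest.R'
    'simulate.R'
    'frames.R'
    'guinier.R'
    'tda.R'
    'correlate.R'
    'mixtures.R'
    'pipeline.R'
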