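Package: qsmdgm
Title: Quantitative Susceptibility Mapping of Deep Grey Matter with a
    Permutation-Tested Regression Battery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates dipole-physics susceptibility phantoms and multi-echo
    complex gradient-echo signals, reconstructs quantitative susceptibility
    maps (QSM) by multi-echo complex total field inversion (mTFI) with
    gradient-weighted total-variation regularization, extracts deep grey
    matter region metrics (CSF-referenced susceptibility means, head-size
    normalized volumes, lesion-filtered total lesion volume), and runs the
    associated cross-sectional and longitudinal multiple-regression batteries
    with Freedman-Lane permutation inference and outcome-grouped false
    discovery rate correction on simulated patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
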