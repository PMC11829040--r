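Package: hydramass
Title: Hydrazine Reactivity Mass Spectrometry Toolkit for RNA Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for aniline-free hydrazine probing of RNA modifications by
    mass spectrometry. Provides exact-mass arithmetic on elemental
    compositions, a registry of canonical and modified ribonucleosides with
    their hydrazine reaction products and dose-response reactivities,
    in-silico RNase T1 digestion of bracket-annotated RNA sequences,
    conversion-ladder prediction and peak matching for pseudouridine/uridine
    discrimination by MALDI or high-resolution MS, calibration-based absolute
    nucleoside quantification with guanosine normalization, conversion-yield
    and log-logistic dose-response fitting, and seeded simulators that
    generate every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
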