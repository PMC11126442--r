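Package: periomri
Title: Longitudinal MRI Quantification of Periodontal Bone-Marrow Edema
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify bone-marrow edema of the alveolar ridge from
    paired (baseline and follow-up) magnetic resonance images. Provides a
    ground-truthed synthetic phantom and clinical-site simulator, rigid
    co-registration of follow-up volumes into the baseline frame, voxelwise
    edema classification at a configurable multiple of the reference-marrow
    standard deviation (default > 2 SD), subtraction-style change maps with
    per-quadrant volumetry in cubic millimetres, apical-coronal edema-depth
    measurement at the six probing sites of each tooth, and the nonparametric
    site-level statistics (median [IQR] summaries, paired Wilcoxon,
    Mann-Whitney, Pearson chi-square with Yates correction) used to tabulate
    probing pocket depth, bleeding on probing, and edema depth before and
    after periodontal treatment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
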