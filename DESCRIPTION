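Package: numerotune
Title: Numerosity Tuning Analysis for Block-Design and Sweep fMRI Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying numerosity-tuned neural populations with
    functional MRI. Generates controlled dot-array stimuli and the two
    standard experimental timelines (a 1-7 dot sweep localizer and a
    six-category natural-image block design), simulates multi-subject BOLD
    datasets with known ground-truth voxel populations, estimates
    log-Gaussian numerosity population receptive fields (pRFs) from sweep
    runs, fits block-design general linear models with a scenery-based
    voxel exclusion rule, and performs ROI-level nonparametric inference
    (exact one-sided Wilcoxon signed-rank tests with Benjamini-Hochberg
    false-discovery-rate correction). Includes radially averaged
    amplitude-spectrum quality control for 1/f natural-image statistics
    and a synthetic natural-image fixture generator with object-count
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
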