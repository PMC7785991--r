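Package: zfecg
Title: Simulation and Rhythm Analysis of Adult Zebrafish Surface ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying bradyarrhythmia in the adult zebrafish
    heart from single-lead surface electrocardiograms. Couples a synthetic
    ECG cohort generator (Gaussian-bump waveform morphology over a
    truncated-normal rhythm with Poisson-injected sinus pauses) with
    automated P-wave and QRS detection, interbeat-interval indices,
    Poincare analysis, sinus-arrest episode scoring with derived interval
    cutoffs, and cohort-level comparison statistics. All analysis stages
    accept and return tibbles so pipelines compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    tibble,
    tidyr,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
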