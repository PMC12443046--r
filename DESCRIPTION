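Package: hippovaso
Title: Laminar VASO fMRI Analysis for the Human Hippocampus
Version: 0.1.0
Authors@R:
    person("hippovaso", "developers", email = "hippovaso@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of interleaved nulled/not-nulled
    (SS-SI VASO) laminar fMRI acquisitions of the human hippocampus.
    Provides a synthetic hippocampal phantom with subfield labels,
    corresponding inner/mid/outer surfaces and known laminar response
    amplitudes; demultiplexing of interleaved series, steady-state
    trimming and BOLD-contamination correction by dynamic division;
    temporal SNR and inflow diagnostics; aCompCor nuisance regressors
    from eroded WM/CSF masks; block-design GLM with canonical HRF,
    DCT high-pass and cluster-extent thresholding; and equidistant
    depth-profile extraction across hippocampal subfields with
    math-referenced z-transformation. Minimal NIfTI-1 and GIFTI
    readers/writers are included so the package has no neuroimaging
    dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
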