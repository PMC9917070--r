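Package: baprofiler
Title: Semi-Targeted Bile Acid Profiling for LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-targeted workflow for profiling bile acids in liquid
    chromatography high-resolution mass spectrometry (LC-HRMS) data acquired in
    negative electrospray mode. Features are assigned against a packaged library
    of 46 bile acid standards and 14 deuterated internal standards by accurate
    mass and retention time; isomeric species are tentatively assigned by exact
    mass alone, and phase-II sulfate and glucuronide conjugates are discovered by
    exact-mass arithmetic on the library formulas. MS/MS spectra are classified
    into glycine, taurine, or sulfate conjugate classes via diagnostic product
    ions, internal-standard area ratios are screened for dose-dependent changes
    with a t-test and fold-change rule, and in-vitro S9-incubation metabolites
    are called against no-cofactor controls and cross-matched to plasma features
    by retention time. A synthetic-study generator with planted ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    jsonlite
Config/testthat/edition: 3
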