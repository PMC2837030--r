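Package: ppalign
Title: Profile-Profile Alignment with Position-Dependent Gap Costs and
    Analytical Significance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds position-specific sequence profiles from multiple sequence
    alignments (complexity filtering, reduced-alignment sequence weighting,
    Tatusov pseudocounts, composition adjustment, per-position insertion and
    deletion probabilities), aligns pairs of profiles with a modified
    Smith-Waterman algorithm under position-dependent two-sided gap costs
    derived from score autocorrelation, and assigns E-values combining
    analytical Karlin-Altschul statistics of a global score system with an
    empirically calibrated extreme value distribution for gapped alignment
    scores. Includes a profile database search interface and a synthetic
    alignment generator for calibration and testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
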