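#' Packaged significance reference
#'
#' The default significance reference used when no profile database of the
#' user's own supplies one: the global ungapped parameters and the gapped
#' EVD reference calibrated once on the package's synthetic unrelated-pair
#' set (150 independent families, 120 positions, 30 sequences each; see the
#' methods vignette). The values are synthetic-data calibrations, not
#' derived from any curated structural database; recalibrate with
#' [ppa_calibrate()] for a database of real profiles.
#'
#' @return List with elements `global` (class `ppa_global`) and `evd`
#'   (class `ppa_evd`).
#' @export
ppa_reference <- function() {
  global <- structure(list(
    lambda_u = 0.31761, K_u = 0.10952, H_u = 6.31624,
    lambda_u_raw = 2.69135,
    n_vectors = 18000L, n_positions = 18000L, digits = 4L),
    class = "ppa_global")
  evd <- structure(list(
    lambda_g = 0.34376, mu = 24.9596, K_g = 0.369728,
    fit_threshold = 26.524,
    stderr = c(lambda = 0.0108, mu = 0.1151),
    space_mn = 14400), class = "ppa_evd")
  list(global = global, evd = evd)
}
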