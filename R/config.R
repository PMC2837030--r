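#' Configuration for profile building, scoring, alignment and statistics
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the method's stated values where it states them (`w = omega = 4`,
#' `c_del = 0.6`, entropy downscale factor `0.5`); the remaining knobs carry
#' documented package defaults (see the methods vignette).
#'
#' @param pseudocount_weight Pseudocount weight beta of the Tatusov mixture.
#' @param c_bits Score precision in bits: scores are multiplied by `2^c_bits`
#'   and rounded to integers before the statistical parameter lambda is solved.
#' @param seg_high,seg_low Enable high-/low-complexity column filtering.
#' @param seg_window Window (columns) for the complexity filter.
#' @param trigger_high,extension_high High-complexity trigger/extension
#'   thresholds on normalized column entropy in \[0, 1\].
#' @param trigger_low,extension_low Low-complexity thresholds.
#' @param w Number of row/column maxima kept per position of the score system.
#' @param omega Autocorrelation window over characteristic values.
#' @param c_del Deletion-probability down-weighting constant in the final
#'   gap costs.
#' @param u,v Thickness-adjustment logistic parameters: indel probabilities
#'   are multiplied by `1/(1 + exp(-t*u + v))` where `t` is the effective
#'   number of sequences at the position.
#' @param zeta First-pass gap-limit widening: `z1 = zeta / sqrt(H)`.
#' @param x,y Second-pass widening parameters: `z2 = -y / (log(E) + x)`.
#' @param z_max Clamp for the second-pass `z`.
#' @param downscale_factor Factor applied to scores of low-entropy positions.
#' @param kappa Entropy-threshold proportionality: `tau = kappa / (-log(E))`.
#' @param expected_evalue Pre-set expected E-value per hit driving the
#'   entropy threshold (and disabled when `>= 1`).
#' @param edge_correction Apply effective-length edge correction in E-values.
#' @param evalue_threshold Report cutoff for searches.
#' @param max_hits Maximum number of reported hits per search.
#' @return A named list of class `ppa_config`.
#' @export
ppa_config <- function(pseudocount_weight = 10,
                       c_bits = 7L,
                       seg_high = TRUE, seg_low = FALSE,
                       seg_window = 12L,
                       trigger_high = 0.9, extension_high = 0.85,
                       trigger_low = 0.15, extension_low = 0.2,
                       w = 4L, omega = 4L, c_del = 0.6,
                       u = 1, v = 2,
                       zeta = 1, x = 0, y = 1, z_max = 5,
                       downscale_factor = 0.5, kappa = 1,
                       expected_evalue = 1e-4,
                       edge_correction = TRUE,
                       evalue_threshold = 10, max_hits = 500L) {
  stopifnot(trigger_low <= extension_low, extension_low <= extension_high,
            extension_high <= trigger_high,
            trigger_low >= 0, trigger_high <= 1,
            seg_window >= 1, w >= 1, omega >= 1,
            c_del >= 0, c_del <= 1,
            downscale_factor > 0, downscale_factor <= 1,
            evalue_threshold > 0)
  structure(as.list(environment()), class = "ppa_config")
}

#' @export
print.ppa_config <- function(x, ...) {
  cat("ppa_config:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
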