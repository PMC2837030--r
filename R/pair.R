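#' Raw score matrix for a pair of profiles
#'
#' The score of matching position `i` of the first profile with position
#' `j` of the second is the symmetric cross log-odds: each profile's
#' positional log-odds scores (in reference-lambda units) averaged over the
#' other profile's observed weighted frequencies,
#' `s_ij = (sum_a f_a^(i) s'_ja + sum_a f_a^(j) s_ia) / 2`.
#' Satisfies exchange symmetry `s_ij(P, Q) == s_ji(Q, P)`.
#'
#' @param profile1,profile2 `ppa_profile` objects (composition-adjusted,
#'   as produced by [build_profile()]).
#' @param terms If `TRUE`, also return the two cross terms `A1`
#'   (`sum_a f_a^(i) s'_ja`) and `A2` (`sum_a f_a^(j) s_ia`) needed by the
#'   thickness correction.
#' @return `m x n` score matrix, or a list `scores`, `A1`, `A2`.
#' @export
raw_pair_scores <- function(profile1, profile2, terms = FALSE) {
  if (profile1$m < 1 || profile2$m < 1) stop("zero-length profile")
  A1 <- profile1$f %*% t(profile2$s)
  A2 <- profile1$s %*% t(profile2$f)
  s <- (A1 + A2) / 2
  if (terms) list(scores = s, A1 = A1, A2 = A2) else s
}

#' Thickness correction of pair scores
#'
#' Re-weights the two cross terms of the pair score by the effective
#' numbers of sequences of the contributing positions:
#' `s_ij = (t^(i) A1_ij + t'^(j) A2_ij) / (t^(i) + t'^(j))`,
#' equivalently weights `2t/(t+t')` and `2t'/(t+t')` (whose sum is the
#' range-keeping constant 2) with an overall 1/2. The term built on the
#' thin profile's log-odds and the thick profile's frequencies receives the
#' higher weight; if the first profile comes from a single sequence the
#' surviving term is its log-odds averaged over the second profile's
#' frequencies. When both profiles are single-sequence no correction is
#' applied (`A1`/`A2` are averaged with equal weight), and the statistical
#' parameter must be re-solved on the corrected scores by the caller.
#'
#' @param A1,A2 Cross-term matrices from [raw_pair_scores()].
#' @param eff1,eff2 Per-position effective sequence counts of the two
#'   profiles.
#' @param single1,single2 Are the profiles built from a single sequence?
#' @return Corrected `m x n` score matrix.
#' @export
correct_scores <- function(A1, A2, eff1, eff2,
                           single1 = FALSE, single2 = FALSE) {
  if (single1 && single2) return((A1 + A2) / 2)
  W1 <- outer(eff1, rep(1, length(eff2)))
  W2 <- outer(rep(1, length(eff1)), eff2)
  (W1 * A1 + W2 * A2) / (W1 + W2)
}

#' Down-scale scores of low-entropy positions
#'
#' Positions whose relative entropy falls below the threshold
#' `tau = kappa / (-log(expected_evalue))` carry little information; their
#' rows (first profile) and columns (second profile) are multiplied by
#' `factor` (0.5 by default). The threshold is inversely proportional to
#' `-log E`, so for compositionally similar profiles expected to reach a
#' given E-value the threshold is low. With `expected_evalue >= 1` the
#' threshold is disabled and scores are returned unchanged.
#'
#' @param scores `m x n` score matrix.
#' @param r1,r2 Per-position relative entropies of the two profiles (nats).
#' @param expected_evalue Pre-set expected E-value per hit.
#' @param kappa Proportionality constant of the threshold.
#' @param factor Down-scaling factor.
#' @return Score matrix with affected rows/columns scaled.
#' @export
entropy_downscale <- function(scores, r1, r2, expected_evalue = 1e-4,
                              kappa = 1, factor = 0.5) {
  if (expected_evalue >= 1) return(scores)
  tau <- kappa / (-log(expected_evalue))
  low1 <- r1 < tau; low2 <- r2 < tau
  if (any(low1)) scores[low1, ] <- scores[low1, , drop = FALSE] * factor
  if (any(low2)) scores[, low2] <- scores[, low2, drop = FALSE] * factor
  scores
}

# (re)solve lambda, H (and optionally the costlier K) of a pair system on
# the uniform cell distribution
pair_solve_stats <- function(pair, with_K = TRUE) {
  sc <- as.vector(pair$scores)
  if (with_K) {
    kp <- karlin_params(sc, c_bits = pair$c_bits)
    pair$lambda <- kp$lambda; pair$H <- kp$H; pair$K <- kp$K
  } else {
    pair$lambda <- solve_lambda(sc, c_bits = pair$c_bits)
    pair$H <- entropy_H(sc, lambda = pair$lambda)
  }
  pair
}

#' Construct the score system for a pair of profiles
#'
#' Raw symmetric cross log-odds, thickness correction, entropy
#' down-scaling, and the solved statistical parameters (lambda, H, K) of
#' the resulting score distribution (uniform over all `m x n` cells,
#' discretized at `c_bits` bits). If a global score system is supplied the
#' scores are composition-scaled so the pair's lambda equals the reference
#' `lambda_u`.
#'
#' @param profile1,profile2 `ppa_profile` objects.
#' @param config A [ppa_config()].
#' @param global Optional [ppa_global][build_global_score_system] reference.
#' @return Object of class `ppa_pair_system`: `scores`, `lambda`, `H`, `K`,
#'   `lambda_before` (pre-scaling lambda), the two profiles, `c_bits`.
#' @export
pair_score_system <- function(profile1, profile2, config = ppa_config(),
                              global = NULL) {
  rt <- raw_pair_scores(profile1, profile2, terms = TRUE)
  sc <- correct_scores(rt$A1, rt$A2, profile1$eff, profile2$eff,
                       single1 = profile1$nseq == 1,
                       single2 = profile2$nseq == 1)
  sc <- entropy_downscale(sc, profile1$r, profile2$r,
                          expected_evalue = config$expected_evalue,
                          kappa = config$kappa,
                          factor = config$downscale_factor)
  pair <- structure(list(scores = sc, profile1 = profile1,
                         profile2 = profile2, c_bits = config$c_bits),
                    class = "ppa_pair_system")
  # K is only needed on the final (possibly composition-scaled) system
  pair <- pair_solve_stats(pair, with_K = is.null(global))
  pair$lambda_before <- pair$lambda
  if (!is.null(global)) {
    pair <- composition_scale_pair(pair, global)
    if (is.null(pair$K)) pair <- pair_solve_stats(pair, with_K = TRUE)
  }
  pair
}

#' @export
print.ppa_pair_system <- function(x, ...) {
  cat(sprintf("ppa_pair_system: %d x %d, lambda = %.4f, H = %.4f, K = %.4f\n",
              nrow(x$scores), ncol(x$scores), x$lambda, x$H, x$K))
  invisible(x)
}
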