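#' Top row/column maxima of a score system
#'
#' For each row (`axis = 1`) or column (`axis = 2`) of the score matrix,
#' the `w` largest scores in descending order. Rows with fewer than `w`
#' entries pad by repeating the smallest kept value, so every position has
#' a length-`w` maxima sequence.
#'
#' @param scores `m x n` score matrix.
#' @param axis 1 for per-row maxima (first profile), 2 for per-column.
#' @param w Number of maxima kept.
#' @return Matrix (positions x `w`) of sorted maxima.
#' @export
top_max_scores <- function(scores, axis = 1, w = 4L) {
  if (axis == 2) scores <- t(scores)
  k <- min(w, ncol(scores))
  out <- t(apply(scores, 1, function(row) {
    top <- sort(row, decreasing = TRUE)[seq_len(k)]
    c(top, rep(top[k], w - k))
  }))
  if (w == 1) out <- matrix(out, ncol = 1)
  out
}

# sum over unordered pairs (incl. self-pairs) of clamped multipliers:
# sum_{k<=l} a_k a_l = ((sum a)^2 + sum a^2) / 2
.autocorr_sum <- function(vals, z, clamp = TRUE) {
  a <- vals + z
  if (clamp) a <- pmax(a, 0)
  (sum(a)^2 + sum(a^2)) / 2
}

#' Characteristic values of positional maxima
#'
#' For each position, the autocorrelation of its `w` top maxima — the sum
#' of products over all unordered multiplier pairs (self-pairs included),
#' each multiplier widened by `z` and clamped at 0 — divided by the number
#' of summed products `w(w+1)/2`, square-rooted. With `z = 0` the
#' characteristic value lies within the range of the (non-negative) maxima;
#' a non-positive autocorrelation sum gives 0.
#'
#' @param maxima Matrix (positions x `w`) from [top_max_scores()].
#' @param w Number of maxima per position.
#' @param z Widening term added to each multiplier.
#' @return Numeric vector of per-position characteristic values.
#' @export
characteristic_values <- function(maxima, w = ncol(maxima), z = 0) {
  np <- w * (w + 1) / 2
  apply(maxima, 1, function(row) sqrt(max(0, .autocorr_sum(row, z)) / np))
}

#' Gap cost limits from characteristic values
#'
#' Second-level autocorrelation: for each position, the `omega`
#' characteristic values starting there (indices clamped at the ends) are
#' widened by `z` and autocorrelated over all unordered pairs including
#' self-pairs, normalized by `omega*(omega+1)/2`, and square-rooted. A
#' non-positive window sum yields limit 0. This makes each position's
#' limit depend on the adjacent characteristic values, so stretches of
#' high-scoring (conserved) positions receive high gap cost limits.
#'
#' @param charvals Per-position characteristic values.
#' @param omega Autocorrelation window.
#' @param z Widening term.
#' @return Numeric vector of non-negative per-position limits.
#' @export
gap_cost_limits <- function(charvals, omega = 4L, z = 0) {
  m <- length(charvals)
  np <- omega * (omega + 1) / 2
  vapply(seq_len(m), function(i) {
    idx <- pmin(seq(i, i + omega - 1L), m)
    sqrt(max(0, .autocorr_sum(charvals[idx], z)) / np)
  }, numeric(1))
}

#' First-pass gap-limit widening term
#'
#' `z1 = zeta / sqrt(H)`: inversely proportional to the square root of the
#' pair's relative entropy, so low-information score systems (low H, low
#' scores) get wider gap cost limits.
#'
#' @param H Relative entropy of the pair score system (nats).
#' @param zeta Proportionality constant.
#' @return Scalar `z1 >= 0`.
#' @export
z_first_pass <- function(H, zeta = 1) {
  if (H <= 0) stop("H must be positive")
  zeta / sqrt(H)
}

#' Second-pass gap-limit widening term
#'
#' After the initial alignment and its E-value, `z2 = -y / (log(E) + x)`:
#' small E-values (likely related pair) give small `z`, narrowing the gap
#' cost limits. When `log(E) + x >= 0` (insignificant initial hit) the
#' term is clamped to `z_max`.
#'
#' @param E Initial estimated E-value per hit.
#' @param x,y Adjustable parameters.
#' @param z_max Clamp.
#' @return Scalar `z2` in `[0, z_max]`.
#' @export
z_second_pass <- function(E, x = 0, y = 1, z_max = 5) {
  d <- log(E) + x
  if (d >= 0) return(z_max)
  min(z_max, -y / d)
}

#' Final position-dependent two-sided gap costs
#'
#' The deletion cost for the first profile at cell `(i, j)` is the fraction
#' of the gap cost limit `A^(i)` left by the superposition (probabilistic
#' OR) of the first profile's down-weighted deletion probability and the
#' second profile's insertion probability:
#' `G_ij = A^(i) (1 - (c D^(i) + I'^(j) - c D^(i) I'^(j)))`, and
#' symmetrically `C_ij = B^(j) (1 - (c P^(j) + J^(i) - c P^(j) J^(i)))`
#' for the second profile. The deletion weight is reduced by the constant
#' `c_del` because the limits by definition already price deletions in the
#' own profile. Zero indel signal keeps the full limit; saturated indel
#' probabilities drive the cost to 0.
#'
#' @param A,B Gap cost limits of the two profiles.
#' @param D1,I1 Thickness-adjusted deletion/insertion probabilities of the
#'   first profile.
#' @param D2,I2 Same for the second profile.
#' @param c_del Deletion weight constant.
#' @return List of `m x n` matrices `G` and `C`.
#' @export
final_gap_costs <- function(A, B, D1, I1, D2, I2, c_del = 0.6) {
  orf <- function(a, b) a + b - a * b
  G <- outer(A, rep(1, length(B))) *
    (1 - orf(outer(c_del * D1, rep(1, length(B))),
             outer(rep(1, length(A)), I2)))
  C <- outer(rep(1, length(A)), B) *
    (1 - orf(outer(rep(1, length(A)), c_del * D2),
             outer(I1, rep(1, length(B)))))
  list(G = G, C = C)
}

#' Build the gap model for a pair score system
#'
#' Computes per-position gap cost limits from the autocorrelation of the
#' score system's row and column maxima (widened by `z`), thickness-adjusts
#' the indel probabilities of both profiles, and assembles the final
#' two-sided per-cell gap costs.
#'
#' @param pair A [ppa_pair_system][pair_score_system].
#' @param config A [ppa_config()].
#' @param z Widening term (see [z_first_pass()]/[z_second_pass()]).
#' @return Object of class `ppa_gap_model`: vectors `A`, `B`, matrices
#'   `G`, `C`, and the `z` used.
#' @export
build_gap_model <- function(pair, config = ppa_config(), z = 0) {
  p1 <- pair$profile1; p2 <- pair$profile2
  cv1 <- characteristic_values(top_max_scores(pair$scores, 1, config$w),
                               config$w, z)
  cv2 <- characteristic_values(top_max_scores(pair$scores, 2, config$w),
                               config$w, z)
  A <- gap_cost_limits(cv1, config$omega, z)
  B <- gap_cost_limits(cv2, config$omega, z)
  D1 <- thickness_adjust(p1$D, p1$eff, config$u, config$v)
  I1 <- thickness_adjust(p1$I, p1$eff, config$u, config$v)
  D2 <- thickness_adjust(p2$D, p2$eff, config$u, config$v)
  I2 <- thickness_adjust(p2$I, p2$eff, config$u, config$v)
  gc <- final_gap_costs(A, B, D1, I1, D2, I2, config$c_del)
  structure(list(A = A, B = B, G = gc$G, C = gc$C, z = z),
            class = "ppa_gap_model")
}
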