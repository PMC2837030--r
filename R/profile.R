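#' Weighted observed residue frequencies at a column
#'
#' Returns the weighted frequencies `f_a` of the twenty residues plus the
#' weighted gap frequency `f_gap` at a column; `sum(f) + f_gap == 1`.
#' Ambiguity codes are redistributed onto the standard alphabet at
#' background-proportional weights.
#'
#' @param msa A [ppa_msa][new_msa].
#' @param weights Per-sequence weights summing to 1.
#' @param i 0-based column index.
#' @return List with `f` (named 20-vector) and `gap` (scalar).
#' @export
observed_frequencies <- function(msa, weights, i) {
  stopifnot(i >= 0, i < ncol(msa$rows), abs(sum(weights) - 1) < 1e-6)
  col <- msa$rows[, i + 1L]
  ind <- residue_indicator(col)
  f <- colSums(ind * weights)
  list(f = f, gap = max(0, 1 - sum(f)))
}

#' Pseudocount-smoothed target probabilities (Tatusov mixture)
#'
#' `t_a = (alpha * f_a + beta * g_a) / (alpha + beta)` with
#' `g_a = sum_b f_b q_ab / p_b`, `alpha = eff_seqs - 1` and `beta` the
#' pseudocount weight. With `beta = 0` the observed frequencies are returned;
#' with a single sequence (`alpha = 0`) the pure pseudocount distribution.
#'
#' @param f Observed residue frequencies over [aa_alphabet()], summing to 1
#'   (gap excluded and renormalized).
#' @param eff_seqs Effective number of sequences (`>= 1`).
#' @param table An [initial_score_table()] supplying `q_ab` and `p_a`.
#' @param beta Pseudocount weight.
#' @return Target probability vector summing to 1.
#' @export
target_probabilities <- function(f, eff_seqs, table, beta = 10) {
  if (eff_seqs < 1) stop("eff_seqs < 1")
  f <- f / sum(f)
  # g_a = sum_b f_b q_ab / p_b
  g <- as.vector(sweep(table$q, 2, table$background, "/") %*% f)
  g <- g / sum(g)
  alpha <- eff_seqs - 1
  t <- (alpha * f + beta * g) / (alpha + beta)
  t / sum(t)
}

#' Generalize raw deletion probabilities over deletion runs
#'
#' Maximal runs of consecutive positions with raw deletion probability
#' `d > 0` are replaced by the straight line through the run's boundary
#' values `(first, d_first)` and `(last, d_last)`; single-position runs are
#' unchanged. Values are clipped to \[0, 1\].
#'
#' @param d Numeric vector of raw per-position deletion probabilities.
#' @return Generalized deletion probabilities, same length.
#' @export
generalize_deletions <- function(d) {
  out <- d
  r <- rle(d > 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < 2) next
    a <- starts[k]; b <- ends[k]
    out[a:b] <- d[a] + (d[b] - d[a]) * (seq(a, b) - a) / (b - a)
  }
  pmin(1, pmax(0, out))
}

#' Thickness adjustment of indel probabilities
#'
#' Multiplies a probability by the logistic factor `1/(1 + exp(-t*u + v))`,
#' damping insertion/deletion estimates from thin alignments. The factor is
#' monotone increasing in the effective sequence count `t`, bounded in
#' (0, 1), and approaches 1 for thick alignments.
#'
#' @param prob Probability (vectorized).
#' @param eff_seqs Effective number of sequences `t` (vectorized).
#' @param u,v Adjustable logistic parameters.
#' @return Adjusted probability.
#' @export
thickness_adjust <- function(prob, eff_seqs, u = 1, v = 2) {
  prob / (1 + exp(-eff_seqs * u + v))
}

#' Relative entropy of a target distribution against the background
#'
#' Computes `sum_a t_a log(t_a / p_a)` in nats; non-negative by Gibbs'
#' inequality, 0 iff `t == p`.
#'
#' @param t Target probabilities (sums to 1).
#' @param p Background probabilities.
#' @return Scalar relative entropy (nats).
#' @export
relative_entropy <- function(t, p) {
  keep <- t > 0
  sum(t[keep] * log(t[keep] / p[keep]))
}

#' Per-position deletion probabilities of an alignment
#'
#' Raw deletion probability at a position is `1 - sum_a f_a`, the weighted
#' gap frequency; runs of positive values are linearly generalized by
#' [generalize_deletions()].
#'
#' @param msa A [ppa_msa][new_msa].
#' @param weights Per-sequence weights (default whole-alignment Henikoff).
#' @param positions 0-based columns to evaluate (default: unmasked columns).
#' @return Numeric vector of generalized deletion probabilities.
#' @export
deletion_probabilities <- function(msa, weights = henikoff_weights(msa$rows),
                                   positions = which(msa$column_mask) - 1L) {
  d <- vapply(positions, function(i) observed_frequencies(msa, weights, i)$gap,
              numeric(1))
  generalize_deletions(d)
}

#' Per-position insertion probabilities of an alignment
#'
#' The insertion probability is the weighted observed gap frequency itself;
#' because an insertion always corresponds to a residue occupying a profile
#' position, no run generalization is applied.
#'
#' @inheritParams deletion_probabilities
#' @return Numeric vector of raw gap frequencies.
#' @export
insertion_probabilities <- function(msa, weights = henikoff_weights(msa$rows),
                                    positions = which(msa$column_mask) - 1L) {
  vapply(positions, function(i) observed_frequencies(msa, weights, i)$gap,
         numeric(1))
}

#' Build a sequence profile from a multiple sequence alignment
#'
#' Runs the full profile construction pipeline: optional complexity
#' filtering, per-position reduced alignments and Henikoff weights, observed
#' frequencies, Tatusov target probabilities, generalized deletion and raw
#' insertion probabilities, relative entropies, positional log-odds scores
#' in reference-lambda units, and composition adjustment so the profile's
#' solved ungapped statistical parameter equals that of the initial table.
#'
#' Per position, sequence weights come from the reduced alignment: Henikoff
#' contributions are accumulated over the columns covered by the reduced
#' alignment, for all rows, and renormalized over all rows, so that residue
#' and gap frequencies sum to 1 at the position while sequences whose
#' residue at the position is terminal do not define the weighting span.
#'
#' @param msa A [ppa_msa][new_msa].
#' @param table An [initial_score_table()].
#' @param config A [ppa_config()].
#' @param name Profile identifier (default: query id).
#' @param provenance Optional source description stored with the profile.
#' @return Object of class `ppa_profile` with per-position matrices/vectors
#'   `f` (residue-renormalized observed frequencies), `f_gap`, `t` (target
#'   probabilities), `s` (adjusted positional scores), `eff`, `D`, `I`, `r`,
#'   and `orig_cols` (0-based source columns of the retained positions).
#' @export
build_profile <- function(msa, table = initial_score_table(),
                          config = ppa_config(),
                          name = msa$sequence_ids[msa$query_index],
                          provenance = NA_character_) {
  if (config$seg_high || config$seg_low) msa <- mask_complexity(msa, config)
  cols <- which(msa$column_mask)
  if (!length(cols)) stop("no unmasked columns: cannot build profile")
  aa <- aa_alphabet()
  m <- length(cols)
  nseq <- nrow(msa$rows)
  spans <- .row_spans(msa$rows)

  f <- matrix(0, m, 20, dimnames = list(NULL, aa))
  fgap <- numeric(m); eff <- numeric(m)
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(m)) {
    j <- cols[k]
    res <- msa$rows[, j] != "-"
    interior <- res & spans[, 1] < j & j < spans[, 2]
    members <- if (any(interior)) which(interior) else if (any(res)) which(res) else msa$query_index
    key <- paste(members, collapse = ",")
    ent <- cache[[key]]
    if (is.null(ent)) {
      covered <- which(colSums(msa$rows[members, , drop = FALSE] != "-") > 0)
      wts <- henikoff_weights(msa$rows, covered)
      ent <- list(w = wts, eff = effective_count(msa$rows, members, covered))
      cache[[key]] <- ent
    }
    of <- observed_frequencies(msa, ent$w, j - 1L)
    f[k, ] <- of$f; fgap[k] <- of$gap; eff[k] <- ent$eff
  }

  # residue-renormalized frequencies, targets, entropies, scores
  fr <- f / pmax(rowSums(f), .Machine$double.eps)
  tmat <- t(apply(cbind(eff, fr), 1, function(row)
    target_probabilities(row[-1], row[1], table, config$pseudocount_weight)))
  dimnames(tmat) <- list(NULL, aa)
  p <- table$background
  r <- apply(tmat, 1, relative_entropy, p = p)
  s <- log(sweep(tmat, 2, p, "/")) / table$lambda_p

  prof <- structure(list(
    name = name, m = m, nseq = nseq, orig_cols = cols - 1L,
    f = fr, f_gap = fgap, t = tmat, s = s, eff = eff,
    D = generalize_deletions(fgap), I = fgap, r = r,
    lambda_scale = 1, table_lambda = table$lambda_p,
    provenance = provenance), class = "ppa_profile")
  composition_adjust_profile(prof, table)
}

#' Compositionally adjust a profile's positional scores
#'
#' Solves the profile's own ungapped statistical parameter lambda on the
#' distribution of positional scores (cell `(i, a)` carrying background
#' probability `p_a / m`) and rescales all scores by `lambda / lambda_p` so
#' that the re-solved parameter equals the initial table's `lambda_p`
#' (identity: scaling scores by `r` scales lambda by `1/r`).
#'
#' @param profile A `ppa_profile`.
#' @param table The [initial_score_table()] supplying the reference
#'   `lambda_p`.
#' @return The profile with rescaled `s` and updated `lambda_scale`.
#' @export
composition_adjust_profile <- function(profile, table) {
  p <- table$background
  probs <- rep(p, each = profile$m) / profile$m
  sc <- as.vector(profile$s)
  if (max(sc) <= 0) stop("no positive score: profile cannot be composition-adjusted")
  if (sum(probs * sc) >= 0) stop("inadmissible profile score distribution: non-negative mean")
  lam <- solve_lambda(sc, probs, c_bits = NULL)
  factor <- lam / table$lambda_p
  profile$s <- profile$s * factor
  profile$lambda_scale <- profile$lambda_scale * factor
  profile
}

#' @export
print.ppa_profile <- function(x, ...) {
  cat(sprintf("ppa_profile '%s': %d positions, %d sequences, mean eff %.2f, mean rel. entropy %.3f nats\n",
              x$name, x$m, x$nseq, mean(x$eff), mean(x$r)))
  invisible(x)
}
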