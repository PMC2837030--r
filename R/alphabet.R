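#' @useDynLib ppalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot optim rgamma runif convolve setNames quantile
#' @importFrom utils head tail
NULL

#' Amino acid alphabet
#'
#' The 20 standard amino acids in the conventional substitution-matrix order.
#' All per-position profile vectors are indexed in this order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Ambiguity codes accepted on input and their redistribution targets.
# 'B' -> N/D, 'Z' -> Q/E at background-proportional weights; 'X' -> background.
.ambiguity_map <- list(B = c("N", "D"), Z = c("Q", "E"), X = aa_alphabet())

#' Robinson-Robinson background amino acid frequencies
#'
#' Standard background residue probabilities estimated from a large protein
#' sequence collection; the conventional background for log-odds profile
#' scores. Sums to 1.
#'
#' @return Named numeric vector over [aa_alphabet()].
#' @export
robinson_background <- function() {
  c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
    Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
    L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
    S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
}

#' Initial residue substitution score table
#'
#' Wraps a 20x20 integer substitution matrix together with background
#' probabilities and the statistical quantities the profile machinery needs:
#' the ungapped statistical parameter `lambda_p` (nats per score unit) solved
#' from the score distribution under independent backgrounds, the relative
#' entropy `H_table`, the Karlin-Altschul `K_table`, and the implied pair
#' target frequencies `q_ab = p_a p_b exp(lambda_p s_ab)` used for
#' pseudocounts. By construction `sum(q_ab) == 1`.
#'
#' @param scores 20x20 numeric matrix with dimnames over [aa_alphabet()].
#'   Default: BLOSUM62 (from Biostrings).
#' @param background Background probabilities; default Robinson-Robinson.
#' @return Object of class `ppa_score_table`.
#' @export
initial_score_table <- function(scores = NULL, background = robinson_background()) {
  aa <- aa_alphabet()
  if (is.null(scores)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    scores <- e$BLOSUM62[aa, aa]
  }
  stopifnot(is.matrix(scores), all(dim(scores) == 20))
  scores <- scores[aa, aa]
  p <- background[aa]
  stopifnot(abs(sum(p) - 1) < 1e-6, all(p > 0))
  pp <- outer(p, p)
  if (sum(pp * scores) >= 0) stop("inadmissible score table: non-negative expected score")
  if (max(scores) <= 0) stop("inadmissible score table: no positive score")
  lam <- solve_lambda(as.vector(scores), as.vector(pp), c_bits = NULL)
  q <- pp * exp(lam * scores)
  H <- sum(pp * lam * scores * exp(lam * scores))
  K <- karlin_K(as.vector(scores), as.vector(pp), lambda = lam, H = H)
  structure(list(scores = scores, background = p, q = q,
                 lambda_p = lam, H_table = H, K_table = K),
            class = "ppa_score_table")
}

#' @export
print.ppa_score_table <- function(x, ...) {
  cat(sprintf("ppa_score_table: 20x20, lambda_p = %.4f nats, H = %.4f, K = %.4f\n",
              x$lambda_p, x$H_table, x$K_table))
  invisible(x)
}

#' Derive an initial score table from a set of multiple sequence alignments
#'
#' Counts weighted residue pairs within columns of the supplied alignments
#' (Henikoff-style clustering via the package's sequence weights), converts
#' pair counts to target frequencies q_ab and marginal backgrounds p_a, and
#' returns half-bit log-odds scores `round(2 * log2(q_ab / (p_a p_b)))`.
#' Provided so that the shipped default table can be re-derived from any
#' alignment collection; the package default remains BLOSUM62.
#'
#' @param msas List of [MultipleAlignment][read_msa] objects.
#' @param pseudo Small additive count preventing zero frequencies.
#' @return A `ppa_score_table`.
#' @export
derive_score_table <- function(msas, pseudo = 1) {
  aa <- aa_alphabet()
  counts <- matrix(pseudo, 20, 20, dimnames = list(aa, aa))
  for (msa in msas) {
    w <- henikoff_weights(msa$rows)
    for (j in seq_len(ncol(msa$rows))) {
      col <- msa$rows[, j]
      keep <- col %in% aa
      if (sum(keep) < 2) next
      res <- col[keep]; ww <- w[keep]
      # weighted frequency vector at this column
      f <- vapply(aa, function(a) sum(ww[res == a]), numeric(1))
      f <- f / sum(f)
      counts <- counts + outer(f, f)
    }
  }
  q <- counts / sum(counts)
  q <- (q + t(q)) / 2
  p <- rowSums(q)
  s <- round(2 * log2(q / outer(p, p)))
  initial_score_table(scores = s, background = p / sum(p))
}
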