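#' Smith-Waterman local alignment under positional gap costs
#'
#' Optimal local alignment of two profiles given their score matrix and the
#' per-cell two-sided gap costs: a diagonal move into cell `(i, j)` adds
#' `s_ij`, a vertical move (gap in the second profile at partner column
#' `j`) subtracts `G_ij`, a horizontal move subtracts `C_ij`; cell values
#' are floored at 0, and traceback starts from the global maximum with
#' deterministic tie-breaking (diagonal > vertical > horizontal).
#'
#' @param scores `m x n` score matrix.
#' @param G,C `m x n` non-negative gap cost matrices (vertical/horizontal).
#' @return Object of class `ppa_hit`: `score`, `pairs` (two-column 0-based
#'   matrix of aligned positions, `NA` marking gaps), `start1`/`end1`,
#'   `start2`/`end2` (0-based half-open), `aligned_length`.
#' @export
smith_waterman_positional <- function(scores, G = scores * 0, C = scores * 0) {
  stopifnot(is.matrix(scores), all(dim(G) == dim(scores)),
            all(dim(C) == dim(scores)))
  if (nrow(scores) < 1 || ncol(scores) < 1) stop("empty score matrix")
  res <- .sw_positional_cpp(scores, G, C)
  pairs <- cbind(i = res$path_i - 1L, j = res$path_j - 1L)
  structure(list(score = res$score, pairs = pairs, moves = res$moves,
                 start1 = res$start_i, end1 = res$end_i,
                 start2 = res$start_j, end2 = res$end_j,
                 aligned_length = sum(res$moves == 1L),
                 evalue = NA_real_, pvalue = NA_real_),
            class = "ppa_hit")
}

#' @export
print.ppa_hit <- function(x, ...) {
  cat(sprintf("ppa_hit: score %.2f, %d aligned pairs, q[%d,%d) t[%d,%d), E = %s\n",
              x$score, x$aligned_length, x$start1, x$end1, x$start2, x$end2,
              format(x$evalue, digits = 3)))
  invisible(x)
}

#' Align two profiles with the two-pass gap-limit protocol
#'
#' Builds the pair score system (thickness-corrected, entropy-downscaled,
#' composition-scaled against the reference), then aligns twice: pass 1
#' with gap limits widened by `z1 = zeta/sqrt(H)`; its alignment's E-value
#' re-estimates `z2 = -y/(log E + x)`, the gap model is recomputed, and the
#' pass-2 alignment is returned with E- and P-values. Small initial
#' E-values narrow the gap cost limits for the final alignment.
#'
#' @param profile1,profile2 `ppa_profile` objects.
#' @param config A [ppa_config()].
#' @param reference A significance reference as returned by
#'   [ppa_reference()] (global ungapped parameters + gapped EVD reference);
#'   default: the packaged synthetic calibration.
#' @param n_db Database length (total positions) for the E-value search
#'   space; default: the second profile's length (pairwise mode).
#' @param n_seqs Number of database profiles (edge correction); default 1.
#' @return A `ppa_hit` with `evalue`, `pvalue`, the pair system's solved
#'   parameters (`lambda_u_star`, `K_u_star`, `H`), pass-1 diagnostics
#'   (`score1`, `evalue1`, `z1`, `z2`).
#' @export
align_two_pass <- function(profile1, profile2, config = ppa_config(),
                           reference = ppa_reference(),
                           n_db = NULL, n_seqs = 1L) {
  pair <- pair_score_system(profile1, profile2, config,
                            global = reference$global)
  n <- if (is.null(n_db)) profile2$m else n_db
  gp <- pair_gapped_params(pair$lambda, pair$K,
                           reference$global, reference$evd)
  params <- list(lambda_g_star = gp$lambda_g_star, K_g_star = gp$K_g_star,
                 H = pair$H, m = profile1$m, n = n, n_seqs = n_seqs,
                 edge_correction = config$edge_correction)

  z1 <- z_first_pass(pair$H, config$zeta)
  gm1 <- build_gap_model(pair, config, z1)
  hit1 <- smith_waterman_positional(pair$scores, gm1$G, gm1$C)
  ev1 <- evalue(hit1$score, params)

  z2 <- z_second_pass(ev1$evalue, config$x, config$y, config$z_max)
  gm2 <- build_gap_model(pair, config, z2)
  hit <- smith_waterman_positional(pair$scores, gm2$G, gm2$C)
  ev <- evalue(hit$score, params)

  hit$evalue <- ev$evalue
  hit$pvalue <- ev$pvalue
  hit$lambda_u_star <- pair$lambda
  hit$K_u_star <- pair$K
  hit$H <- pair$H
  hit$lambda_g_star <- gp$lambda_g_star
  hit$K_g_star <- gp$K_g_star
  hit$score1 <- hit1$score
  hit$evalue1 <- ev1$evalue
  hit$z1 <- z1
  hit$z2 <- z2
  hit$query <- profile1$name
  hit$target <- profile2$name
  hit
}

#' Render a pairwise profile alignment
#'
#' Side-by-side blocks of 60 columns with a match line; coordinates are
#' 1-based inclusive. Each profile position is shown as its query
#' (representative) consensus residue: the highest-target-probability
#' residue, upper case.
#'
#' @param hit A `ppa_hit` from [align_two_pass()].
#' @param profile1,profile2 The aligned profiles.
#' @param width Columns per block.
#' @return Character vector of rendered lines (invisibly printed with
#'   `cat` when `print = TRUE`).
#' @param print Print to the console?
#' @export
render_alignment <- function(hit, profile1, profile2, width = 60L,
                             print = TRUE) {
  aa <- aa_alphabet()
  cons <- function(p, i) aa[which.max(p$t[i + 1L, ])]
  n <- nrow(hit$pairs)
  a1 <- a2 <- mid <- character(n)
  for (k in seq_len(n)) {
    i <- hit$pairs[k, 1]; j <- hit$pairs[k, 2]
    a1[k] <- if (is.na(i)) "-" else cons(profile1, i)
    a2[k] <- if (is.na(j)) "-" else cons(profile2, j)
    mid[k] <- if (!is.na(i) && !is.na(j) && a1[k] == a2[k]) a1[k]
              else if (!is.na(i) && !is.na(j)) "+" else " "
  }
  lines <- c(sprintf("# %s vs %s  score %.2f  E = %.3g  P = %.3g",
                     hit$query, hit$target, hit$score, hit$evalue, hit$pvalue))
  pos1 <- hit$start1 + 1L; pos2 <- hit$start2 + 1L
  for (off in seq(1L, n, by = width)) {
    idx <- off:min(off + width - 1L, n)
    n1 <- sum(!is.na(hit$pairs[idx, 1])); n2 <- sum(!is.na(hit$pairs[idx, 2]))
    lines <- c(lines,
               sprintf("Q %5d %s %d", pos1, paste(a1[idx], collapse = ""),
                       pos1 + n1 - 1L),
               sprintf("        %s", paste(mid[idx], collapse = "")),
               sprintf("T %5d %s %d", pos2, paste(a2[idx], collapse = ""),
                       pos2 + n2 - 1L), "")
    pos1 <- pos1 + n1; pos2 <- pos2 + n2
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
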