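#' Per-column compositional complexity of an alignment
#'
#' For every column, the Shannon entropy of the weighted residue distribution
#' (gaps excluded, distribution renormalized) divided by `log(20)`, giving a
#' normalized complexity in \[0, 1\]: 0 for a perfectly conserved column, 1
#' for a column where all twenty residues are equally likely. All-gap columns
#' get complexity 0 and are flagged in the `"degenerate"` attribute.
#'
#' @param msa A [ppa_msa][new_msa].
#' @param weights Per-sequence weights summing to 1; default: Henikoff
#'   weights over the whole alignment.
#' @return Numeric vector, one value per column, attribute `degenerate`
#'   marking all-gap columns.
#' @export
column_complexity <- function(msa, weights = NULL) {
  if (is.null(weights)) weights <- henikoff_weights(msa$rows)
  stopifnot(length(weights) == nrow(msa$rows),
            abs(sum(weights) - 1) < 1e-6)
  m <- ncol(msa$rows)
  out <- numeric(m)
  degen <- logical(m)
  for (j in seq_len(m)) {
    ind <- residue_indicator(msa$rows[, j])
    f <- colSums(ind * weights)
    tot <- sum(f)
    if (tot <= 0) { degen[j] <- TRUE; next }
    f <- f / tot
    f <- f[f > 0]
    out[j] <- -sum(f * log(f)) / log(20)
  }
  attr(out, "degenerate") <- degen
  out
}

# Two-threshold segment detection on a numeric track: seed where
# above trigger, extend contiguously while above extension.
seg_segments <- function(track, trigger, extension) {
  above_ext <- track >= extension
  seeds <- track >= trigger
  mask <- logical(length(track))
  if (!any(seeds)) return(mask)
  r <- rle(above_ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (any(seeds[starts[k]:ends[k]])) mask[starts[k]:ends[k]] <- TRUE
  }
  mask
}

#' Mask compositionally extreme column stretches of an alignment
#'
#' Windowed two-threshold filtering of column complexity, applied before
#' profile construction. Windows of mean complexity above `trigger_high`
#' seed high-complexity segments that are extended while the windowed mean
#' stays above `extension_high`; symmetric logic below `trigger_low` /
#' `extension_low` when low-complexity filtering is enabled. Masked columns
#' are excluded from profile positions but retain their coordinates in the
#' alignment. A window larger than the alignment degenerates to a
#' whole-alignment test.
#'
#' @param msa A [ppa_msa][new_msa].
#' @param config A [ppa_config()] (uses the `seg_*`, `trigger_*`,
#'   `extension_*` entries).
#' @param weights Optional per-sequence weights for [column_complexity()].
#' @return The alignment with an updated `column_mask` (`FALSE` = masked).
#' @export
mask_complexity <- function(msa, config = ppa_config(), weights = NULL) {
  m <- ncol(msa$rows)
  comp <- column_complexity(msa, weights)
  win <- min(config$seg_window, m)
  # centered running mean of complexity over `win` columns
  half <- (win - 1L) %/% 2L
  wmean <- vapply(seq_len(m), function(j) {
    lo <- max(1L, j - half); hi <- min(m, lo + win - 1L); lo <- max(1L, hi - win + 1L)
    mean(comp[lo:hi])
  }, numeric(1))
  mask <- rep(TRUE, m)
  if (config$seg_high)
    mask[seg_segments(wmean, config$trigger_high, config$extension_high)] <- FALSE
  if (config$seg_low)
    mask[seg_segments(-wmean, -config$trigger_low, -config$extension_low)] <- FALSE
  mask[attr(comp, "degenerate")] <- FALSE
  msa$column_mask <- mask
  msa
}
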