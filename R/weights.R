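#' Position-based sequence weights (Henikoff & Henikoff)
#'
#' Each column distributes one unit of weight: a sequence holding residue
#' `a` in a column with `r` distinct residue types, `n_a` of them equal to
#' `a`, earns `1/(r * n_a)`. Per-sequence sums are normalized to 1.
#' Ambiguity codes count as their own residue types; gap cells earn nothing.
#'
#' @param rows Character matrix (sequences x columns) of aligned residues.
#' @param columns Optional column subset over which to accumulate weight.
#' @return Numeric weights, one per row, summing to 1 (uniform if no column
#'   carries any residue).
#' @export
henikoff_weights <- function(rows, columns = seq_len(ncol(rows))) {
  n <- nrow(rows)
  raw <- numeric(n)
  for (j in columns) {
    col <- rows[, j]
    res <- col != "-"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    contrib <- 1 / (r * tab[col[res]])
    raw[res] <- raw[res] + contrib
  }
  if (sum(raw) <= 0) return(rep(1 / n, n))
  raw / sum(raw)
}

#' Reduced multiple alignment membership at a column
#'
#' Sequences belong to the reduced alignment at column `i` iff they hold a
#' residue (non-gap) there that is strictly interior to their aligned span:
#' the residue is neither the sequence's first nor last aligned residue.
#' This stringency avoids degenerate single-column reduced alignments built
#' from terminal residues.
#'
#' If no sequence qualifies, membership falls back to all sequences with a
#' residue at `i`; if the column is all gaps, to the query sequence alone.
#'
#' @param msa A [ppa_msa][new_msa].
#' @param i 0-based column index.
#' @return Integer vector of 1-based sequence indices.
#' @export
reduced_alignment <- function(msa, i) {
  stopifnot(i >= 0, i < ncol(msa$rows))
  j <- i + 1L
  res <- msa$rows[, j] != "-"
  span <- .row_spans(msa$rows)
  interior <- res & span[, 1] < j & j < span[, 2]
  if (any(interior)) return(which(interior))
  if (any(res)) return(which(res))
  msa$query_index
}

# first/last non-gap column per row (0 if none)
.row_spans <- function(rows) {
  t(apply(rows != "-", 1, function(x) {
    w <- which(x)
    if (!length(w)) c(0L, 0L) else c(w[1], w[length(w)])
  }))
}

#' Effective number of sequences of a reduced alignment
#'
#' The mean number of distinct residue types per column, taken over the
#' columns of the alignment restricted to the member sequences that carry at
#' least one residue (the PSI-BLAST convention for position-specific
#' alignment "thickness"). Always `>= 1` for a non-empty membership.
#'
#' @param rows Character matrix of the full alignment.
#' @param members Row indices of the reduced alignment.
#' @param columns Columns over which to average (default: columns where at
#'   least one member holds a residue).
#' @return Scalar effective sequence count.
#' @export
effective_count <- function(rows, members,
                            columns = which(colSums(rows[members, , drop = FALSE] != "-") > 0)) {
  if (!length(columns)) return(1)
  sub <- rows[members, columns, drop = FALSE]
  k <- apply(sub, 2, function(col) length(unique(col[col != "-"])))
  max(1, mean(k[k > 0]))
}
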