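#' Multiple sequence alignment container
#'
#' Internal representation: `sequence_ids`, a character matrix `rows`
#' (sequences x columns, single characters), `query_index` (index of the
#' representative sequence, always 1 for alignments read from FASTA), and a
#' per-column logical `column_mask` (`TRUE` = column participates in profile
#' construction; set by [mask_complexity()]).
#'
#' All API coordinates are 0-based half-open; rendered output is 1-based
#' inclusive.
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of equal-length aligned sequences
#'   (gaps `'-'`; `'.'` accepted and normalized).
#' @param query_index 1-based index of the query row.
#' @return Object of class `ppa_msa`.
#' @export
new_msa <- function(ids, seqs, query_index = 1L) {
  if (length(seqs) < 1) stop("alignment format error: empty input")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment format error: unequal alignment lengths")
  if (lens[1] < 1) stop("alignment format error: zero-length alignment")
  rows <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                 nrow = length(seqs), byrow = TRUE)
  legal <- c(aa_alphabet(), names(.ambiguity_map), "-")
  bad <- which(!(rows %in% legal))
  if (length(bad)) {
    r <- ((bad[1] - 1) %% nrow(rows)) + 1
    stop(sprintf("alignment format error: illegal character '%s' in row %d (%s)",
                 rows[bad[1]], r, ids[r]))
  }
  if (all(rows[query_index, ] == "-"))
    stop("alignment format error: query row is all gaps")
  structure(list(sequence_ids = as.character(ids), rows = rows,
                 query_index = as.integer(query_index),
                 column_mask = rep(TRUE, ncol(rows))),
            class = "ppa_msa")
}

#' @export
print.ppa_msa <- function(x, ...) {
  cat(sprintf("ppa_msa: %d sequences x %d columns (query: %s), %d masked columns\n",
              nrow(x$rows), ncol(x$rows), x$sequence_ids[x$query_index],
              sum(!x$column_mask)))
  invisible(x)
}

#' Read an aligned-FASTA multiple sequence alignment
#'
#' The first record is taken as the query/representative sequence. Rows must
#' be equal length; characters are upper-cased and `'.'` is normalized to
#' `'-'`; `B`/`Z`/`X` ambiguity codes are accepted.
#'
#' @param path File path or connection of aligned FASTA.
#' @return A [ppa_msa][new_msa] object.
#' @export
read_msa <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("alignment format error: ", conditionMessage(e)))
  if (length(set) == 0) stop("alignment format error: empty input")
  new_msa(names(set), as.character(set), query_index = 1L)
}

#' Write a multiple sequence alignment as aligned FASTA
#'
#' @param msa A [ppa_msa][new_msa] object.
#' @param path Output file path.
#' @export
write_msa <- function(msa, path) {
  seqs <- apply(msa$rows, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- msa$sequence_ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Distribute ambiguity codes onto the 20-letter alphabet at
# background-proportional weights. Returns, for a vector of residue
# characters, a (length x 20) matrix of residue-indicator weights
# (rows sum to 1 for residue characters, 0 for gaps).
residue_indicator <- function(chars, background = robinson_background()) {
  aa <- aa_alphabet()
  out <- matrix(0, length(chars), 20, dimnames = list(NULL, aa))
  plain <- chars %in% aa
  out[cbind(which(plain), match(chars[plain], aa))] <- 1
  for (code in names(.ambiguity_map)) {
    idx <- which(chars == code)
    if (!length(idx)) next
    targets <- .ambiguity_map[[code]]
    wts <- background[targets] / sum(background[targets])
    out[idx, targets] <- matrix(wts, length(idx), length(targets), byrow = TRUE)
  }
  out
}
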