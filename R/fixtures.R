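#' Specification of a synthetic alignment family
#'
#' Describes a protein family for the synthetic generator: per-position
#' Dirichlet concentrations controlling conservation (low concentration =
#' peaked, conserved column; high = near-background, variable column), gap
#' runs, and a seed. The generator emulates the statistical structure the
#' profile machinery assumes — conserved cores, variable stretches,
#' deletion runs — with residues drawn i.i.d. per column; it does not model
#' phylogenetic correlation between sequences.
#'
#' @param n_positions Number of alignment columns.
#' @param n_sequences Number of sequences.
#' @param conservation Per-position Dirichlet concentration (recycled);
#'   default: each position conserved (0.5) with probability
#'   `p_conserved`, else variable (20).
#' @param p_conserved Fraction of conserved positions when `conservation`
#'   is not given.
#' @param gap_runs List of `c(start, length, gap_probability)` (0-based
#'   start): each non-query sequence deletes the whole run with the given
#'   probability.
#' @param seed RNG seed (generation is bit-for-bit reproducible).
#' @return List of class `ppa_fixture_spec`.
#' @export
fixture_spec <- function(n_positions = 200L, n_sequences = 50L,
                         conservation = NULL, p_conserved = 0.6,
                         gap_runs = list(), seed = 1L) {
  stopifnot(n_positions >= 1, n_sequences >= 1)
  for (gr in gap_runs)
    stopifnot(length(gr) == 3, gr[3] >= 0, gr[3] <= 1,
              gr[1] >= 0, gr[1] + gr[2] <= n_positions)
  structure(list(n_positions = as.integer(n_positions),
                 n_sequences = as.integer(n_sequences),
                 conservation = conservation, p_conserved = p_conserved,
                 gap_runs = gap_runs, seed = seed),
            class = "ppa_fixture_spec")
}

.rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) <= 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# per-position parent distributions for a spec (RNG state consumed)
.sample_parents <- function(spec) {
  p <- robinson_background()
  conc <- spec$conservation
  if (is.null(conc))
    conc <- ifelse(runif(spec$n_positions) < spec$p_conserved, 0.5, 20)
  conc <- rep_len(conc, spec$n_positions)
  t(vapply(conc, function(cc) .rdirichlet1(cc * 20 * p), numeric(20)))
}

# sample an MSA from given parent distributions
.sample_msa_from_parents <- function(parents, spec, name = "query") {
  aa <- aa_alphabet()
  m <- spec$n_positions; n <- spec$n_sequences
  rows <- matrix("", n, m)
  for (i in seq_len(m))
    rows[, i] <- sample(aa, n, replace = TRUE, prob = parents[i, ])
  for (gr in spec$gap_runs) {
    cols <- (gr[1] + 1L):(gr[1] + gr[2])
    if (n > 1) {
      del <- which(runif(n - 1) < gr[3]) + 1L  # query row stays gapless
      rows[del, cols] <- "-"
    }
  }
  ids <- c(name, sprintf("%s_s%d", name, seq_len(n - 1L))[seq_len(n - 1L)])
  msa <- new_msa(ids[seq_len(n)], apply(rows, 1, paste, collapse = ""))
  attr(msa, "parents") <- parents  # sampled per-position distributions
  msa
}

#' Sample a synthetic family alignment
#'
#' Draws per-position residue distributions from
#' `Dirichlet(concentration * 20 * background)` and samples sequences
#' i.i.d. per column; gap runs are applied to non-query sequences, keeping
#' the query row gapless.
#'
#' @param spec A [fixture_spec()].
#' @param name Query/family identifier.
#' @return A [ppa_msa][new_msa].
#' @export
sample_family_msa <- function(spec, name = sprintf("fam%d", spec$seed)) {
  set.seed(spec$seed)
  parents <- .sample_parents(spec)
  .sample_msa_from_parents(parents, spec, name)
}

#' Sample a pair of families with controlled relatedness
#'
#' Both families share parent residue distributions on a centered
#' contiguous block covering `relatedness` of the positions (0 = fully
#' independent, 1 = same family); the remaining positions get independent
#' parents. Each family then samples its own sequences.
#'
#' @param spec A [fixture_spec()].
#' @param relatedness Fraction of shared positions in \[0, 1\].
#' @param names Identifiers for the two families.
#' @return List of two [ppa_msa][new_msa] objects.
#' @export
sample_related_pair <- function(spec, relatedness,
                                names = sprintf("fam%d%s", spec$seed, c("a", "b"))) {
  stopifnot(relatedness >= 0, relatedness <= 1)
  set.seed(spec$seed)
  m <- spec$n_positions
  shared <- .sample_parents(spec)
  pa <- .sample_parents(spec)
  pb <- .sample_parents(spec)
  L <- round(relatedness * m)
  if (L > 0) {
    start <- (m - L) %/% 2
    idx <- (start + 1L):(start + L)
    pa[idx, ] <- shared[idx, ]
    pb[idx, ] <- shared[idx, ]
  }
  list(.sample_msa_from_parents(pa, spec, names[1]),
       .sample_msa_from_parents(pb, spec, names[2]))
}

#' Emit a set of synthetic fixture alignments to disk
#'
#' Writes `n` family alignments as aligned FASTA plus a JSON manifest
#' recording the generation parameters.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Number of families.
#' @param spec Base [fixture_spec()]; family `k` uses `seed + k - 1`.
#' @return Invisibly, the manifest as a list.
#' @export
ppa_fixtures <- function(out_dir, n = 10L, spec = fixture_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n)
  for (k in seq_len(n)) {
    sp <- spec; sp$seed <- spec$seed + k - 1L
    msa <- sample_family_msa(sp)
    files[k] <- file.path(out_dir, sprintf("fam%d.fa", sp$seed))
    write_msa(msa, files[k])
  }
  manifest <- list(n = n, n_positions = spec$n_positions,
                   n_sequences = spec$n_sequences,
                   p_conserved = spec$p_conserved,
                   base_seed = spec$seed, files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
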