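# shared fixtures and independent oracles

msa_from <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  new_msa(ids, seqs)
}

# independent lambda oracle: plain interval-halving, no Newton step
bisect_lambda <- function(s, p, lo = 1e-9, hi = NULL) {
  f <- function(l) sum(p * exp(l * s)) - 1
  if (is.null(hi)) {
    hi <- 1e-3
    while (f(hi) < 0) hi <- hi * 2
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# random admissible lattice score distribution (negative mean, a positive score)
random_admissible <- function() {
  repeat {
    k <- sample(3:8, 1)
    s <- sort(sample(-10:10, k))
    p <- rgamma(k, 1); p <- p / sum(p)
    if (sum(p * s) < -0.2 && max(s) > 0) return(list(s = s, p = p))
  }
}

# brute-force local alignment oracle: enumerate every monotone path from
# every start cell under the same per-cell gap-cost convention as the DP
enum_local_max <- function(S, G, C) {
  m <- nrow(S); n <- ncol(S)
  best <- 0
  rec <- function(i, j, sc) {
    if (sc > best) best <<- sc
    if (i < m && j < n) rec(i + 1, j + 1, sc + S[i + 1, j + 1])
    if (i < m) rec(i + 1, j, sc - G[i + 1, j])
    if (j < n) rec(i, j + 1, sc - C[i, j + 1])
  }
  for (i in seq_len(m)) for (j in seq_len(n)) {
    rec(i, j, S[i, j])            # enter via a match
    rec(i, j, -G[i, j])           # enter via a vertical gap
    rec(i, j, -C[i, j])           # enter via a horizontal gap
  }
  best
}

# rank-based AUC: probability a related pair outranks (smaller E) an unrelated one
rank_auc <- function(pos_scores, neg_scores) {
  r <- rank(c(pos_scores, neg_scores))
  n1 <- length(pos_scores); n2 <- length(neg_scores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

test_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- initial_score_table()
    tab
  }
})

small_profile <- function(seed = 1, m = 60, nseq = 12, ...) {
  sp <- fixture_spec(n_positions = m, n_sequences = nseq, seed = seed, ...)
  build_profile(sample_family_msa(sp), test_table())
}
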