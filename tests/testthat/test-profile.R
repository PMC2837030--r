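test_that("Henikoff weights match hand computation and symmetry limits", {
  rows <- rbind(c("A", "A"), c("A", "A"), c("A", "C"))
  # col 1: A x3 -> 1/3 each; col 2: r=2, A: 1/4 each, C: 1/2
  # raw (7/12, 7/12, 5/6) -> normalized (0.29167, 0.29167, 0.41667)
  expect_equal(henikoff_weights(rows), c(7, 7, 10) / 24, tolerance = 1e-12)

  ident <- matrix("A", 5, 4)
  expect_equal(henikoff_weights(ident), rep(0.2, 5))
  expect_equal(henikoff_weights(matrix(c("A", "C", "D"), 1, 3)), 1)
})

test_that("reduced alignment excludes terminal residues, with fallbacks", {
  # all 3 sequences cover the full span: interior position keeps all
  msa <- msa_from(c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(reduced_alignment(msa, 5), 1:3)

  # a sequence whose last residue sits at column 5 (0-based) is excluded there
  msa2 <- msa_from(c("ACDEFGHIKL", "ACDEFG----"))
  expect_equal(reduced_alignment(msa2, 5), 1L)
  expect_equal(reduced_alignment(msa2, 4), 1:2)

  # first-residue exclusion on the other end
  msa3 <- msa_from(c("ACDEFGHIKL", "--DEFGHIKL"))
  expect_equal(reduced_alignment(msa3, 2), 1L)

  # fallback: every contributing residue is terminal -> all residue holders
  expect_equal(reduced_alignment(msa2, 0), 1:2)
})

test_that("reduced alignment membership matches the predicate oracle", {
  set.seed(21)
  for (trial in 1:100) {
    n <- sample(2:8, 1); m <- sample(4:12, 1)
    rows <- matrix(sample(c(aa_alphabet()[1:5], "-"), n * m, replace = TRUE,
                          prob = c(rep(0.15, 5), 0.25)), n, m)
    rows[1, ] <- "A"  # query gapless
    msa <- new_msa(paste0("s", 1:n), apply(rows, 1, paste, collapse = ""))
    i <- sample(m, 1) - 1L
    got <- reduced_alignment(msa, i)
    # oracle: direct statement of the predicate
    pred <- vapply(seq_len(n), function(s) {
      nz <- which(rows[s, ] != "-")
      ((i + 1L) %in% nz) && (i + 1L) > min(nz) && (i + 1L) < max(nz)
    }, logical(1))
    if (any(pred)) expect_identical(got, which(pred))
    else expect_true(all(rows[got, i + 1L] != "-") || identical(got, msa$query_index))
  }
})

test_that("observed frequencies account for gaps and sum to one", {
  msa <- msa_from(c("A", "A"))
  of <- observed_frequencies(msa, c(0.5, 0.5), 0)
  expect_equal(unname(of$f["A"]), 1)
  expect_equal(of$gap, 0)

  msa2 <- msa_from(c("AC", "A-"))
  of2 <- observed_frequencies(msa2, c(0.5, 0.5), 1)
  expect_equal(of2$gap, 0.5)
  expect_equal(sum(of2$f) + of2$gap, 1)

  # ambiguity codes redistribute to constituents
  msaB <- msa_from(c("B", "B"))
  ofB <- observed_frequencies(msaB, c(0.5, 0.5), 0)
  expect_gt(ofB$f["N"], 0); expect_gt(ofB$f["D"], 0)
  expect_equal(sum(ofB$f), 1, tolerance = 1e-12)
})

test_that("Tatusov target probabilities interpolate data and pseudocounts", {
  tab <- test_table()
  f <- setNames(numeric(20), aa_alphabet()); f["A"] <- 1

  # beta = 0: observed frequencies returned
  expect_equal(target_probabilities(f, 5, tab, beta = 0), f)

  # alpha = 0 (single sequence): pure pseudocount distribution
  g <- as.vector(sweep(tab$q, 2, tab$background, "/") %*% f)
  g <- g / sum(g)
  expect_equal(unname(target_probabilities(f, 1, tab, beta = 10)), g,
               tolerance = 1e-12)

  # mixture: alpha = 4, beta = 10
  t_mix <- target_probabilities(f, 5, tab, beta = 10)
  expected <- (4 * f + 10 * g) / 14
  expect_equal(unname(t_mix), unname(expected / sum(expected)), tolerance = 1e-12)
  expect_equal(sum(t_mix), 1, tolerance = 1e-12)

  expect_error(target_probabilities(f, 0.5, tab), "eff_seqs")
})

test_that("deletion probabilities are linearly generalized over runs", {
  expect_equal(generalize_deletions(c(0, 0.2, 0.9, 0.4, 0)),
               c(0, 0.2, 0.3, 0.4, 0))
  expect_equal(generalize_deletions(c(0, 0.5, 0)), c(0, 0.5, 0))  # isolated
  expect_equal(generalize_deletions(rep(0, 6)), rep(0, 6))        # gapless

  # interpolated runs are exactly linear: zero second difference
  set.seed(9)
  d <- generalize_deletions(c(0, runif(6), 0, runif(4), 0))
  run_second_diff <- diff(diff(d[2:7]))
  expect_lt(max(abs(run_second_diff)), 1e-12)
})

test_that("insertion probabilities are raw gap frequencies", {
  msa <- msa_from(c("AAAA", "A--A", "AAAA"))
  w <- rep(1 / 3, 3)
  positions <- 0:3
  ins <- insertion_probabilities(msa, w, positions)
  del <- deletion_probabilities(msa, w, positions)
  expect_equal(ins, c(0, 1 / 3, 1 / 3, 0))
  # equal-boundary run: interpolation coincides here, D == I
  expect_equal(del, ins)

  # a run with unequal interior: D and I differ exactly on the interpolated run
  msa2 <- msa_from(c("AAAAA", "A---A", "AA-AA"))
  ins2 <- insertion_probabilities(msa2, rep(1 / 3, 3), 0:4)
  del2 <- deletion_probabilities(msa2, rep(1 / 3, 3), 0:4)
  expect_equal(del2[c(1, 5)], ins2[c(1, 5)])
  expect_equal(del2[3], (ins2[2] + ins2[4]) / 2)
  expect_false(isTRUE(all.equal(del2[3], ins2[3])))
})

test_that("thickness adjustment is a bounded monotone logistic factor", {
  expect_equal(thickness_adjust(0.8, 1000, u = 1, v = 2), 0.8, tolerance = 1e-6)
  expect_equal(thickness_adjust(1, 0, u = 1, v = 2), 1 / (1 + exp(2)))
  expect_equal(thickness_adjust(1, 2, u = 1, v = 2), 0.5)
  t_grid <- thickness_adjust(1, seq(0, 30, by = 0.5), u = 1, v = 2)
  expect_true(all(diff(t_grid) > 0))
  expect_true(all(t_grid > 0 & t_grid < 1))
})

test_that("relative entropy is Gibbs non-negative with known closed forms", {
  p <- robinson_background()
  expect_equal(relative_entropy(p, p), 0)
  t1 <- setNames(numeric(20), aa_alphabet()); t1["A"] <- 1
  expect_equal(relative_entropy(t1, rep(1 / 20, 20)), log(20))
  set.seed(4)
  for (k in 1:1000) {
    x <- rgamma(20, 1); x <- x / sum(x)
    expect_gte(relative_entropy(x, p), 0)
  }
})

test_that("composition adjustment pins the profile lambda to the table's", {
  tab <- test_table()
  # single-sequence profile
  msa <- msa_from("ACDEFGHIKLMNPQRSTVWY", ids = "q")
  prof <- build_profile(msa, tab, ppa_config(seg_high = FALSE))
  probs <- rep(tab$background, each = prof$m) / prof$m
  lam <- bisect_lambda(as.vector(prof$s), probs)
  expect_equal(lam, tab$lambda_p, tolerance = 1e-4)

  # multi-sequence profile
  prof2 <- small_profile(seed = 6, m = 50, nseq = 20)
  probs2 <- rep(tab$background, each = prof2$m) / prof2$m
  expect_equal(bisect_lambda(as.vector(prof2$s), probs2), tab$lambda_p,
               tolerance = 1e-4)

  # flat profile (t == p everywhere) cannot be adjusted
  flat <- prof
  flat$s <- matrix(0, prof$m, 20)
  expect_error(composition_adjust_profile(flat, tab), "no positive score")
})

test_that("profile invariants hold on a gappy fixture", {
  prof <- small_profile(seed = 8, m = 60, nseq = 15,
                        gap_runs = list(c(20, 8, 0.5), c(45, 3, 0.3)))
  expect_lt(max(abs(rowSums(prof$t) - 1)), 1e-9)
  expect_true(all(prof$D >= 0 & prof$D <= 1))
  expect_true(all(prof$I >= 0 & prof$I <= 1))
  expect_true(all(prof$r >= 0))
  expect_true(all(prof$eff >= 1))
})
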