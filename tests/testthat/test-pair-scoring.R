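test_that("solve_lambda reproduces closed forms and the bisection oracle", {
  # {+1: 1/4, -1: 3/4}: exp(lambda) is the root of x/4 + 3/(4x) = 1 -> x = 3
  expect_equal(solve_lambda(c(1, -1), c(0.25, 0.75)), log(3), tolerance = 1e-6)

  expect_error(solve_lambda(c(1, -1), c(0.5, 0.5)), "inadmissible")
  expect_error(solve_lambda(c(-1, -2), c(0.5, 0.5)), "inadmissible")

  tab <- test_table()
  pp <- as.vector(outer(tab$background, tab$background))
  sc <- as.vector(tab$scores)
  expect_equal(solve_lambda(sc, pp, c_bits = NULL), bisect_lambda(sc, pp),
               tolerance = 1e-3)
})

test_that("solved lambda normalizes the implied target distribution", {
  set.seed(31)
  for (k in 1:100) {
    d <- random_admissible()
    lam <- solve_lambda(d$s, d$p, c_bits = NULL)
    expect_lt(abs(sum(d$p * exp(lam * d$s)) - 1), 1e-6)
  }
})

test_that("pair scores are symmetric cross log-odds", {
  set.seed(32)
  # exchange symmetry of the raw scores and of the full score system
  for (k in 1:10) {
    p1 <- small_profile(seed = 100 + k, m = 25, nseq = 8)
    p2 <- small_profile(seed = 200 + k, m = 30, nseq = 12)
    expect_lt(max(abs(raw_pair_scores(p1, p2) - t(raw_pair_scores(p2, p1)))), 1e-9)
    s12 <- pair_score_system(p1, p2)$scores
    s21 <- pair_score_system(p2, p1)$scores
    expect_lt(max(abs(s12 - t(s21))), 1e-9)
  }

  # profile vs itself: matrix equals its own transpose
  p <- small_profile(seed = 300, m = 20, nseq = 6)
  expect_equal(raw_pair_scores(p, p), t(raw_pair_scores(p, p)))
})

test_that("identical single-sequence profiles score positive on the diagonal", {
  cfg <- ppa_config(seg_high = FALSE)
  msa <- msa_from("ACDEFGHIKLMNPQRSTVWY", ids = "q")
  p1 <- build_profile(msa, test_table(), cfg)
  s <- raw_pair_scores(p1, p1)
  expect_true(all(diag(s) > 0))
  expect_lt(mean(s[row(s) != col(s)]), 0)
})

test_that("thickness correction follows the effective-count weighting", {
  p1 <- small_profile(seed = 41, m = 20, nseq = 8)
  p2 <- small_profile(seed = 42, m = 20, nseq = 8)
  rt <- raw_pair_scores(p1, p2, terms = TRUE)

  # both single-sequence: no correction
  uncorr <- correct_scores(rt$A1, rt$A2, p1$eff, p2$eff,
                           single1 = TRUE, single2 = TRUE)
  expect_equal(uncorr, (rt$A1 + rt$A2) / 2)

  # equal effective counts: correction reduces to the plain average
  eq <- correct_scores(rt$A1, rt$A2, rep(7, 20), rep(7, 20))
  expect_equal(eq, (rt$A1 + rt$A2) / 2, tolerance = 1e-12)

  # thick profile 1 (t=50) vs thin profile 2 (t=2): the corrected score is
  # dominated by the term averaging the thin profile's log-odds over the
  # thick profile's observed frequencies (A1), the higher-weighted term
  thick_thin <- correct_scores(rt$A1, rt$A2, rep(50, 20), rep(2, 20))
  expect_lt(max(abs(thick_thin - (50 * rt$A1 + 2 * rt$A2) / 52)), 1e-12)
  expect_lt(mean(abs(thick_thin - rt$A1)), mean(abs(thick_thin - rt$A2)))

  # single-sequence first profile: its log-odds averaged over the second
  # profile's frequencies (A2) survive
  single_first <- correct_scores(rt$A1, rt$A2, rep(1, 20), rep(50, 20))
  expect_lt(mean(abs(single_first - rt$A2)), mean(abs(single_first - rt$A1)))
})

test_that("entropy down-scaling halves exactly the low-entropy rows/columns", {
  set.seed(5)
  s <- matrix(rnorm(30), 5, 6)
  r1 <- c(0.5, 0.5, 0.05, 0.5, 0.5)  # third row below tau at E = 1e-4
  r2 <- rep(0.5, 6)
  out <- entropy_downscale(s, r1, r2, expected_evalue = 1e-4, kappa = 1)
  expect_equal(out[3, ], s[3, ] * 0.5)
  expect_equal(out[-3, ], s[-3, ])

  # threshold value: kappa/(-log E)
  expect_equal(1 / (-log(1e-4)), 1 / (4 * log(10)), tolerance = 1e-12)
  expect_equal(entropy_downscale(s, r1, r2, expected_evalue = 1),  s)

  # all entropies above threshold: unchanged
  expect_equal(entropy_downscale(s, rep(1, 5), rep(1, 6), 1e-4), s)
})

test_that("pair system satisfies the post-solve normalization invariant", {
  for (k in 1:5) {
    p1 <- small_profile(seed = 500 + k, m = 30, nseq = 10)
    p2 <- small_profile(seed = 600 + k, m = 35, nseq = 10)
    pair <- pair_score_system(p1, p2)
    d <- score_distribution(as.vector(pair$scores), c_bits = pair$c_bits)
    expect_lt(abs(sum(d$p * exp(pair$lambda / d$scale * d$k)) - 1), 1e-6)
    expect_gt(pair$lambda, 0)
  }
})

test_that("composition scaling reaches the reference lambda and is idempotent", {
  profs <- lapply(1:6, small_profile, m = 30, nseq = 10)
  global <- build_global_score_system(profs,
                                      unit_lambda = test_table()$lambda_p)
  pair <- pair_score_system(profs[[1]], profs[[2]], global = global)
  expect_equal(pair$lambda, global$lambda_u, tolerance = 1e-4)
  again <- composition_scale_pair(pair, global)
  expect_equal(again$scores, pair$scores, tolerance = 1e-4)
})
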