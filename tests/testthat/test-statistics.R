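test_that("entropy H matches the expectation closed form", {
  lam <- solve_lambda(c(1, -1), c(0.25, 0.75))
  H <- entropy_H(c(1, -1), c(0.25, 0.75), lam)
  # lambda (0.25 * 3 * 1 + 0.75 * (1/3) * (-1)) = lambda / 2
  expect_equal(H, log(3) * 0.5, tolerance = 1e-9)
})

test_that("K lies in (0, 1] and respects the lattice rescaling identity", {
  set.seed(91)
  for (k in 1:100) {
    d <- random_admissible()
    lam <- solve_lambda(d$s, d$p, c_bits = NULL)
    K <- karlin_K(d$s, d$p, lambda = lam)
    expect_gt(K, 0); expect_lte(K, 1)
  }

  # doubling all scores halves lambda and leaves the E-value model invariant
  d <- list(s = c(2, -1, -3), p = c(0.3, 0.3, 0.4))
  lam <- solve_lambda(d$s, d$p, c_bits = NULL)
  lam2 <- solve_lambda(2 * d$s, d$p, c_bits = NULL)
  expect_equal(lam2, lam / 2, tolerance = 1e-9)
  expect_equal(karlin_K(2 * d$s, d$p, lambda = lam2),
               karlin_K(d$s, d$p, lambda = lam), tolerance = 1e-6)

  expect_error(karlin_K(c(1, 1), c(0.5, 0.5), lambda = 1), "degenerate")
})

test_that("K agrees with the known two-point closed form", {
  # {+1: p, -1: q}: the excursion analysis gives K = (q - p)^2 / q
  for (pp in c(0.2, 0.25, 0.35)) {
    lam <- solve_lambda(c(1, -1), c(pp, 1 - pp), c_bits = NULL)
    K <- karlin_K(c(1, -1), c(pp, 1 - pp), lambda = lam)
    expect_equal(K, (1 - 2 * pp)^2 / (1 - pp), tolerance = 1e-4)
  }
})

test_that("global score system deduplicates vectors and solves lambda_u", {
  # one profile with identical columns: a single unique vector
  msa <- msa_from(rep("AAAAAAAAAA", 4), paste0("s", 1:4))
  prof <- build_profile(msa, test_table(), ppa_config(seg_high = FALSE))
  expect_warning(g1 <- build_global_score_system(list(prof)), "inadmissible")
  expect_equal(g1$n_vectors, 1L)

  profs <- lapply(1:3, small_profile, m = 50, nseq = 10)
  g <- build_global_score_system(profs)
  # brute-force dedup oracle on the same rounding
  keys <- unlist(lapply(profs, function(p)
    apply(round(cbind(p$t, p$f), 4), 1, paste, collapse = ",")))
  expect_equal(g$n_vectors, length(unique(keys)))
  expect_equal(g$n_positions, sum(vapply(profs, `[[`, 0, "m")))
  expect_gt(g$lambda_u, 0)
  expect_gt(g$K_u, 0); expect_lte(g$K_u, 1)

  expect_error(build_global_score_system(list()), "empty")
})

test_that("EVD reference fitting recovers known Gumbel parameters", {
  set.seed(92)
  lam0 <- 0.3; mu0 <- 50
  x <- mu0 - log(-log(runif(50000))) / lam0
  fit <- fit_evd_reference(x, m = 200, n = 200)
  expect_lt(abs(fit$lambda_g / lam0 - 1), 0.05)
  expect_lt(abs(fit$mu / mu0 - 1), 0.02)
  expect_true(all(is.finite(fit$stderr)))
  # K_g consistency with mu = log(K m n)/lambda
  expect_equal(log(fit$K_g * 200 * 200) / fit$lambda_g, fit$mu,
               tolerance = 1e-6)

  expect_error(fit_evd_reference(rep(5, 2000)), "degenerate|constant")
  expect_error(fit_evd_reference(x[1:100]), "at least 1000")
})

test_that("EVD tail fit survives low-score contamination", {
  set.seed(93)
  lam0 <- 0.3; mu0 <- 50
  tail_part <- mu0 - log(-log(runif(45000))) / lam0
  noise <- runif(5000, 20, 40)
  fit <- fit_evd_reference(c(tail_part, noise), m = 200, n = 200)
  expect_lt(abs(fit$lambda_g / lam0 - 1), 0.10)
})

test_that("pair-level gapped parameters follow the reference ratios", {
  global <- list(lambda_u = 0.3, K_u = 0.1)
  evd <- list(lambda_g = 0.25, K_g = 0.05)
  # composition-scaled pair (lambda_u* == lambda_u): gapped scale unchanged
  gp <- pair_gapped_params(0.3, 0.1, global, evd)
  expect_equal(gp$lambda_g_star, 0.25)
  expect_equal(gp$K_g_star, 0.05)
  # K ratio rule
  gp2 <- pair_gapped_params(0.3, 0.2, global, evd)
  expect_equal(gp2$K_g_star, 0.10)
  # random ratio fixtures
  set.seed(94)
  for (k in 1:20) {
    lu <- runif(1, 0.1, 1); ku <- runif(1)
    gp3 <- pair_gapped_params(lu, ku, global, evd)
    expect_equal(gp3$lambda_g_star, evd$lambda_g * lu / global$lambda_u)
    expect_equal(gp3$K_g_star, evd$K_g * ku / global$K_u)
  }
})

test_that("E-values follow the extreme value model with sane limits", {
  params <- list(lambda_g_star = 0.25, K_g_star = 0.1, H = 0.4,
                 m = 100, n = 100, n_seqs = 1, edge_correction = FALSE)
  ev <- evalue(40, params)
  expect_equal(ev$evalue, 0.1 * 1e4 * exp(-10), tolerance = 1e-9)
  expect_equal(ev$evalue, 0.0454, tolerance = 1e-3)
  expect_equal(ev$pvalue, 1 - exp(-ev$evalue), tolerance = 1e-12)

  expect_lt(evalue(1e6, params)$evalue, 1e-100)
  ev3 <- evalue(log(1e3) / 0.25 + log(0.1 * 1e4) / 0.25, params)  # E = 1e-3
  expect_equal(ev3$pvalue, 9.995e-4, tolerance = 1e-3)

  # E strictly decreasing in s; P <= E; edge correction shrinks the space
  s_grid <- seq(10, 60, by = 5)
  Es <- vapply(s_grid, function(s) evalue(s, params)$evalue, numeric(1))
  expect_true(all(diff(Es) < 0))
  expect_true(all(vapply(s_grid, function(s) {
    e <- evalue(s, params); e$pvalue <= e$evalue + 1e-15
  }, logical(1))))
  params$edge_correction <- TRUE
  ev_edge <- evalue(40, params)
  expect_lte(ev_edge$evalue, ev$evalue)
  expect_gte(ev_edge$m_eff, 1)
})
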