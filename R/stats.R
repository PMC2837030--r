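#' Discretize a score distribution onto an integer lattice
#'
#' Scores are multiplied by `2^c_bits` (preserving `c_bits` bits of
#' precision) and rounded to the nearest integer; probabilities of scores
#' falling in the same bin are summed.
#'
#' @param s Numeric score values.
#' @param p Probabilities (default uniform); must sum to 1.
#' @param c_bits Precision bits.
#' @return List with integer `k`, probabilities `p`, and `scale = 2^c_bits`.
#' @export
score_distribution <- function(s, p = NULL, c_bits = 5L) {
  if (is.null(p)) p <- rep(1 / length(s), length(s))
  stopifnot(length(s) == length(p), abs(sum(p) - 1) < 1e-6)
  scale <- 2^c_bits
  k <- as.integer(round(s * scale))
  agg <- rowsum(p, k)
  list(k = as.integer(rownames(agg)), p = as.vector(agg), scale = scale)
}

#' Solve the Karlin-Altschul statistical parameter lambda
#'
#' Finds the unique positive root of `sum(p * exp(lambda * s)) == 1` for a
#' score distribution with negative mean and at least one positive score.
#' When `c_bits` is given, scores are first discretized onto the
#' `2^-c_bits` lattice (the solved root is returned on the original score
#' scale). Root search: bisection bracketing followed by Newton polishing to
#' tolerance 1e-8 (well below it in practice).
#'
#' @param s Score values.
#' @param p Probabilities (default uniform over `s`).
#' @param c_bits Precision bits for lattice discretization, or `NULL` to
#'   solve on the raw values.
#' @return Positive scalar lambda (nats per score unit).
#' @export
solve_lambda <- function(s, p = NULL, c_bits = 5L) {
  if (is.null(p)) p <- rep(1 / length(s), length(s))
  if (!is.null(c_bits)) {
    d <- score_distribution(s, p, c_bits)
    return(solve_lambda(d$k, d$p, c_bits = NULL) * d$scale)
  }
  if (sum(p * s) >= 0) stop("inadmissible score system: non-negative mean score")
  if (max(s) <= 0) stop("inadmissible score system: no positive score")
  f <- function(l) sum(p * exp(l * s)) - 1
  hi <- 1e-3
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  lam <- uniroot(f, c(hi / 2^20, hi), tol = 1e-12)$root
  # Newton polish
  for (it in 1:4) {
    fv <- sum(p * exp(lam * s)) - 1
    dv <- sum(p * s * exp(lam * s))
    step <- fv / dv
    if (!is.finite(step)) break
    lam <- lam - step
    if (abs(step) < 1e-14) break
  }
  lam
}

#' Relative entropy H of a score system
#'
#' `H = lambda * sum(p * s * exp(lambda * s))` in nats: the expected
#' per-position log-odds under the implied target distribution. Invariant
#' under joint rescaling of scores and lambda.
#'
#' @inheritParams solve_lambda
#' @param lambda Solved statistical parameter for `(s, p)`.
#' @return Scalar H (nats).
#' @export
entropy_H <- function(s, p = NULL, lambda) {
  if (is.null(p)) p <- rep(1 / length(s), length(s))
  sum(p * lambda * s * exp(lambda * s))
}

.gcd2 <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }

#' Karlin-Altschul parameter K of a lattice score distribution
#'
#' Evaluates the classical series for the constant K of the asymptotic
#' ungapped local-alignment score distribution `E = K m n exp(-lambda s)`:
#' with partial sums `S_j` of i.i.d. scores,
#' `sigma = sum_j (1/j) (E(exp(lambda S_j); S_j < 0) + P(S_j >= 0))` and
#' `K = delta * lambda * exp(-2 sigma) / (H (1 - exp(-lambda delta)))`,
#' `delta` the lattice span. Partial-sum distributions are obtained by
#' repeated convolution; the series is truncated when a term falls below
#' `tol` (terms decay geometrically).
#'
#' @param s Integer lattice score values.
#' @param p Probabilities (default uniform).
#' @param lambda Solved lambda for `(s, p)` (per unit of `s`).
#' @param H Relative entropy; computed if missing.
#' @param tol Series truncation tolerance.
#' @param maxit Maximum number of series terms.
#' @return Scalar K in (0, 1].
#' @export
karlin_K <- function(s, p = NULL, lambda, H = NULL,
                     tol = 1e-6, maxit = 80L) {
  if (is.null(p)) p <- rep(1 / length(s), length(s))
  if (any(abs(s - round(s)) > 1e-9))
    stop("karlin_K requires integer lattice scores")
  s <- as.integer(round(s))
  if (length(unique(s)) < 2)
    stop("lattice period detection failed: degenerate score distribution")
  delta <- Reduce(.gcd2, abs(s[s != 0]))
  if (delta == 0) stop("lattice period detection failed: all scores zero")
  s <- s %/% delta
  lamd <- lambda * delta
  if (is.null(H)) H <- entropy_H(s, p, lamd)
  lo <- min(s); hiv <- max(s)
  base <- numeric(hiv - lo + 1)
  for (i in seq_along(s)) base[s[i] - lo + 1] <- base[s[i] - lo + 1] + p[i]
  cur <- base; curoff <- lo
  sigma <- 0
  term <- prev <- NA_real_
  # small lattices convolve cheaply: run the series out far enough that
  # truncation is negligible even close to the zero-mean boundary
  maxit <- max(maxit, ceiling(4000 / length(base)))
  for (j in seq_len(maxit)) {
    if (j > 1) {
      cur <- convolve(cur, rev(base), type = "open")
      cur[cur < 0] <- 0  # FFT round-off
      curoff <- curoff + lo
    }
    vals <- seq(curoff, by = 1, length.out = length(cur))
    neg <- vals < 0
    inner <- sum(cur[neg] * exp(lamd * vals[neg])) + sum(cur[!neg])
    prev <- term; term <- inner / j
    sigma <- sigma + term
    if (term < tol) break
  }
  # geometric extrapolation of the truncated tail (terms decay ~ r^j)
  if (term >= tol && is.finite(prev) && prev > 0 && term < prev) {
    r <- term / prev
    sigma <- sigma + term * r / (1 - r)
  }
  lamd * exp(-2 * sigma) / (H * (1 - exp(-lamd)))
}

#' Ungapped statistical parameters of a score system
#'
#' Convenience wrapper: solves lambda on the fine (`c_bits`) lattice,
#' computes H there, and evaluates K on a coarser (`c_bits_K`) lattice with
#' a consistently re-solved lambda, which keeps the convolution series
#' cheap while leaving K's accuracy well within the needs of E-value
#' estimation.
#'
#' @param s Score values (e.g. all cells of a pair score system).
#' @param p Cell probabilities (default uniform).
#' @param c_bits Precision bits for lambda/H.
#' @param c_bits_K Precision bits for the K series.
#' @return List `lambda`, `H`, `K`.
#' @export
karlin_params <- function(s, p = NULL, c_bits = 5L, c_bits_K = 2L) {
  if (is.null(p)) p <- rep(1 / length(s), length(s))
  lam <- solve_lambda(s, p, c_bits = c_bits)
  H <- entropy_H(s, p, lam)
  dK <- score_distribution(s, p, c_bits_K)
  lamK <- solve_lambda(dK$k, dK$p, c_bits = NULL)
  K <- karlin_K(dK$k, dK$p, lambda = lamK)
  list(lambda = lam, H = H, K = K)
}

# ---------------------------------------------------------------------------
# Global score system

#' Two-level keyed index of unique profile position vectors
#'
#' Content-addressed lookup used for exact deduplication of profile vectors:
#' the first level is a hashed bucket keyed on a short prefix of the rounded
#' vector key; within a bucket, full keys are kept sorted and membership is
#' resolved by binary search. Rounding to `digits` decimals defines vector
#' identity.
#'
#' @param digits Decimal rounding defining vector identity.
#' @return An environment with `insert(key) -> id` and `size()` functions.
#' @keywords internal
vector_index <- function(digits = 4L) {
  buckets <- new.env(parent = emptyenv(), hash = TRUE)
  nuniq <- 0L
  # binary search: number of sorted keys <= key
  bsearch <- function(keys, key) {
    lo <- 0L; hi <- length(keys)
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (keys[mid] <= key) lo <- mid else hi <- mid - 1L
    }
    lo
  }
  insert <- function(key) {
    bk <- substr(key, 1L, 16L)
    b <- buckets[[bk]]
    if (is.null(b)) {
      nuniq <<- nuniq + 1L
      buckets[[bk]] <- list(keys = key, ids = nuniq)
      return(list(id = nuniq, new = TRUE))
    }
    pos <- bsearch(b$keys, key)
    if (pos >= 1 && b$keys[pos] == key)
      return(list(id = b$ids[pos], new = FALSE))
    nuniq <<- nuniq + 1L
    keys <- append(b$keys, key, after = pos)
    ids <- append(b$ids, nuniq, after = pos)
    buckets[[bk]] <- list(keys = keys, ids = ids)
    list(id = nuniq, new = TRUE)
  }
  list(insert = insert, size = function() nuniq)
}

#' Build the global score system of a profile collection
#'
#' Compiles all unique position vectors (target probabilities + observed
#' frequencies, rounded to `digits` decimals for identity) from a profile
#' database, scores every vector pair with the pair-score cell formula, and
#' solves the reference ungapped parameters `lambda_u`, `K_u`, `H_u` of the
#' resulting score distribution. When the full all-vs-all product exceeds
#' `max_pairs` cells, a uniform random sample of vector pairs of that size
#' is scored instead (seeded).
#'
#' The reference frame can be re-expressed in conventional score units via
#' `unit_lambda`: the stored `lambda_u` is then that value, meaning that
#' composition-scaled pair scores live on the scale of the initial score
#' table rather than on the raw cross-log-odds scale. This is a pure change
#' of score units — `K_u` and `H_u` are invariant under the joint rescaling
#' of scores and lambda — and keeps alignment scores in a familiar range.
#'
#' @param profiles List of `ppa_profile` objects.
#' @param config A [ppa_config()].
#' @param digits Vector-identity rounding.
#' @param max_pairs Cell budget for the all-vs-all product.
#' @param seed Seed used if sampling is needed.
#' @param unit_lambda Optional target lambda defining the score units of
#'   the reference frame (e.g. the initial table's `lambda_p`).
#' @return Object of class `ppa_global` with `lambda_u`, `K_u`, `H_u`,
#'   `lambda_u_raw`, `n_vectors`, `n_positions`.
#' @export
build_global_score_system <- function(profiles, config = ppa_config(),
                                      digits = 4L, max_pairs = 1e6,
                                      seed = 1L, unit_lambda = NULL) {
  if (!length(profiles)) stop("empty profile database")
  idx <- vector_index(digits)
  Fs <- list(); Ss <- list()
  npos <- 0L
  for (pr in profiles) {
    npos <- npos + pr$m
    keys <- apply(round(cbind(pr$t, pr$f), digits), 1, paste, collapse = ",")
    for (i in seq_len(pr$m)) {
      ins <- idx$insert(keys[i])
      if (ins$new) {
        Fs[[ins$id]] <- pr$f[i, ]
        Ss[[ins$id]] <- pr$s[i, ]
      }
    }
  }
  V <- idx$size()
  Fm <- do.call(rbind, Fs); Sm <- do.call(rbind, Ss)
  if (as.double(V)^2 <= max_pairs) {
    cells <- (Fm %*% t(Sm) + Sm %*% t(Fm)) / 2
    sc <- as.vector(cells)
  } else {
    set.seed(seed)
    n <- as.integer(max_pairs)
    i <- sample.int(V, n, replace = TRUE)
    j <- sample.int(V, n, replace = TRUE)
    sc <- (rowSums(Fm[i, ] * Sm[j, ]) + rowSums(Sm[i, ] * Fm[j, ])) / 2
  }
  kp <- tryCatch(karlin_params(sc, c_bits = config$c_bits),
                 error = function(e) {
                   warning("inadmissible global score distribution: ",
                           conditionMessage(e))
                   list(lambda = NA_real_, H = NA_real_, K = NA_real_)
                 })
  lam <- if (!is.null(unit_lambda) && is.finite(kp$lambda)) unit_lambda
         else kp$lambda
  structure(list(lambda_u = lam, K_u = kp$K, H_u = kp$H,
                 lambda_u_raw = kp$lambda,
                 n_vectors = V, n_positions = npos, digits = digits),
            class = "ppa_global")
}

#' @export
print.ppa_global <- function(x, ...) {
  cat(sprintf("ppa_global: %d unique vectors / %d positions; lambda_u = %.4f, K_u = %.4f, H_u = %.4f\n",
              x$n_vectors, x$n_positions, x$lambda_u, x$K_u, x$H_u))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gapped-score EVD reference

# negative log-likelihood of a Gumbel observed exactly above `thr` and
# left-censored below it (`n_below` scores known only to be < thr); the
# censored mass anchors the localization parameter, which a purely
# truncated fit leaves nearly unidentified
.gumbel_cens_nll <- function(par, x, thr, n_below) {
  lam <- exp(par[1]); mu <- par[2]
  z <- -lam * (x - mu)
  logf <- log(lam) + z - exp(z)
  logF <- -exp(-lam * (thr - mu))  # log CDF at the threshold
  -(sum(logf) + n_below * logF)
}

#' Fit the gapped-alignment EVD reference by progressive tail thresholds
#'
#' Fits a Gumbel (extreme value) distribution to alignment scores of
#' unrelated profile pairs by maximum likelihood, observing scores above a
#' lower bound exactly and censoring those below it (they contribute only
#' their count through the CDF, which keeps the localization parameter
#' identified), progressively raising the bound and re-estimating until both
#' the scale parameter `lambda_g` and the localization parameter `mu`
#' change by less than `stab_tol` over three consecutive bounds. The
#' stabilized parameters describe the distribution tail, the region that
#' matters for significance estimation. `K_g` is derived from
#' `mu = log(K_g * m * n) / lambda_g` at the calibration search space.
#'
#' @param scores Numeric alignment scores (>= 1000 required).
#' @param m,n Query and database lengths of the calibration search space.
#' @param n_thresholds Number of lower bounds tried (quantile-spaced from
#'   the median upward).
#' @param min_tail Minimum number of exceedances for a fit.
#' @param stab_tol Relative-change tolerance declaring stabilization.
#' @return Object of class `ppa_evd`: `lambda_g`, `mu`, `K_g`,
#'   `fit_threshold`, `stderr` (named, for lambda and mu), `space_mn`.
#' @export
fit_evd_reference <- function(scores, m = 200L, n = 200L,
                              n_thresholds = 20L, min_tail = 200L,
                              stab_tol = 0.02) {
  if (length(scores) < 1000) stop("need at least 1000 scores to fit the EVD reference")
  if (stats::sd(scores) < .Machine$double.eps^0.5)
    stop("degenerate fit: scores are constant")
  thr <- unique(quantile(scores, seq(0.5, 0.995, length.out = n_thresholds),
                         names = FALSE))
  lams <- mus <- rep(NA_real_, length(thr))
  fits <- vector("list", length(thr))
  chosen <- NA_integer_
  for (k in seq_along(thr)) {
    x <- scores[scores >= thr[k]]
    if (length(x) < min_tail) break
    lam0 <- if (k == 1) pi / (stats::sd(x) * sqrt(6)) else lams[k - 1]
    mu0 <- if (k == 1) mean(x) - 0.5772157 / lam0 else mus[k - 1]
    opt <- optim(c(log(lam0), mu0), .gumbel_cens_nll, x = x, thr = thr[k],
                 n_below = length(scores) - length(x),
                 method = "BFGS", hessian = TRUE)
    lams[k] <- exp(opt$par[1]); mus[k] <- opt$par[2]
    fits[[k]] <- opt
    if (k >= 3) {
      # lambda: relative change; mu: change on its natural scale
      # (max(|mu|, 1/lambda)), robust when mu is near zero
      msc <- max(abs(mus[k]), 1 / lams[k])
      d1 <- abs(lams[k] / lams[k - 1] - 1); d2 <- abs(lams[k - 1] / lams[k - 2] - 1)
      e1 <- abs(mus[k] - mus[k - 1]) / msc; e2 <- abs(mus[k - 1] - mus[k - 2]) / msc
      if (max(d1, d2, e1, e2) < stab_tol) { chosen <- k; break }
    }
  }
  if (is.na(chosen)) stop("tail too short: EVD parameters did not stabilize")
  opt <- fits[[chosen]]
  vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  lam <- lams[chosen]; mu <- mus[chosen]
  structure(list(lambda_g = lam, mu = mu,
                 K_g = exp(lam * mu) / (as.double(m) * n),
                 fit_threshold = thr[chosen],
                 stderr = c(lambda = se[1] * lam, mu = se[2]),
                 space_mn = as.double(m) * n),
            class = "ppa_evd")
}

#' @export
print.ppa_evd <- function(x, ...) {
  cat(sprintf("ppa_evd: lambda_g = %.4f (se %.4f), mu = %.2f (se %.2f), K_g = %.4g, threshold %.1f\n",
              x$lambda_g, x$stderr["lambda"], x$mu, x$stderr["mu"],
              x$K_g, x$fit_threshold))
  invisible(x)
}

#' Pair-level gapped statistical parameters
#'
#' Transfers the empirically calibrated gapped reference parameters to a
#' particular profile pair in the same ratios as the pair's ungapped
#' parameters differ from the global (reference) ungapped parameters:
#' `lambda_g* = lambda_g * lambda_u*/lambda_u` and
#' `K_g* = K_g * K_u*/K_u`. After composition scaling `lambda_u* == lambda_u`
#' and the gapped scale parameter is the reference one.
#'
#' @param lambda_u_star,K_u_star Ungapped parameters of the pair score
#'   system.
#' @param global A [ppa_global][build_global_score_system] reference.
#' @param evd A [ppa_evd][fit_evd_reference] reference.
#' @return List `lambda_g_star`, `K_g_star`.
#' @export
pair_gapped_params <- function(lambda_u_star, K_u_star, global, evd) {
  list(lambda_g_star = evd$lambda_g * lambda_u_star / global$lambda_u,
       K_g_star = evd$K_g * K_u_star / global$K_u)
}

#' E-value and P-value of an alignment score
#'
#' `E = K_g* m' n' exp(-lambda_g* s)` with edge-corrected effective lengths
#' `m' = max(1, m - l(s))` and `n' = max(1, n - l(s) * n_seqs)`, where the
#' expected alignment length is the affine approximation
#' `l(s) = alpha * s + beta` with `alpha = lambda_g*/H` by default.
#' `P = 1 - exp(-E)`.
#'
#' @param s Alignment score.
#' @param params List with `lambda_g_star`, `K_g_star`, `H`, `m`, `n`,
#'   `n_seqs` (number of database profiles; 1 for pairwise comparisons),
#'   optional `alpha`, `beta`, and logical `edge_correction`.
#' @return List `evalue`, `pvalue`, `m_eff`, `n_eff`.
#' @export
evalue <- function(s, params) {
  lam <- params$lambda_g_star; K <- params$K_g_star
  m <- params$m; n <- params$n
  nseq <- if (is.null(params$n_seqs)) 1 else params$n_seqs
  if (isTRUE(params$edge_correction)) {
    alpha <- if (is.null(params$alpha)) lam / params$H else params$alpha
    beta <- if (is.null(params$beta)) 0 else params$beta
    l <- max(0, alpha * s + beta)
    m1 <- max(1, m - l); n1 <- max(1, n - l * nseq)
  } else {
    m1 <- m; n1 <- n
  }
  E <- K * m1 * n1 * exp(-lam * s)
  list(evalue = E, pvalue = -expm1(-E), m_eff = m1, n_eff = n1)
}

#' Rescale a pair score system to the global reference lambda
#'
#' Multiplies all scores by `lambda_u*/lambda_u` so that the re-solved
#' ungapped parameter of the pair equals the reference `lambda_u` of the
#' global score system (identity `lambda(r s) = lambda(s)/r`); idempotent.
#'
#' @param pair A `ppa_pair_system` (see [pair_score_system()]).
#' @param global A [ppa_global][build_global_score_system].
#' @return The rescaled pair system with updated statistical parameters.
#' @export
composition_scale_pair <- function(pair, global, tol = 1e-6, maxit = 12L) {
  changed <- FALSE
  for (it in seq_len(maxit)) {
    factor <- pair$lambda / global$lambda_u
    if (abs(factor - 1) < tol) break
    pair$scores <- pair$scores * factor
    pair <- pair_solve_stats(pair, with_K = FALSE)
    changed <- TRUE
  }
  if (changed) pair <- pair_solve_stats(pair, with_K = TRUE)
  pair
}
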