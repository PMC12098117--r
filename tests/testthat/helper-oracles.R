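# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, textbook recursions, and
# closed forms.

# Truncated-power construction of a natural cubic spline basis, projected to
# the natural constraint (linear beyond the boundary knots). Returns a basis
# spanning the same space as ns(); agreement is checked after a least-squares
# change of basis.
tp_natural_spline_cols <- function(x, knots, boundary) {
  # cubic truncated powers for all knots (interior + boundary)
  allk <- sort(c(boundary, knots))
  d <- function(z, k) pmax(z - k, 0)^3
  K <- length(allk)
  # natural spline basis via the standard d_k construction (e.g. ESL 5.2.1):
  # N1 = 1, N2 = x, N_{k+2} = d_k - d_{K-1}, with
  # d_k = (tp(x,k) - tp(x,K)) / (K_last - k)
  dk <- function(k) (d(x, allk[k]) - d(x, allk[K])) / (allk[K] - allk[k])
  cols <- cbind(1, x)
  for (k in seq_len(K - 2L)) cols <- cbind(cols, dk(k) - dk(K - 1L))
  cols
}

# de Boor recursion for B-splines on an arbitrary (possibly periodic-
# extended) knot vector; returns basis functions of the given degree.
bspline_recursion <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- matrix(0, length(x), length(knots) - 1L)
  for (j in seq_len(length(knots) - 1L)) {
    B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1L])
  }
  if (degree > 0) {
    for (p in seq_len(degree)) {
      Bn <- matrix(0, length(x), length(knots) - p - 1L)
      for (j in seq_len(length(knots) - p - 1L)) {
        a <- knots[j + p] - knots[j]
        b <- knots[j + p + 1L] - knots[j + 1L]
        t1 <- if (a > 0) (x - knots[j]) / a * B[, j] else 0
        t2 <- if (b > 0) (knots[j + p + 1L] - x) / b * B[, j + 1L] else 0
        Bn[, j] <- t1 + t2
      }
      B <- Bn
    }
  }
  B[, seq_len(n_basis), drop = FALSE]
}

# Periodic cubic B-spline basis by wrapping the de Boor recursion: evaluate
# on an extended knot sequence and fold the overhanging basis functions.
cyclic_bspline_oracle <- function(x, n_knots, period = 366) {
  h <- period / n_knots
  knots <- seq(-3 * h, period + 3 * h, by = h)
  Bfull <- bspline_recursion(x %% period, knots, degree = 3L)
  nb <- ncol(Bfull)  # n_knots + 3 functions before folding
  B <- Bfull[, 1:n_knots, drop = FALSE]
  for (j in seq_len(nb - n_knots)) {
    B[, j] <- B[, j] + Bfull[, n_knots + j]
  }
  B
}

# Brute-force cross-basis: direct double loop over rows and lags.
crossbasis_bruteforce <- function(x, E, Blag) {
  L <- nrow(Blag) - 1L
  n <- length(x)
  out <- matrix(0, n, ncol(E) * ncol(Blag))
  for (t in seq_len(n)) {
    for (j in seq_len(ncol(E))) {
      for (k in seq_len(ncol(Blag))) {
        s <- 0
        for (l in 0:min(L, t - 1L)) {
          s <- s + E[t - l, j] * Blag[l + 1L, k]
        }
        out[t, (j - 1L) * ncol(Blag) + k] <- s
      }
    }
  }
  out
}

# Day-by-day attributable-fraction summation, written independently of
# analytic_truth(): plain loops, no convolution helper.
af_bruteforce <- function(exposure_code, mu, curve, keep = NULL) {
  L <- nrow(curve) - 1L
  n <- length(exposure_code)
  if (is.null(keep)) keep <- rep(TRUE, n)
  an <- 0; tot <- 0
  for (t in seq_len(n)) {
    if (!keep[t]) next
    s <- 0
    for (l in 0:min(L, t - 1L)) {
      code <- exposure_code[t - l]
      if (code > 0) s <- s + curve[l + 1L, code]
    }
    an <- an + mu[t] * (1 - exp(-s))
    tot <- tot + mu[t]
  }
  100 * an / tot
}

# Univariate REML profile: grid + optimize() maximization of the restricted
# likelihood over tau^2 for d = 1.
reml_tau2_grid <- function(theta, v) {
  nll <- function(tau2) {
    w <- 1 / (v + tau2)
    beta <- sum(w * theta) / sum(w)
    0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (theta - beta)^2))
  }
  stats::optimize(nll, c(0, 100 * (stats::var(theta) + mean(v))))$minimum
}

# Small simulated panel settings shared by several tests: short lag window
# so fits stay fast.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_communities = 6L, years_per_community = 2L, baseline_rate = 25,
    flood_episode_rate = 2, max_lag = 60L,
    overdispersion = 1.2, heterogeneity_sd = 0.05, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  if (is.null(args$planted_lag_curve)) {
    args$planted_lag_curve <- lag_curve_exp_decay(args$max_lag,
                                                  rate = 1 / 20,
                                                  scale = 0.004)
  }
  do.call(sim_config, args)
}

small_spec <- function(max_lag = 60L, ...) {
  stage1_spec(max_lag = max_lag, temp_max_lag = 7L, precip_max_lag = 7L, ...)
}

# Synthetic coefficient-level studies for stage-2 tests.
simulate_meta_studies <- function(k, d, beta, Psi, s_scale = 0.02, seed = 1) {
  set.seed(seed)
  S <- lapply(seq_len(k), function(i) {
    A <- matrix(stats::rnorm(d * d, sd = s_scale), d, d)
    crossprod(A) + diag(s_scale^2, d)
  })
  theta <- do.call(rbind, lapply(seq_len(k), function(i) {
    MASS::mvrnorm(1, beta, S[[i]] + Psi)
  }))
  list(theta = theta, S = S)
}

# Wrap coefficient-level studies as stage1_fit objects.
as_fake_fits <- function(theta, S, ids = NULL) {
  k <- nrow(theta)
  if (is.null(ids)) ids <- sprintf("c%03d", seq_len(k))
  fits <- lapply(seq_len(k), function(i) {
    structure(list(community_id = ids[i], cause = "all", stratum = "all",
                   eta = theta[i, ], vcov = S[[i]], dispersion = 1,
                   n_days = 1000L, converged = TRUE),
              class = "stage1_fit")
  })
  names(fits) <- ids
  structure(fits, class = "stage1_fits")
}
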