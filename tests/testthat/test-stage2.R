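test_that("single-study pooling degenerates to the study itself", {
  d <- 3
  theta <- matrix(c(0.1, -0.2, 0.05), 1)
  S <- list(diag(0.01, d))
  expect_warning(mf <- mvmeta_reml(as_fake_fits(theta, S)), "one unit")
  expect_equal(mf$beta, theta[1, ], ignore_attr = TRUE)
  expect_equal(mf$Psi, matrix(0, d, d))
})

test_that("homogeneous studies reduce to fixed-effect pooling", {
  sim <- simulate_meta_studies(k = 25, d = 4, beta = c(0.2, -0.1, 0.05, 0),
                               Psi = diag(0, 4), s_scale = 0.05, seed = 2)
  # closed-form inverse-variance-weighted fixed-effect oracle
  Sw <- Reduce(`+`, lapply(sim$S, solve))
  swt <- Reduce(`+`, lapply(seq_len(25), function(i) {
    solve(sim$S[[i]]) %*% sim$theta[i, ]
  }))
  beta_fe <- as.numeric(solve(Sw, swt))
  # the package's fixed-effect path reproduces the closed form exactly
  fe <- suppressWarnings(
    floodlag:::pool_fixed_or_single(as_fake_fits(sim$theta, sim$S), "fixed"))
  expect_equal(fe$beta, beta_fe, tolerance = 1e-6)
  expect_equal(fe$vcov, solve(Sw), tolerance = 1e-6, ignore_attr = TRUE)
  # REML on truly homogeneous studies estimates a small Psi, and its GLS
  # estimate stays close to the fixed-effect solution
  mf <- mvmeta_reml(sim)
  se_fe <- sqrt(diag(solve(Sw)))
  expect_true(all(abs(mf$beta - beta_fe) < se_fe))
  expect_lt(sum(diag(mf$Psi)), 0.01)
})

test_that("univariate REML matches a grid/profile oracle and metafor", {
  set.seed(3)
  k <- 20
  v <- runif(k, 0.01, 0.05)
  tau2_true <- 0.03
  theta <- rnorm(k, 0.3, sqrt(v + tau2_true))
  mf <- mvmeta_reml(list(theta = matrix(theta), S = lapply(v, function(x) {
    matrix(x, 1, 1)
  })))
  tau2_oracle <- reml_tau2_grid(theta, v)
  expect_lt(abs(mf$Psi[1, 1] - tau2_oracle), 1e-4)
  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = theta, vi = v, method = "REML",
                      control = list(tol = 1e-10))
  expect_lt(abs(mf$Psi[1, 1] - ref$tau2), 1e-4)
  expect_lt(abs(mf$beta - as.numeric(ref$beta)), 1e-4)
})

test_that("heterogeneity statistics behave at the boundaries", {
  d <- 2
  theta <- matrix(rep(c(0.1, 0.2), 5), ncol = d, byrow = TRUE)
  S <- replicate(5, diag(0.01, d), simplify = FALSE)
  het <- heterogeneity(list(theta = theta, S = S))
  expect_equal(het$Q, 0, tolerance = 1e-12)
  expect_equal(het$I2, 0)
  expect_equal(het$df_Q, d * 4L)

  # homogeneous simulation: mean Q ~ df over replicates
  set.seed(8)
  qs <- replicate(200, {
    sim <- simulate_meta_studies(k = 8, d = 2, beta = c(0, 0),
                                 Psi = diag(0, 2), s_scale = 0.1,
                                 seed = sample.int(1e6, 1))
    heterogeneity(sim)$Q
  })
  df_q <- 2 * 7
  expect_equal(mean(qs), df_q, tolerance = 3 * sqrt(2 * df_q / 200) / df_q)

  # I2 >= 40 labels moderate-or-strong inconsistency
  sim_het <- simulate_meta_studies(k = 30, d = 1, beta = 0,
                                   Psi = matrix(0.05), s_scale = 0.05,
                                   seed = 4)
  expect_gt(heterogeneity(sim_het)$I2, 40)
})

test_that("planted between-community covariance is recovered", {
  # positive planted Psi -> positive tr(Psi-hat) in most replicates;
  # zero planted Psi -> median tr(Psi-hat) near zero
  set.seed(10)
  tr_pos <- replicate(20, {
    sim <- simulate_meta_studies(k = 25, d = 2, beta = c(0.1, 0),
                                 Psi = diag(0.04, 2), s_scale = 0.05,
                                 seed = sample.int(1e6, 1))
    sum(diag(mvmeta_reml(sim)$Psi))
  })
  expect_gte(mean(tr_pos > 0.01), 0.9)
  tr_zero <- replicate(20, {
    sim <- simulate_meta_studies(k = 25, d = 2, beta = c(0.1, 0),
                                 Psi = diag(0, 2), s_scale = 0.05,
                                 seed = sample.int(1e6, 1))
    sum(diag(mvmeta_reml(sim)$Psi))
  })
  expect_lt(stats::median(tr_zero), 0.005)
})

test_that("pooling is invariant to community order", {
  sim <- simulate_meta_studies(k = 12, d = 3, beta = c(0.1, 0, -0.1),
                               Psi = diag(0.01, 3), seed = 6)
  fits <- as_fake_fits(sim$theta, sim$S)
  mf1 <- mvmeta_reml(fits)
  perm <- c(7, 2, 11, 1, 12, 3, 9, 4, 10, 5, 8, 6)
  fits_p <- structure(unclass(fits)[perm], class = "stage1_fits")
  mf2 <- mvmeta_reml(fits_p)
  expect_identical(mf1$beta, mf2$beta)
  expect_identical(mf1$Psi, mf2$Psi)
  expect_identical(mf1$Q, mf2$Q)
})

test_that("k <= d falls back to proportional Psi with a warning", {
  sim <- simulate_meta_studies(k = 3, d = 4, beta = rep(0, 4),
                               Psi = diag(0.01, 4), seed = 7)
  expect_warning(mf <- mvmeta_reml(sim), "proportional")
  expect_equal(mf$Psi[1, 1], mf$Psi[2, 2])
  expect_true(all(mf$Psi[upper.tri(mf$Psi)] == 0))
})

test_that("groupwise pooling partitions and recombines consistently", {
  sim <- simulate_meta_studies(k = 18, d = 2, beta = c(0.2, -0.1),
                               Psi = diag(0, 2), s_scale = 0.05, seed = 9)
  fits <- as_fake_fits(sim$theta, sim$S)
  ids <- vapply(unclass(fits), function(f) f$community_id, character(1))

  # one group = global pool
  g1 <- stats::setNames(rep("all", 18), ids)
  tab1 <- pool_by_grouping(fits, g1)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$fit[[1]]$beta, mvmeta_reml(sim)$beta, tolerance = 1e-6)

  # two groups: precision-weighted recombination of fixed-effect results
  # approximates the global fixed-effect fit (exact when Psi = 0)
  g2 <- stats::setNames(rep(c("x", "y"), each = 9), ids)
  tab2 <- pool_by_grouping(fits, g2)
  expect_equal(nrow(tab2), 2L)
  Vx <- tab2$fit[[which(tab2$group == "x")]]$vcov
  Vy <- tab2$fit[[which(tab2$group == "y")]]$vcov
  bx <- tab2$fit[[which(tab2$group == "x")]]$beta
  by <- tab2$fit[[which(tab2$group == "y")]]$beta
  recomb <- solve(solve(Vx) + solve(Vy)) %*% (solve(Vx) %*% bx +
                                                solve(Vy) %*% by)
  expect_equal(as.numeric(recomb), tab1$fit[[1]]$beta, tolerance = 0.02)

  # tertile cut on simulated densities: near-equal group sizes
  dens <- stats::rlnorm(18, 5, 1)
  tert <- cut_groups(dens, "tertile")
  expect_lte(diff(range(table(tert))), 1)
})

test_that("meta-regression contrasts behave under null and planted effects", {
  spec <- crossbasis_spec(max_lag = 20L, lag_df = 3L)
  wsum <- colSums(lag_basis(spec))
  d <- 3L

  # two identical groups: contrast = 0, p = 1
  theta <- matrix(rep(c(0.01, 0.02, -0.01), 8), ncol = d, byrow = TRUE)
  S <- replicate(8, diag(1e-4, d), simplify = FALSE)
  fits <- as_fake_fits(theta, S)
  ids <- vapply(unclass(fits), function(f) f$community_id, character(1))
  mod <- stats::setNames(rep(c("a", "b"), 4), ids)
  tab <- suppressWarnings(meta_regression(fits, mod, spec, mode = "fixed"))
  expect_equal(tab$cum_rr[tab$level == "a"], tab$cum_rr[tab$level == "b"],
               tolerance = 1e-10)
  expect_equal(tab$p_difference[tab$level == "b"], 1, tolerance = 1e-6)

  # null modifier: difference p-values uniform over replicates
  set.seed(11)
  pvals <- replicate(150, {
    sim <- simulate_meta_studies(k = 12, d = d, beta = c(0.02, 0.01, 0),
                                 Psi = diag(0, d), s_scale = 0.03,
                                 seed = sample.int(1e6, 1))
    f <- as_fake_fits(sim$theta, sim$S)
    m <- stats::setNames(rep(c("a", "b"), 6),
                         vapply(unclass(f), function(x) x$community_id,
                                character(1)))
    suppressWarnings(
      meta_regression(f, m, spec, mode = "fixed"))$p_difference[2]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # planted 2x difference in the cumulative effect: detected mostly
  set.seed(12)
  base_curve <- 0.03 * exp(-(0:20) / 6)
  proj <- qr.solve(lag_basis(spec), base_curve)  # curve in basis coords
  hits <- replicate(40, {
    sim_a <- simulate_meta_studies(k = 30, d = d, beta = proj,
                                   Psi = diag(0, d), s_scale = 0.005,
                                   seed = sample.int(1e6, 1))
    sim_b <- simulate_meta_studies(k = 30, d = d, beta = 2 * proj,
                                   Psi = diag(0, d), s_scale = 0.005,
                                   seed = sample.int(1e6, 1))
    th <- rbind(sim_a$theta, sim_b$theta)
    Ss <- c(sim_a$S, sim_b$S)
    f <- as_fake_fits(th, Ss)
    m <- stats::setNames(rep(c("a", "b"), each = 30),
                         vapply(unclass(f), function(x) x$community_id,
                                character(1)))
    suppressWarnings(
      meta_regression(f, m, spec, mode = "fixed"))$p_difference[2] < 0.05
  })
  expect_gte(mean(hits), 0.8)

  # a level with one community is estimate-only
  f1 <- as_fake_fits(theta[1:3, ], S[1:3])
  m1 <- stats::setNames(c("a", "a", "b"),
                        vapply(unclass(f1), function(x) x$community_id,
                               character(1)))
  tab1 <- suppressWarnings(meta_regression(f1, m1, spec, mode = "fixed"))
  expect_true(is.na(tab1$p_difference[tab1$level == "b"]))
})
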