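test_that("event intervals code inclusive flooded days with severity rules", {
  cal <- seq(as.Date("2010-01-01"), as.Date("2010-03-01"), by = "day")
  ev <- tibble::tibble(community_id = "a",
                       start = as.Date("2010-01-05"),
                       end = as.Date("2010-01-08"),
                       severity = "lower")
  code <- events_to_daily_exposure(ev, cal)
  expect_equal(sum(code > 0), 4L)  # start..end inclusive
  expect_equal(which(code == 1L), 5:8)
  expect_false(attr(code, "never_flooded"))

  # overlapping lower- and higher-severity events: higher wins
  ev2 <- dplyr::bind_rows(ev, tibble::tibble(
    community_id = "a", start = as.Date("2010-01-07"),
    end = as.Date("2010-01-10"), severity = "higher"))
  code2 <- events_to_daily_exposure(ev2, cal)
  expect_equal(unname(code2[5:10]), c(1L, 1L, 2L, 2L, 2L, 2L))

  # no events -> all-zero vector with never-flooded flag
  code0 <- events_to_daily_exposure(ev[0, ], cal)
  expect_true(all(code0 == 0L))
  expect_true(attr(code0, "never_flooded"))

  expect_error(events_to_daily_exposure(
    tibble::tibble(community_id = "a", start = cal[1], end = cal[2],
                   severity = "catastrophic"), cal), "severity")

  # collapse to binary for the main two-strata analysis
  expect_equal(unname(collapse_severity(code2)[5:10]), rep(1L, 6))
})

test_that("never-flooded communities are excluded with a report", {
  panel <- tibble::tibble(
    community_id = rep(c("a", "b", "c"), each = 5),
    exposure_code = c(0, 1, 0, 0, 0,  0, 0, 0, 0, 0,  2, 0, 0, 1, 0))
  out <- exclude_unflooded(panel)
  rep_ <- attr(out, "exclusion_report")
  expect_equal(sort(unique(out$community_id)), c("a", "c"))
  expect_equal(rep_$n_kept, 2L)
  expect_equal(rep_$n_excluded, 1L)
  expect_equal(rep_$excluded_ids[[1]], "b")

  # all flooded -> identity
  all_fl <- panel[panel$community_id != "b", ]
  expect_equal(nrow(exclude_unflooded(all_fl)), nrow(all_fl))

  # none flooded -> abort
  panel0 <- dplyr::mutate(panel, exposure_code = 0)
  expect_error(exclude_unflooded(panel0), "no community")
})

test_that("exclusion report matches the generator's event bookkeeping", {
  cfg <- small_config(seed = 12, n_communities = 10L,
                      flood_episode_rate = 0.3)
  sim <- generate_panel(cfg)
  flooded_ids <- sort(unique(sim$events$community_id[
    sim$events$end >= min(sim$panel$date)]))
  out <- exclude_unflooded(sim$panel)
  rep_ <- attr(out, "exclusion_report")
  expect_equal(rep_$n_kept, length(flooded_ids))
  expect_equal(sort(setdiff(unique(sim$panel$community_id), flooded_ids)),
               sort(rep_$excluded_ids[[1]]))
})

test_that("stage-1 design has the documented block structure", {
  cfg <- small_config(seed = 2)
  sim <- generate_panel(cfg)
  series <- sim$panel[sim$panel$community_id == "c001", ]
  spec <- small_spec()
  des <- build_design(series, spec)
  X <- des$X
  # flood block: binary strata x lag df 4
  expect_length(des$flood_cols, 4L)
  expect_true(all(startsWith(colnames(X)[des$flood_cols], "flood.")))
  # day-of-week block: 6 indicators, row sums <= 1
  dw <- X[, startsWith(colnames(X), "dow"), drop = FALSE]
  expect_equal(ncol(dw), 6L)
  expect_true(all(rowSums(dw) <= 1))
  # incomplete flood-lag history dropped from the likelihood
  expect_equal(des$drop_rows, 1:60)
  # row-wise blocks (day-of-week, season) are equivariant under row
  # permutation; the lagged cross-basis blocks are deliberately not, since
  # they depend on temporal order
  perm <- sample(nrow(series))
  des_p <- build_design(series[perm, ], spec)
  rowwise <- startsWith(colnames(X), "dow") | startsWith(colnames(X), "cyc")
  expect_equal(unname(des_p$X[, rowwise]), unname(X[perm, rowwise]))
})

test_that("quasi-Poisson matches Poisson ML with sqrt(phi)-scaled errors", {
  set.seed(5)
  n <- 5000
  X <- cbind(1, rnorm(n), runif(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  beta <- c(1.5, 0.3, -0.5)
  y <- rnbinom(n, mu = exp(X %*% beta), size = 10)
  fit <- fit_quasipoisson(y, X, flood_cols = 1:3)
  ref <- glm(y ~ x1 + x2, family = poisson(),
             data = data.frame(y = y, x1 = X[, 2], x2 = X[, 3]))
  expect_equal(unname(fit$eta), unname(coef(ref)), tolerance = 1e-8)
  phi_ref <- sum(residuals(ref, "pearson")^2) / ref$df.residual
  expect_equal(fit$dispersion, phi_ref, tolerance = 1e-8)
  # vcov equals the Poisson ML vcov inflated by phi
  expect_equal(unname(fit$vcov), unname(vcov(ref)) * fit$dispersion /
                 summary(ref)$dispersion, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
})

test_that("coefficients are recovered from simulated Poisson data", {
  set.seed(6)
  n <- 20000; p <- 10
  X <- cbind(1, matrix(rnorm(n * (p - 1), sd = 0.5), n))
  colnames(X) <- c("(Intercept)", paste0("x", 1:(p - 1)))
  beta <- c(2, runif(p - 1, -0.3, 0.3))
  y <- rpois(n, exp(X %*% beta))
  fit <- fit_quasipoisson(y, X, flood_cols = seq_len(p))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$eta - beta) < 3 * se))
  # pure Poisson noise: dispersion near 1
  n2 <- 50000
  y2 <- rpois(n2, 20)
  X2 <- matrix(1, n2, 1, dimnames = list(NULL, "(Intercept)"))
  fit2 <- fit_quasipoisson(y2, X2)
  expect_gt(fit2$dispersion, 0.9)
  expect_lt(fit2$dispersion, 1.1)
})

test_that("run_stage1 bookkeeping covers communities and count columns", {
  cfg <- small_config(seed = 9, n_communities = 2L,
                      strata_props = list(sex = c(f = 0.55, m = 0.45)))
  sim <- generate_panel(cfg)
  spec <- small_spec()
  fits <- run_stage1(sim$panel, spec,
                     count_cols = c("count", "count_sex_f", "count_sex_m"))
  expect_length(fits, 6L)  # 2 communities x 3 count columns
  lg <- attr(fits, "log")
  expect_equal(nrow(lg), 6L)
  expect_setequal(unique(lg$count_col), c("count", "count_sex_f", "count_sex_m"))
  # stratified counts sum to the total by construction
  expect_equal(sim$panel$count_sex_f + sim$panel$count_sex_m, sim$panel$count)
  # all-ages fit on the summed series equals the direct total fit
  f_total <- fits[["c001.count"]]
  series <- sim$panel[sim$panel$community_id == "c001", ]
  series$count2 <- series$count_sex_f + series$count_sex_m
  f_manual <- run_stage1(series, spec, count_cols = "count2")[[1]]
  expect_equal(f_manual$eta, f_total$eta, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("planted cumulative RR is recovered within its CI", {
  cfg <- small_config(seed = 14, n_communities = 10L,
                      years_per_community = 3L,
                      flood_episode_rate = 3,
                      heterogeneity_sd = 0, overdispersion = 1)
  cfg <- calibrate_to_target(cfg, target_cum_rr = 1.4)
  sim <- generate_panel(cfg)
  spec <- small_spec()
  fits <- run_stage1(exclude_unflooded(sim$panel), spec)
  mf <- suppressWarnings(mvmeta_reml(fits))
  cr <- cum_rr(mf, spec$flood)
  expect_gt(cr$ci_high, 1.4 * 0.98)
  expect_lt(cr$ci_low, 1.4 * 1.02)
  expect_equal(cr$estimate, 1.4, tolerance = 0.12)
})
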