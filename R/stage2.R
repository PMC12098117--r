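#' Multivariate random-effects meta-analysis by REML
#'
#' Pools community-specific coefficient vectors \eqn{\theta_i} with
#' within-community covariances \eqn{S_i} under the model
#' \eqn{\theta_i \sim N(\beta, S_i + \Psi)}. The between-community
#' covariance \eqn{\Psi} is parametrized by its Cholesky factor with
#' log-transformed diagonal (so \eqn{\Psi} is always positive
#' semi-definite) and estimated by maximizing the restricted likelihood
#' with BFGS from five deterministic scaled starting points; \eqn{\beta}
#' is the generalized-least-squares estimate at the optimum and its
#' covariance is \eqn{(\sum_i (S_i + \Psi)^{-1})^{-1}}.
#'
#' Heterogeneity is summarized by Cochran's Q (evaluated at the
#' fixed-effect solution), its degrees of freedom d(k-1), and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#'
#' @param fits A `stage1_fits` list (non-converged fits are dropped with a
#'   message), or a list with elements `theta` (k x d matrix) and `S`
#'   (list of k covariance matrices).
#' @return Object of class `meta_fit`: `beta`, `vcov`, `Psi`, `Q`, `df_Q`,
#'   `I2`, `p_Q`, `loglik_reml`, `k`, `d`, `dropped`.
#' @export
mvmeta_reml <- function(fits) {
  dat <- as_meta_input(fits)
  theta <- dat$theta; S <- dat$S
  k <- nrow(theta); d <- ncol(theta)
  if (k < 1L) stop("no usable fits to pool")
  if (k == 1L) {
    warning("only one unit to pool; returning it with Psi = 0")
    return(new_meta_fit(beta = theta[1, ], vcov = S[[1]],
                        Psi = matrix(0, d, d), theta = theta, S = S,
                        loglik = NA_real_, dropped = dat$dropped))
  }
  proportional <- k <= d
  if (proportional) {
    warning("k <= d: falling back to proportional (scalar x identity) Psi")
  }
  npar <- if (proportional) 1L else d * (d + 1L) / 2L
  # scale of the empirical between-unit spread seeds the starts
  sd0 <- stats::sd(as.vector(scale(theta, scale = FALSE)))
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- 0.1
  starts <- lapply(c(1, 0.1, 10, 0.01, 3), function(f) {
    if (proportional) log(sd0 * f)
    else {
      par <- numeric(npar)
      par[diag_chol_idx(d)] <- log(sd0 * f)
      par
    }
  })
  nll <- function(par) reml_nll(par, theta, S, proportional)
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value - 1e-10)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("REML optimization failed from all starts")
  Psi <- par_to_psi(best$par, d, proportional)
  gls <- gls_pool(theta, S, Psi)
  new_meta_fit(beta = gls$beta, vcov = gls$vcov, Psi = Psi,
               theta = theta, S = S, loglik = -best$value,
               dropped = dat$dropped)
}

# Positions of the log-diagonal entries in the packed lower-triangle vector
# (column-major over the lower triangle).
diag_chol_idx <- function(d) {
  cumsum(c(1L, if (d > 1L) rev(seq_len(d - 1L) + 1L)[seq_len(d - 1L)] else NULL))
}

par_to_psi <- function(par, d, proportional = FALSE) {
  if (proportional) return(exp(2 * par[1]) * diag(d))
  Lm <- matrix(0, d, d)
  Lm[lower.tri(Lm, diag = TRUE)] <- par
  diag(Lm) <- exp(diag(Lm))
  Lm %*% t(Lm)
}

# Negative restricted log-likelihood (constants dropped).
reml_nll <- function(par, theta, S, proportional = FALSE) {
  d <- ncol(theta)
  Psi <- par_to_psi(par, d, proportional)
  k <- nrow(theta)
  Sw <- matrix(0, d, d)
  swt <- numeric(d)
  ldet <- 0
  W <- vector("list", k)
  for (i in seq_len(k)) {
    V <- S[[i]] + Psi
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- ldet + 2 * sum(log(diag(ch)))
    Wi <- chol2inv(ch)
    W[[i]] <- Wi
    Sw <- Sw + Wi
    swt <- swt + Wi %*% theta[i, ]
  }
  chS <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(chS)) return(1e10)
  beta <- chol2inv(chS) %*% swt
  quad <- 0
  for (i in seq_len(k)) {
    r <- theta[i, ] - beta
    quad <- quad + as.numeric(t(r) %*% W[[i]] %*% r)
  }
  0.5 * (ldet + 2 * sum(log(diag(chS))) + quad)
}

gls_pool <- function(theta, S, Psi) {
  d <- ncol(theta)
  Sw <- matrix(0, d, d); swt <- numeric(d)
  for (i in seq_len(nrow(theta))) {
    Wi <- solve(S[[i]] + Psi)
    Sw <- Sw + Wi
    swt <- swt + Wi %*% theta[i, ]
  }
  vc <- solve(Sw)
  vc <- (vc + t(vc)) / 2
  list(beta = as.numeric(vc %*% swt), vcov = vc)
}

new_meta_fit <- function(beta, vcov, Psi, theta, S, loglik, dropped) {
  het <- heterogeneity_stats(theta, S)
  structure(
    list(beta = beta, vcov = vcov, Psi = Psi,
         Q = het$Q, df_Q = het$df_Q, I2 = het$I2, p_Q = het$p,
         loglik_reml = loglik, k = nrow(theta), d = ncol(theta),
         theta = theta, S = S, dropped = dropped),
    class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("<meta_fit> k =", x$k, "| d =", x$d,
      "| Q =", round(x$Q, 2), "on", x$df_Q, "df",
      "| I2 =", round(x$I2, 1), "%\n")
  invisible(x)
}

as_meta_input <- function(fits) {
  if (is.list(fits) && !is.null(fits$theta)) {
    return(list(theta = fits$theta, S = fits$S, dropped = character(0)))
  }
  fl <- unclass(fits)
  attr(fl, "log") <- NULL
  ok <- vapply(fl, function(f) isTRUE(f$converged), logical(1))
  dropped <- names(fl)[!ok]
  if (length(dropped)) {
    message(length(dropped), " non-converged fit(s) excluded from pooling")
  }
  fl <- fl[ok]
  # canonical ordering: pooling is then bit-identical under permutation of
  # the input list
  ord <- order(vapply(fl, function(f) paste(f$community_id, f$cause,
                                            f$stratum), character(1)))
  fl <- fl[ord]
  d <- length(fl[[1]]$eta)
  stopifnot(all(vapply(fl, function(f) length(f$eta) == d, logical(1))))
  theta <- do.call(rbind, lapply(fl, function(f) unname(f$eta)))
  S <- lapply(fl, function(f) unname(f$vcov))
  list(theta = theta, S = S, dropped = dropped)
}

#' Cochran's Q, its degrees of freedom, and I-squared
#'
#' Q is the weighted residual sum of squares of the study coefficients
#' about the fixed-effect (inverse-variance) pooled solution, with
#' community-specific weight matrices \eqn{S_i^{-1}}; df = d(k-1);
#' I2 = max(0, (Q - df)/Q) x 100. An I2 of 40% or more is conventionally
#' read as moderate-or-strong inconsistency.
#'
#' @param fits As in [mvmeta_reml()].
#' @return Tibble with `Q`, `df_Q`, `I2`, `p_value`, `k`, `d`.
#' @export
heterogeneity <- function(fits) {
  dat <- as_meta_input(fits)
  het <- heterogeneity_stats(dat$theta, dat$S)
  tibble::tibble(Q = het$Q, df_Q = het$df_Q, I2 = het$I2,
                 p_value = het$p, k = nrow(dat$theta), d = ncol(dat$theta))
}

heterogeneity_stats <- function(theta, S) {
  k <- nrow(theta); d <- ncol(theta)
  if (k < 2L) return(list(Q = NA_real_, df_Q = NA_integer_,
                          I2 = NA_real_, p = NA_real_))
  fe <- gls_pool(theta, S, matrix(0, d, d))
  Q <- 0
  for (i in seq_len(k)) {
    r <- theta[i, ] - fe$beta
    Q <- Q + as.numeric(t(r) %*% solve(S[[i]]) %*% r)
  }
  df_Q <- d * (k - 1L)
  I2 <- max(0, (Q - df_Q) / Q) * 100
  list(Q = Q, df_Q = df_Q, I2 = I2,
       p = stats::pchisq(Q, df_Q, lower.tail = FALSE))
}

#' Pool stage-1 fits within groups of communities
#'
#' Runs one meta-analysis per group (country, climate type, population
#' density tertile, socioeconomic half, ...). Groups with a single
#' community pass through on the degenerate path with a warning; empty
#' groups are omitted.
#'
#' @param fits A `stage1_fits` list.
#' @param groups Named character vector or data frame (`community_id`,
#'   `group`) mapping communities to groups.
#' @return Tibble: `group`, `k`, `Q`, `df_Q`, `I2`, `p_value` and a
#'   list-column `fit` of `meta_fit` objects.
#' @export
pool_by_grouping <- function(fits, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$community_id)
  }
  fl <- unclass(fits); attr(fl, "log") <- NULL
  ids <- vapply(fl, function(f) f$community_id, character(1))
  gvals <- groups[ids]
  out <- list()
  for (g in sort(unique(stats::na.omit(gvals)))) {
    sub <- fl[which(gvals == g)]
    if (!length(sub)) next
    mf <- suppressWarnings(mvmeta_reml(structure(sub, class = "stage1_fits")))
    out[[g]] <- tibble::tibble(group = g, k = mf$k, Q = mf$Q, df_Q = mf$df_Q,
                               I2 = mf$I2, p_value = mf$p_Q, fit = list(mf))
  }
  dplyr::bind_rows(out)
}

#' Cut a numeric community covariate into meta-analysis groups
#'
#' `tertile` mirrors the population-density grouping (three groups of
#' near-equal size); `median` the socioeconomic lower/higher split.
#'
#' @param x Numeric vector.
#' @param type `"tertile"` or `"median"`.
#' @return Character vector of group labels.
#' @export
cut_groups <- function(x, type = c("tertile", "median")) {
  type <- match.arg(type)
  if (type == "median") {
    return(ifelse(x <= stats::median(x), "lower", "higher"))
  }
  q <- stats::quantile(x, c(1, 2) / 3, type = 1)
  labs <- c("low", "middle", "high")
  labs[1L + (x > q[1]) + (x > q[2])]
}

#' Effect-modification meta-regression across community strata
#'
#' Pools the stage-1 coefficients separately per level of a community-level
#' modifier and tests each level against the reference on the derived
#' cumulative log relative risk (a Wald contrast): mode `"random"` uses a
#' random-effects pool per level (modifiers compared across different
#' populations); mode `"fixed"` pools with Psi = 0 (severity strata
#' estimated on the same populations).
#'
#' @param fits A `stage1_fits` list.
#' @param modifier Named character vector or data frame (`community_id`,
#'   `level`) assigning each community a modifier level.
#' @param spec The flood [crossbasis_spec()] used in stage 1 (needed to
#'   form the cumulative-log-RR contrast).
#' @param mode `"random"` or `"fixed"`.
#' @param reference Reference level (default: first sorted level).
#' @return Tibble: `level`, `k`, `cum_rr`, `ci_low`, `ci_high`,
#'   `p_difference` (NA for the reference and for estimate-only levels),
#'   plus a list-column `fit`.
#' @export
meta_regression <- function(fits, modifier, spec, mode = c("random", "fixed"),
                            reference = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(modifier)) {
    modifier <- stats::setNames(as.character(modifier$level),
                                modifier$community_id)
  }
  fl <- unclass(fits); attr(fl, "log") <- NULL
  ids <- vapply(fl, function(f) f$community_id, character(1))
  lev <- modifier[ids]
  if (anyNA(lev)) stop("modifier level missing for some communities")
  levels_ <- sort(unique(lev))
  if (is.null(reference)) reference <- levels_[1]
  stopifnot(reference %in% levels_)
  wsum <- colSums(lag_basis(spec))  # cumulative contrast vector (one level)
  per_level <- list()
  for (g in levels_) {
    sub <- structure(fl[lev == g], class = "stage1_fits")
    if (length(sub) < 1L) next
    mf <- if (length(sub) == 1L || mode == "fixed") {
      pool_fixed_or_single(sub, mode)
    } else {
      suppressWarnings(mvmeta_reml(sub))
    }
    est <- cum_logrr_level(mf, spec, wsum)
    per_level[[g]] <- list(fit = mf, est = est, k = mf$k)
  }
  ref <- per_level[[reference]]
  out <- lapply(names(per_level), function(g) {
    pl <- per_level[[g]]
    p <- NA_real_
    if (g != reference && pl$k >= 2L && ref$k >= 2L) {
      z <- (pl$est$log_rr - ref$est$log_rr) /
        sqrt(pl$est$var + ref$est$var)
      p <- 2 * stats::pnorm(-abs(z))
    }
    tibble::tibble(level = g, k = pl$k,
                   cum_rr = exp(pl$est$log_rr),
                   ci_low = exp(pl$est$log_rr - 1.96 * sqrt(pl$est$var)),
                   ci_high = exp(pl$est$log_rr + 1.96 * sqrt(pl$est$var)),
                   p_difference = p, fit = list(pl$fit))
  })
  dplyr::bind_rows(out)
}

pool_fixed_or_single <- function(fits, mode) {
  dat <- as_meta_input(fits)
  d <- ncol(dat$theta)
  if (nrow(dat$theta) == 1L) {
    warning("level with a single community: estimate only, no test")
    return(new_meta_fit(beta = dat$theta[1, ], vcov = dat$S[[1]],
                        Psi = matrix(0, d, d), theta = dat$theta, S = dat$S,
                        loglik = NA_real_, dropped = dat$dropped))
  }
  fe <- gls_pool(dat$theta, dat$S, matrix(0, d, d))
  new_meta_fit(beta = fe$beta, vcov = fe$vcov, Psi = matrix(0, d, d),
               theta = dat$theta, S = dat$S, loglik = NA_real_,
               dropped = dat$dropped)
}

# Cumulative log RR and its variance for the first exposure level.
cum_logrr_level <- function(meta, spec, wsum = colSums(lag_basis(spec))) {
  vl <- length(wsum)
  w <- rep(0, meta$d)
  w[seq_len(vl)] <- wsum
  list(log_rr = sum(w * meta$beta),
       var = as.numeric(t(w) %*% meta$vcov %*% w))
}
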