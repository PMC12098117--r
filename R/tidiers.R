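#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a community-level fit
#'
#' @param x A `stage1_fit`.
#' @param ... Unused.
#' @return Tibble with one row per flood cross-basis coefficient: `term`,
#'   `estimate`, `std.error`.
#' @method tidy stage1_fit
#' @export
tidy.stage1_fit <- function(x, ...) {
  tibble::tibble(
    community_id = x$community_id, cause = x$cause, stratum = x$stratum,
    term = names(x$eta), estimate = unname(x$eta),
    std.error = sqrt(pmax(0, diag(x$vcov))))
}

#' @rdname tidy.stage1_fit
#' @method glance stage1_fit
#' @export
glance.stage1_fit <- function(x, ...) {
  tibble::tibble(
    community_id = x$community_id, cause = x$cause, stratum = x$stratum,
    dispersion = x$dispersion, n_days = x$n_days, converged = x$converged)
}

#' @rdname tidy.stage1_fit
#' @method tidy stage1_fits
#' @export
tidy.stage1_fits <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @rdname tidy.stage1_fit
#' @method glance stage1_fits
#' @export
glance.stage1_fits <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}

#' Tidy a pooled meta-analytic fit
#'
#' @param x A `meta_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per pooled coefficient with `estimate`,
#'   `std.error`, `conf.low`, `conf.high`. `glance()`: one row with `k`,
#'   `d`, `Q`, `df_Q`, `I2`, `p_Q`, `loglik_reml`, `tr_Psi`.
#' @method tidy meta_fit
#' @export
tidy.meta_fit <- function(x, ...) {
  se <- sqrt(pmax(0, diag(x$vcov)))
  tibble::tibble(
    term = paste0("eta", seq_along(x$beta)),
    estimate = x$beta, std.error = se,
    conf.low = x$beta - 1.96 * se, conf.high = x$beta + 1.96 * se)
}

#' @rdname tidy.meta_fit
#' @method glance meta_fit
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(k = x$k, d = x$d, Q = x$Q, df_Q = x$df_Q, I2 = x$I2,
                 p_Q = x$p_Q, loglik_reml = x$loglik_reml,
                 tr_Psi = sum(diag(x$Psi)))
}
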