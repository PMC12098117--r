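#' Natural cubic spline basis
#'
#' Thin wrapper around [splines::ns()] that fixes the boundary knots
#' explicitly and validates its inputs. Natural cubic splines are linear
#' beyond the boundary knots, which keeps lag-response tails from exploding
#' at the end of long lag windows.
#'
#' @param x Numeric vector of evaluation points.
#' @param df Integer, number of basis columns (>= 1).
#' @param boundary Length-2 numeric, boundary knots; defaults to `range(x)`.
#' @param knots Optional interior knots. When supplied, `df` is ignored and
#'   the dimension is `length(knots) + 1`.
#' @return Numeric matrix with one row per element of `x`.
#' @export
ns_basis <- function(x, df = 4L, boundary = range(x), knots = NULL) {
  stopifnot(is.numeric(x), length(boundary) == 2L, boundary[1] < boundary[2])
  if (is.null(knots)) {
    stopifnot(df >= 1L)
    if (length(unique(x)) < df) {
      warning("fewer distinct x values than df; basis may be rank-deficient")
    }
    # interior knots at quantiles of x; for heavily tied exposures (e.g.
    # zero-inflated precipitation) quantiles can collapse onto a boundary,
    # in which case fall back to equal spacing over the boundary span
    nk <- df - 1L
    if (nk > 0L) {
      kq <- unname(stats::quantile(x, seq_len(nk) / (nk + 1L), type = 7))
      if (anyDuplicated(kq) || any(kq <= boundary[1]) || any(kq >= boundary[2])) {
        kq <- seq(boundary[1], boundary[2], length.out = nk + 2L)[-c(1L, nk + 2L)]
      }
      B <- splines::ns(x, knots = kq, Boundary.knots = boundary)
    } else {
      B <- splines::ns(x, df = 1L, Boundary.knots = boundary)
    }
  } else {
    B <- splines::ns(x, knots = knots, Boundary.knots = boundary)
  }
  B <- unclass(B)
  attributes(B)[c("degree", "intercept", "class")] <- NULL
  colnames(B) <- paste0("ns", seq_len(ncol(B)))
  B
}

#' Cyclic cubic B-spline basis for day of year
#'
#' Periodic basis used to absorb seasonality. Knots are equally spaced over
#' the annual cycle (period 366 days so leap years evaluate inside the
#' period); days outside \[0, 366\] are wrapped before evaluation, so the
#' basis value for day 367 equals day 1 by construction and to machine
#' precision.
#'
#' @param day_of_year Integer vector (usually 1..366).
#' @param n_knots Number of equally spaced knots (>= 3); the basis has
#'   `n_knots` columns.
#' @return Numeric matrix, `length(day_of_year)` rows by `n_knots` columns.
#' @export
cyclic_basis <- function(day_of_year, n_knots = 3L) {
  stopifnot(is.numeric(day_of_year))
  if (n_knots < 3L) stop("cyclic basis needs at least 3 knots")
  period <- 366
  kn <- seq(0, period, length.out = n_knots + 1L)
  x <- as.numeric(day_of_year) %% period
  B <- mgcv::cSplineDes(x, knots = kn)
  colnames(B) <- paste0("cyc", seq_len(ncol(B)))
  B
}

#' Cubic B-spline basis for long-term trend
#'
#' @param date_index Integer day index, contiguous over the study span.
#' @param df Number of columns (>= 1; cubic, so interior knots are added
#'   once `df > 3`).
#' @return Numeric matrix with `df` columns.
#' @export
trend_basis <- function(date_index, df = 3L) {
  stopifnot(df >= 1L)
  d <- diff(sort(unique(date_index)))
  if (length(d) && any(d != 1)) stop("date_index must be contiguous")
  B <- splines::bs(date_index, df = df)
  B <- unclass(B)
  attributes(B)[c("degree", "knots", "Boundary.knots", "intercept", "class")] <- NULL
  colnames(B) <- paste0("trend", seq_len(ncol(B)))
  B
}

#' Strata (indicator) basis for flood exposure
#'
#' Level 0 (not exposed) is the reference and maps to an all-zero row;
#' levels 1..(n_levels-1) map to indicator columns. With `n_levels = 3`
#' the columns are lower-severity and higher-severity flooded days.
#'
#' @param exposure_code Integer vector with values in `0:(n_levels - 1)`.
#' @param n_levels 2 (not exposed / exposed) or 3 (adds severity split).
#' @return Indicator matrix with `n_levels - 1` columns.
#' @export
strata_basis <- function(exposure_code, n_levels = 2L) {
  stopifnot(n_levels %in% c(2L, 3L))
  code <- as.integer(exposure_code)
  if (anyNA(code) || any(code < 0L) || any(code >= n_levels)) {
    stop("exposure_code values must lie in 0:", n_levels - 1L)
  }
  B <- vapply(seq_len(n_levels - 1L), function(lev) as.numeric(code == lev),
              numeric(length(code)))
  B <- matrix(B, ncol = n_levels - 1L)
  colnames(B) <- paste0("strata", seq_len(ncol(B)))
  B
}

#' Specify a cross-basis (exposure dimension x lag dimension)
#'
#' The cross-basis is the tensor product of a basis in the exposure
#' dimension and a basis in the lag dimension; its coefficients encode the
#' full exposure-lag-response surface of a distributed lag non-linear model.
#'
#' For flood exposure the exposure dimension is a strata basis (reference:
#' not exposed), so it carries no intercept. The lag dimension is a natural
#' cubic spline with an intercept column and interior knots equally spaced
#' on the log-lag scale, the usual convention for long lag windows: it
#' concentrates flexibility at short lags where risk changes fastest.
#'
#' @param max_lag Maximum lag in days (flood default 210; weather
#'   cross-bases typically 21 and 14).
#' @param exposure Either `"strata"` or `"ns"`.
#' @param exposure_levels For strata: number of exposure levels (2 or 3).
#' @param exposure_df For `"ns"`: spline df in the exposure dimension.
#' @param exposure_boundary For `"ns"`: boundary knots in the exposure
#'   dimension (defaults to the data range at build time).
#' @param lag_df Dimension of the lag basis, counting the intercept column
#'   when `lag_intercept` is `TRUE` (flood default 4).
#' @param lag_intercept Keep an intercept column in the lag dimension?
#' @param lag_knots Optional explicit interior lag knots, overriding the
#'   log-spaced rule.
#' @return An object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(max_lag,
                            exposure = c("strata", "ns"),
                            exposure_levels = 2L,
                            exposure_df = 3L,
                            exposure_boundary = NULL,
                            lag_df = 4L,
                            lag_intercept = TRUE,
                            lag_knots = NULL) {
  exposure <- match.arg(exposure)
  stopifnot(max_lag >= 0L, lag_df >= 1L)
  if (exposure == "strata") stopifnot(exposure_levels %in% c(2L, 3L))
  structure(
    list(max_lag = as.integer(max_lag), exposure = exposure,
         exposure_levels = as.integer(exposure_levels),
         exposure_df = as.integer(exposure_df),
         exposure_boundary = exposure_boundary,
         lag_df = as.integer(lag_df), lag_intercept = isTRUE(lag_intercept),
         lag_knots = lag_knots),
    class = "crossbasis_spec")
}

#' @export
print.crossbasis_spec <- function(x, ...) {
  cat("<crossbasis_spec> max_lag =", x$max_lag,
      "| exposure =", x$exposure,
      if (x$exposure == "strata") paste0("(", x$exposure_levels, " levels)")
      else paste0("(df ", x$exposure_df, ")"),
      "| lag df =", x$lag_df,
      if (x$lag_intercept) "(with lag intercept)" else "(no lag intercept)",
      "\n")
  invisible(x)
}

# Interior knots equally spaced on the log-lag scale between log(1) and
# log(max_lag). nk = 0 yields no interior knots.
log_lag_knots <- function(max_lag, nk) {
  if (nk <= 0L) return(numeric(0))
  exp(seq(log(1), log(max_lag), length.out = nk + 2L))[-c(1L, nk + 2L)]
}

#' Lag-dimension basis matrix of a cross-basis
#'
#' Evaluates the lag basis at lags `0:max_lag`; used both to build the
#' cross-basis and to reconstruct lag-specific log relative risks from
#' fitted coefficients.
#'
#' @param spec A [crossbasis_spec()].
#' @return Matrix with `max_lag + 1` rows and `lag_df` columns.
#' @export
lag_basis <- function(spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  lags <- 0:spec$max_lag
  nfree <- spec$lag_df - as.integer(spec$lag_intercept)
  if (nfree == 0L && spec$lag_intercept) {
    # pure-intercept lag basis (constant effect over the window)
    B <- matrix(1, length(lags), 1L, dimnames = list(NULL, "l1"))
    return(B)
  }
  if (nfree < 1L) stop("lag_df too small for the requested intercept setting")
  knots <- spec$lag_knots
  if (is.null(knots)) knots <- log_lag_knots(spec$max_lag, nfree - 1L)
  Bs <- if (length(knots)) {
    ns_basis(lags, boundary = c(0, spec$max_lag), knots = knots)
  } else {
    splines_1col <- splines::ns(lags, df = 1, Boundary.knots = c(0, spec$max_lag))
    matrix(unclass(splines_1col), ncol = 1L, dimnames = list(NULL, "ns1"))
  }
  B <- if (spec$lag_intercept) cbind(l0 = 1, Bs) else Bs
  colnames(B) <- paste0("l", seq_len(ncol(B)))
  B
}

# Exposure-dimension basis evaluated on the observed series.
exposure_basis <- function(x, spec) {
  if (spec$exposure == "strata") {
    strata_basis(x, spec$exposure_levels)
  } else {
    bd <- spec$exposure_boundary
    if (is.null(bd)) bd <- range(x)
    ns_basis(x, df = spec$exposure_df, boundary = bd)
  }
}

#' Build a cross-basis matrix from an exposure series
#'
#' Column (j, k) at day t holds
#' \deqn{\sum_{l=0}^{L} E_j(x_{t-l}) \, B_k(l)}
#' where E is the exposure basis and B the lag basis. Rows whose full lag
#' window precedes the series start have no complete history; they are
#' either set to `NA` (default, so downstream fits drop them) or computed
#' with the missing history treated as unexposed.
#'
#' @param x Exposure series (exposure codes for strata, numeric otherwise),
#'   in time order, one value per day.
#' @param spec A [crossbasis_spec()].
#' @param incomplete `"na"` to flag rows with incomplete history, or
#'   `"truncate"` to zero-pad history before the series start.
#' @return Matrix of dimension `length(x)` by (exposure cols x lag cols),
#'   with attributes `spec`, `incomplete_rows` and column labels
#'   `v<j>.l<k>`.
#' @export
cross_basis <- function(x, spec, incomplete = c("na", "truncate")) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  incomplete <- match.arg(incomplete)
  L <- spec$max_lag
  n <- length(x)
  if (n <= L) stop("series length (", n, ") must exceed max_lag (", L, ")")
  E <- exposure_basis(x, spec)
  B <- lag_basis(spec)
  vx <- ncol(E); vl <- ncol(B)
  out <- matrix(0, n, vx * vl)
  # convolution of each exposure-basis column with each lag-basis column
  for (j in seq_len(vx)) {
    ej <- c(rep(0, L), E[, j])          # zero-padded history
    for (k in seq_len(vl)) {
      w <- B[, k]                        # weight at lag 0..L
      conv <- stats::filter(ej, w, method = "convolution", sides = 1)
      out[, (j - 1L) * vl + k] <- conv[(L + 1L):(L + n)]
    }
  }
  colnames(out) <- as.vector(t(outer(seq_len(vx), seq_len(vl),
                                     function(j, k) paste0("v", j, ".l", k))))
  inc <- seq_len(min(L, n))
  if (incomplete == "na" && L > 0L) out[inc, ] <- NA_real_
  attr(out, "spec") <- spec
  attr(out, "incomplete_rows") <- if (L > 0L) inc else integer(0)
  out
}
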