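#' Convert a flood-event table to a daily exposure code
#'
#' A day is a "flooded day" when it falls between an event's start and end
#' dates, both inclusive. When events of different severity overlap on a
#' day, the higher severity wins. Codes: 0 not exposed, 1 lower-severity
#' flooded day, 2 higher-severity flooded day; collapse to 0/1 with
#' [collapse_severity()] for the two-strata main analysis.
#'
#' @param events Data frame with columns `start`, `end` (Dates) and
#'   `severity` (`"lower"` / `"higher"`); rows outside `calendar` are
#'   clipped.
#' @param calendar Vector of consecutive Dates defining the series.
#' @return Integer vector along `calendar` with attribute `never_flooded`.
#' @export
events_to_daily_exposure <- function(events, calendar) {
  code <- integer(length(calendar))
  if (nrow(events) > 0) {
    if (!all(events$severity %in% c("lower", "higher"))) {
      stop("unknown severity label: ",
           paste(setdiff(unique(events$severity), c("lower", "higher")),
                 collapse = ", "))
    }
    if (any(events$end < events$start)) stop("event end precedes start")
    sev_code <- ifelse(events$severity == "higher", 2L, 1L)
    for (r in seq_len(nrow(events))) {
      idx <- which(calendar >= events$start[r] & calendar <= events$end[r])
      code[idx] <- pmax(code[idx], sev_code[r])
    }
  }
  attr(code, "never_flooded") <- !any(code > 0L)
  code
}

#' @rdname events_to_daily_exposure
#' @param exposure_code Integer 0/1/2 code.
#' @export
collapse_severity <- function(exposure_code) {
  out <- as.integer(exposure_code > 0L)
  attributes(out) <- attributes(exposure_code)
  out
}

#' Drop communities that never flooded
#'
#' Communities without any flooded day carry no information about the
#' flood coefficients and are excluded before stage 1.
#'
#' @param panel Daily panel with `community_id` and `exposure_code`.
#' @return The filtered panel, with attribute `exclusion_report`: a tibble
#'   listing kept/excluded community counts and the excluded ids.
#' @export
exclude_unflooded <- function(panel) {
  status <- panel |>
    dplyr::group_by(.data$community_id) |>
    dplyr::summarise(flooded = any(.data$exposure_code > 0L), .groups = "drop")
  excluded <- status$community_id[!status$flooded]
  if (all(!status$flooded)) {
    stop("no community has any flooded day; nothing to analyse")
  }
  out <- dplyr::filter(panel, !.data$community_id %in% excluded)
  attr(out, "exclusion_report") <- tibble::tibble(
    n_total = nrow(status),
    n_kept = sum(status$flooded),
    n_excluded = length(excluded),
    excluded_ids = list(excluded))
  out
}

#' Default stage-1 model specification
#'
#' Bundles the flood, temperature and precipitation cross-basis specs plus
#' trend/season/day-of-week settings. Defaults follow the standard
#' two-stage DLNM design for flood studies: flood strata exposure with a
#' natural-cubic-spline lag basis (df 4) over lags 0-210; temperature and
#' precipitation confounder cross-bases (ns df 3 in both dimensions) over
#' lags 0-21 and 0-14; cubic B-spline trend with df 3 per study span;
#' cyclic cubic B-spline with 3 equally spaced knots for day of year;
#' day-of-week indicators with Monday as reference.
#'
#' @param max_lag Flood maximum lag (days).
#' @param lag_df Flood lag-basis dimension.
#' @param severity_strata 2 (not exposed / exposed) or 3 (adds the
#'   lower/higher severity split).
#' @param temp_max_lag,precip_max_lag Confounder maximum lags (days).
#' @param trend_df Trend spline df.
#' @param season_knots Cyclic-spline knots for day of year.
#' @param keep_incomplete Keep head rows without full lag history, with
#'   truncated lag sums, instead of dropping them.
#' @return List of class `stage1_spec`.
#' @export
stage1_spec <- function(max_lag = 210L, lag_df = 4L, severity_strata = 2L,
                        temp_max_lag = 21L, precip_max_lag = 14L,
                        trend_df = 3L, season_knots = 3L,
                        keep_incomplete = FALSE) {
  stopifnot(severity_strata %in% c(2L, 3L))
  structure(
    list(flood = crossbasis_spec(max_lag, "strata",
                                 exposure_levels = severity_strata,
                                 lag_df = lag_df),
         temp = crossbasis_spec(temp_max_lag, "ns", exposure_df = 3L,
                                lag_df = 3L),
         precip = crossbasis_spec(precip_max_lag, "ns", exposure_df = 3L,
                                  lag_df = 3L),
         trend_df = as.integer(trend_df),
         season_knots = as.integer(season_knots),
         severity_strata = as.integer(severity_strata),
         keep_incomplete = isTRUE(keep_incomplete)),
    class = "stage1_spec")
}

#' Build the stage-1 design matrix for one community
#'
#' Columns: intercept, flood cross-basis, temperature cross-basis,
#' precipitation cross-basis, long-term trend B-spline, cyclic seasonal
#' spline, and six day-of-week indicators (Monday reference). Rows whose
#' flood lag window is incomplete are marked for dropping (default).
#'
#' @param series One community's daily rows, in date order, with columns
#'   `exposure_code`, `temp`, `precip`, `doy`, `dow`, `day_index`.
#' @param spec A [stage1_spec()].
#' @return List: `X` (matrix), `flood_cols` (integer positions of the flood
#'   block), `drop_rows` (rows without complete lag history).
#' @export
build_design <- function(series, spec) {
  stopifnot(inherits(spec, "stage1_spec"))
  expo <- series$exposure_code
  if (spec$severity_strata == 2L) expo <- collapse_severity(expo)
  mode <- if (spec$keep_incomplete) "truncate" else "na"
  cb_flood <- cross_basis(expo, spec$flood, incomplete = mode)
  cb_temp <- cross_basis(series$temp, spec$temp, incomplete = mode)
  cb_precip <- cross_basis(series$precip, spec$precip, incomplete = mode)
  tr <- trend_basis(series$day_index, spec$trend_df)
  # the cyclic basis is a partition of unity; drop one column so it is not
  # collinear with the intercept (the span with intercept is unchanged)
  se <- cyclic_basis(series$doy, spec$season_knots)[, -1L, drop = FALSE]
  dw <- dow_indicators(series$dow)
  X <- cbind(`(Intercept)` = 1,
             flood_block(cb_flood),
             prefix_cols(cb_temp, "temp."),
             prefix_cols(cb_precip, "precip."),
             tr, se, dw)
  drop_rows <- sort(unique(c(attr(cb_flood, "incomplete_rows"),
                             attr(cb_temp, "incomplete_rows"),
                             attr(cb_precip, "incomplete_rows"))))
  if (spec$keep_incomplete) drop_rows <- integer(0)
  flood_cols <- which(startsWith(colnames(X), "flood."))
  list(X = X, flood_cols = flood_cols, drop_rows = drop_rows)
}

# Six indicator columns for days 2..7 (1 = Monday is the reference).
dow_indicators <- function(dow) {
  stopifnot(all(dow %in% 1:7))
  B <- vapply(2:7, function(d) as.numeric(dow == d), numeric(length(dow)))
  colnames(B) <- paste0("dow", 2:7)
  B
}

flood_block <- function(cb) {
  colnames(cb) <- paste0("flood.", colnames(cb))
  cb
}
prefix_cols <- function(m, p) {
  colnames(m) <- paste0(p, colnames(m))
  m
}

#' Fit the community-level quasi-Poisson model
#'
#' Point estimates solve the Poisson score equations by iteratively
#' reweighted least squares ([stats::glm.fit()], convergence when the
#' relative deviance change is below 1e-9, at most 100 iterations); the
#' dispersion is the Pearson chi-square over residual degrees of freedom,
#' and the coefficient covariance is `phi * (X' W X)^-1` -- so point
#' estimates are identical to Poisson maximum likelihood and standard
#' errors scale by `sqrt(phi)`.
#'
#' @param y Non-negative counts.
#' @param X Design matrix (with intercept column).
#' @param flood_cols Integer positions of the flood cross-basis block.
#' @param community_id,cause,stratum Identifiers carried into the fit.
#' @return Object of class `stage1_fit`: `eta` (flood coefficients),
#'   `vcov` (their covariance), `dispersion`, `n_days`, `converged`,
#'   `coefficients` (full vector), ids.
#' @export
fit_quasipoisson <- function(y, X, flood_cols = seq_len(ncol(X)),
                             community_id = NA_character_,
                             cause = "all", stratum = "all") {
  stopifnot(all(y >= 0), nrow(X) == length(y))
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, family = stats::poisson(),
    control = stats::glm.control(epsilon = 1e-9, maxit = 100L)))
  p <- fit$rank
  n <- length(y)
  mu <- fit$fitted.values
  phi <- sum((y - mu)^2 / mu) / (n - p)
  ok <- fit$converged && fit$rank == ncol(X)
  # (X' W X)^{-1} from the final IRLS QR factorization
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  xtwxi <- tryCatch(chol2inv(Rmat), error = function(e) NULL)
  if (is.null(xtwxi)) ok <- FALSE
  vc_full <- matrix(NA_real_, ncol(X), ncol(X),
                    dimnames = list(colnames(X), colnames(X)))
  if (!is.null(xtwxi)) {
    piv <- fit$qr$pivot[seq_len(p)]
    vc_full[piv, piv] <- phi * xtwxi
  }
  eta <- fit$coefficients[flood_cols]
  vc <- vc_full[flood_cols, flood_cols, drop = FALSE]
  vc <- (vc + t(vc)) / 2
  if (any(!is.finite(vc)) ||
      (ok && kappa(vc, exact = FALSE) > 1e10)) {
    ok <- FALSE
  }
  structure(
    list(community_id = community_id, cause = cause, stratum = stratum,
         eta = eta, vcov = vc, dispersion = phi,
         n_days = n, converged = ok,
         coefficients = fit$coefficients),
    class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("<stage1_fit>", x$community_id, "| cause", x$cause, "| stratum",
      x$stratum, "| d =", length(x$eta), "| phi =", round(x$dispersion, 3),
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Run stage 1 over a panel
#'
#' Fits one quasi-Poisson DLNM per community and count column. Non-converged
#' or numerically singular fits are retained with `converged = FALSE` and
#' excluded from pooling downstream, with the reason recorded.
#'
#' @param panel Daily panel (validated; one block of contiguous days per
#'   community) with an `exposure_code` column.
#' @param spec A [stage1_spec()].
#' @param count_cols Count columns to analyse; each is reported as its own
#'   cause/stratum (the column name, minus a `count_` prefix).
#' @return List of `stage1_fit` objects with attribute `log`: a tibble of
#'   per-fit status.
#' @export
run_stage1 <- function(panel, spec = stage1_spec(), count_cols = "count") {
  stopifnot(all(count_cols %in% names(panel)))
  ids <- unique(panel$community_id)
  fits <- list()
  log <- list()
  for (id in ids) {
    series <- panel[panel$community_id == id, ]
    des <- build_design(series, spec)
    keep <- setdiff(seq_len(nrow(series)), des$drop_rows)
    for (cc in count_cols) {
      label <- sub("^count_?", "", cc)
      if (label == "") label <- "all"
      f <- fit_quasipoisson(series[[cc]][keep], des$X[keep, , drop = FALSE],
                            flood_cols = des$flood_cols,
                            community_id = id, cause = label)
      fits[[paste(id, cc, sep = ".")]] <- f
      log[[paste(id, cc, sep = ".")]] <- tibble::tibble(
        community_id = id, count_col = cc, converged = f$converged,
        dispersion = f$dispersion, n_days = f$n_days,
        reason = if (f$converged) NA_character_ else "non-converged or singular")
    }
  }
  structure(fits, log = dplyr::bind_rows(log), class = "stage1_fits")
}

#' @export
print.stage1_fits <- function(x, ...) {
  lg <- attr(x, "log")
  cat("<stage1_fits>", length(x), "fits;", sum(lg$converged), "converged\n")
  invisible(x)
}

#' Serialize stage-1 fits to JSON-lines
#'
#' One record per fit with the coefficient vector and flattened covariance,
#' the contract consumed by stage 2 when the stages run as separate
#' processes.
#'
#' @param fits A `stage1_fits` list.
#' @param path Output file.
#' @export
write_stage1_fits <- function(fits, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write stage-1 fits")
  }
  lines <- vapply(fits, function(f) {
    jsonlite::toJSON(list(
      community_id = f$community_id, cause = f$cause, stratum = f$stratum,
      eta = unname(f$eta), vcov = as.vector(f$vcov),
      dispersion = f$dispersion, n_days = f$n_days,
      converged = f$converged), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stage1_fits
#' @export
read_stage1_fits <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to read stage-1 fits")
  }
  lines <- readLines(path)
  fits <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    d <- length(rec$eta)
    structure(
      list(community_id = rec$community_id, cause = rec$cause,
           stratum = rec$stratum, eta = rec$eta,
           vcov = matrix(rec$vcov, d, d), dispersion = rec$dispersion,
           n_days = rec$n_days, converged = rec$converged,
           coefficients = NULL),
      class = "stage1_fit")
  })
  names(fits) <- vapply(fits, function(f) paste(f$community_id, f$cause,
                                                sep = "."), character(1))
  structure(fits, class = "stage1_fits")
}
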