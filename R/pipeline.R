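#' Validate a daily panel (and optional events/covariates tables)
#'
#' Schema and integrity checks run before any model fitting: required
#' columns, ISO-8601-parsable dates, per-community date contiguity without
#' duplicates, non-negative counts, event start <= end and known severity
#' labels, covariate coverage of every panel community.
#'
#' @param panel Daily panel data frame.
#' @param events Optional flood-event table.
#' @param covariates Optional community-covariates table.
#' @param count_cols Count columns that must be present and non-negative.
#' @return Invisibly, a summary tibble (communities, days, columns) when
#'   valid; otherwise an error listing every violation found.
#' @export
validate_panel <- function(panel, events = NULL, covariates = NULL,
                           count_cols = "count") {
  problems <- character(0)
  need <- c("community_id", "date", count_cols)
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    problems <- c(problems, paste("missing panel column(s):",
                                  paste(missing_cols, collapse = ", ")))
  } else {
    dates <- tryCatch(as.Date(panel$date), error = function(e) NULL,
                      warning = function(w) NULL)
    if (is.null(dates) || anyNA(dates)) {
      problems <- c(problems, "dates not parseable as ISO-8601")
    } else {
      for (id in unique(panel$community_id)) {
        d <- dates[panel$community_id == id]
        if (anyDuplicated(d)) {
          problems <- c(problems, paste0("community ", id,
                                         ": duplicated date ",
                                         d[duplicated(d)][1]))
        }
        dd <- diff(sort(d))
        if (length(dd) && any(dd != 1)) {
          problems <- c(problems, paste0("community ", id,
                                         ": dates not contiguous"))
        }
      }
    }
    for (cc in count_cols) {
      bad <- which(panel[[cc]] < 0)
      if (length(bad)) {
        problems <- c(problems,
                      paste0("negative count in '", cc, "' at row ", bad[1],
                             " (community ", panel$community_id[bad[1]], ")"))
      }
    }
  }
  if (!is.null(events) && nrow(events)) {
    if (!all(c("community_id", "start", "end", "severity") %in% names(events))) {
      problems <- c(problems, "events table missing required columns")
    } else {
      if (any(as.Date(events$end) < as.Date(events$start))) {
        problems <- c(problems, "event with end date before start date")
      }
      bad_sev <- setdiff(unique(events$severity), c("lower", "higher"))
      if (length(bad_sev)) {
        problems <- c(problems, paste("unknown severity label:",
                                      paste(bad_sev, collapse = ", ")))
      }
    }
  }
  if (!is.null(covariates)) {
    uncovered <- setdiff(unique(panel$community_id), covariates$community_id)
    if (length(uncovered)) {
      problems <- c(problems, paste("communities without covariates:",
                                    paste(utils::head(uncovered, 5),
                                          collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("panel validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(tibble::tibble(
    n_communities = length(unique(panel$community_id)),
    n_days = nrow(panel),
    count_cols = paste(count_cols, collapse = ",")))
}

#' Run the full two-stage flood-hospitalization pipeline
#'
#' simulate/load -> daily exposure coding -> exclusion of never-flooded
#' communities -> community-level quasi-Poisson DLNM fits -> multivariate
#' REML pooling -> lag-response curve, cumulative RR, heterogeneity, and
#' attributable fraction. Deterministic given the inputs and seed.
#'
#' @param panel Daily panel (e.g. from [generate_panel()]); must contain
#'   `exposure_code` or be accompanied by `events`.
#' @param events Optional flood-event table used to derive `exposure_code`
#'   when the panel lacks it.
#' @param spec A [stage1_spec()].
#' @param count_cols Count columns to analyse (each pooled separately).
#' @param af_draws,af_seed Monte-Carlo settings for the attributable
#'   fraction empirical CI.
#' @param covariates Optional community covariates; when given, pooled
#'   results by country are added.
#' @return List of class `flood_pipeline`: per-cause tibbles `cum_rr`,
#'   `lag_curves`, `heterogeneity`, `af`, plus `stage1`, `meta` (list per
#'   cause), `exclusions`, `spec`.
#' @export
run_flood_pipeline <- function(panel, events = NULL, spec = stage1_spec(),
                               count_cols = "count", af_draws = 1000L,
                               af_seed = 1L, covariates = NULL) {
  validate_panel(panel, events, covariates, count_cols)
  panel$date <- as.Date(panel$date)
  if (!"exposure_code" %in% names(panel)) {
    if (is.null(events)) stop("panel lacks exposure_code and no events given")
    panel <- panel |>
      dplyr::group_by(.data$community_id) |>
      dplyr::group_modify(function(df, key) {
        ev <- events[events$community_id == key$community_id, ]
        df$exposure_code <- as.integer(
          events_to_daily_exposure(ev, df$date))
        df
      }) |>
      dplyr::ungroup()
  }
  if (!"burn_in" %in% names(panel)) panel$burn_in <- FALSE
  if (!"day_index" %in% names(panel)) {
    panel <- panel |>
      dplyr::group_by(.data$community_id) |>
      dplyr::mutate(day_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  if (!"doy" %in% names(panel)) {
    panel$doy <- as.integer(strftime(panel$date, "%j"))
  }
  if (!"dow" %in% names(panel)) {
    panel$dow <- as.integer(strftime(panel$date, "%u"))
  }
  panel <- exclude_unflooded(panel)
  exclusions <- attr(panel, "exclusion_report")

  fits <- run_stage1(panel, spec, count_cols = count_cols)
  fl <- unclass(fits); attr(fl, "log") <- NULL
  by_cause <- split(seq_along(fl),
                    vapply(fl, function(f) f$cause, character(1)))
  n_levels <- spec$severity_strata - 1L
  meta <- list(); cumrr <- list(); curves <- list(); het <- list(); af <- list()
  for (cause in names(by_cause)) {
    sub <- structure(fl[by_cause[[cause]]], class = "stage1_fits")
    mf <- suppressWarnings(mvmeta_reml(sub))
    meta[[cause]] <- mf
    for (lev in seq_len(n_levels)) {
      lev_lab <- if (n_levels == 1L) "exposed" else c("lower", "higher")[lev]
      cr <- cum_rr(mf, spec$flood, level = lev)
      cumrr[[paste(cause, lev_lab)]] <-
        dplyr::mutate(cr, cause = cause, level = lev_lab, .before = 1)
      lc <- lag_rr(mf, spec$flood, level = lev)
      curves[[paste(cause, lev_lab)]] <-
        dplyr::mutate(lc, cause = cause, level = lev_lab, .before = 1)
      afr <- attributable_fraction(panel, mf, spec$flood,
                                   count_col = count_col_for(cause, count_cols),
                                   n_draws = af_draws, seed = af_seed)
      af[[paste(cause, lev_lab)]] <-
        dplyr::mutate(tibble::as_tibble(afr), cause = cause,
                      level = lev_lab, .before = 1)
    }
    het[[cause]] <- dplyr::mutate(heterogeneity(sub), cause = cause,
                                  .before = 1)
  }
  by_country <- NULL
  if (!is.null(covariates) && "country" %in% names(covariates)) {
    first_cause <- names(by_cause)[1]
    sub <- structure(fl[by_cause[[first_cause]]], class = "stage1_fits")
    grp <- stats::setNames(covariates$country, covariates$community_id)
    by_country <- suppressWarnings(pool_by_grouping(sub, grp))
  }
  structure(
    list(cum_rr = dplyr::bind_rows(cumrr),
         lag_curves = dplyr::bind_rows(curves),
         heterogeneity = dplyr::bind_rows(het),
         af = dplyr::bind_rows(af),
         by_country = by_country,
         stage1 = fits, meta = meta,
         exclusions = exclusions, spec = spec),
    class = "flood_pipeline")
}

count_col_for <- function(cause, count_cols) {
  hit <- count_cols[sub("^count_?", "", count_cols) == cause |
                      (count_cols == "count" & cause == "all")]
  if (length(hit)) hit[1] else count_cols[1]
}

#' @export
print.flood_pipeline <- function(x, ...) {
  cat("<flood_pipeline>", length(x$meta), "cause(s);",
      x$exclusions$n_kept, "communities pooled (",
      x$exclusions$n_excluded, "excluded, never flooded )\n")
  print(x$cum_rr)
  invisible(x)
}

#' Write pipeline outputs as CSV files
#'
#' Emits `cum_rr.csv`, `lag_curves.csv`, `heterogeneity.csv`, `af.csv`
#' (and `by_country.csv` when present) into `dir`. Reruns with the same
#' inputs produce byte-identical files.
#'
#' @param result A `flood_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "flood_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("cum_rr", "lag_curves", "heterogeneity", "af")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(result[[nm]], p)
    paths <- c(paths, p)
  }
  if (!is.null(result$by_country)) {
    p <- file.path(dir, "by_country.csv")
    readr::write_csv(dplyr::select(result$by_country, -"fit"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a generated panel to the CSV exchange schemas
#'
#' @param sim Output of [generate_panel()].
#' @param dir Output directory.
#' @return Invisibly, the paths written (panel, events, covariates CSVs and
#'   a JSON truth sidecar).
#' @export
write_panel_csv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "panel.csv")
  pe <- file.path(dir, "events.csv")
  pc <- file.path(dir, "covariates.csv")
  readr::write_csv(sim$panel, pp)
  readr::write_csv(sim$events, pe)
  readr::write_csv(sim$covariates, pc)
  pt <- file.path(dir, "truth.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(true_cum_rr = as.list(sim$truth$true_cum_rr),
           true_af = sim$truth$true_af,
           planted_lag_curve = as.data.frame(sim$truth$planted_lag_curve)),
      pt, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(pp, pe, pc, pt))
}
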