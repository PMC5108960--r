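#' Build a pipeline run configuration
#'
#' Collects every knob of the seven-step analysis (study area, hygiene,
#' calibration, proxies, taphonomic correction, trend fitting, derivative
#' significance) into one validated list, so a run is fully described by
#' its configuration and seed.
#'
#' @param dates Path to the CARD-like CSV date table.
#' @param curve Path to the IntCal-format calibration curve.
#' @param out_dir Output directory (created if missing).
#' @param anchors Path to an anchors CSV (`site`, `lon`, `lat`) or a data
#'   frame; default the built-in [domestication_anchors()].
#' @param ellipse_scale Study-ellipse scale in standard deviations.
#' @param use_spatial_filter Apply the study-area filter (disable when the
#'   table has no usable coordinates).
#' @param step Calibration grid step, years.
#' @param taph `a`, `b`, `c` constants for [taph_model()], as a list.
#' @param bootstrap List with `n_iter` (0 disables the envelope) and
#'   `frac`.
#' @param basis_dim GAM basis dimension.
#' @param alpha Significance level for derivative intervals.
#' @param simultaneous Use simultaneous derivative intervals.
#' @param seed Integer seed for the bootstrap.
#' @param make_plot Write a trend-panel figure for the corrected KDE
#'   proxy.
#' @param dialect A [card_dialect()] for reading the date table.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dates, curve, out_dir,
                       anchors = NULL, ellipse_scale = 2,
                       use_spatial_filter = TRUE, step = 1,
                       taph = list(), bootstrap = list(n_iter = 0, frac = 0.5),
                       basis_dim = 10, alpha = 0.05, simultaneous = FALSE,
                       seed = 1, make_plot = FALSE, dialect = card_dialect()) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1).", class = "chronopop_config_error")
  cfg <- list(
    dates = dates, curve = curve, out_dir = out_dir, anchors = anchors,
    ellipse_scale = ellipse_scale, use_spatial_filter = use_spatial_filter,
    step = step,
    taph = utils::modifyList(list(a = 5726442, b = 2176.4, c = -1.3925309), taph),
    bootstrap = utils::modifyList(list(n_iter = 0, frac = 0.5), bootstrap),
    basis_dim = basis_dim, alpha = alpha, simultaneous = simultaneous,
    seed = seed, make_plot = make_plot, dialect = dialect
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file may set any argument of [run_config()]; unset keys keep their
#' defaults. `dates`, `curve` and `out_dir` are required.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list applied on top of the file (e.g. from
#'   command-line `--set key=value` pairs).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  need <- c("dates", "curve", "out_dir")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Config missing required key(s): ", paste(miss, collapse = ", ")),
      class = "chronopop_config_error"
    )
  }
  if (!is.null(raw$dialect)) raw$dialect <- do.call(card_dialect, raw$dialect)
  do.call(run_config, raw)
}

read_anchors <- function(anchors) {
  if (is.null(anchors)) {
    return(domestication_anchors())
  }
  if (is.data.frame(anchors)) {
    return(anchors)
  }
  out <- readr::read_csv(anchors, show_col_types = FALSE, progress = FALSE)
  if (!all(c("lon", "lat") %in% names(out))) {
    abort("Anchors file needs lon and lat columns.", class = "chronopop_config_error")
  }
  out
}

#' Run the full dates-as-data pipeline
#'
#' Executes the seven analysis steps in order: (1) fit the study ellipse
#' to the anchor sites, (2) read the date table and apply chronometric
#' hygiene, (3) filter records to the study area, (4) calibrate and take
#' median calibrated ages, (5) build the four population proxies,
#' (6) taphonomically correct (and optionally bootstrap) them, and
#' (7) fit GLM/GAM trends and extract significant periods of change.
#' Writes `proxies.csv`, `trend_report.json`, `report.json` and (if
#' configured) `fig_trend.png` to the output directory.
#'
#' @param config A `run_config` (or path to a YAML file for
#'   [read_run_config()]).
#' @return A `run_report` (list): hygiene report, record counts per stage,
#'   date-range and quartile summary, per-proxy fit summaries and period
#'   tables, and run provenance. Returned invisibly; also serialized to
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  anchors <- read_anchors(config$anchors)
  ell <- study_ellipse(anchors, scale = config$ellipse_scale)
  log_stage("[1/7] study ellipse from %d anchors", nrow(anchors))

  raw <- read_dates(config$dates, dialect = config$dialect)
  clean <- apply_hygiene(raw)
  hyg <- hygiene_report(clean)
  log_stage("[2/7] hygiene: %d -> %d records", hyg$n_input, hyg$n_after_anomaly)

  if (config$use_spatial_filter) {
    in_area <- filter_study_area(clean, ell)
    log_stage("[3/7] study area: %d -> %d records", nrow(clean), nrow(in_area))
  } else {
    in_area <- clean
    log_stage("[3/7] study-area filter disabled")
  }

  curve <- read_curve(config$curve)
  medians <- calibrate_batch(in_area, curve, step = config$step)
  n_failed <- nrow(attr(medians, "failed"))
  log_stage("[4/7] calibrated %d records (%d failed)", nrow(medians), n_failed)

  model <- taph_model(config$taph$a, config$taph$b, config$taph$c)
  proxies <- build_proxies(medians, model = model)
  log_stage("[5/7] built %d proxy series", dplyr::n_distinct(proxies[, c("proxy", "corrected")]))

  envelopes <- NULL
  if (config$bootstrap$n_iter > 0) {
    combos <- dplyr::distinct(proxies[, c("proxy", "corrected")])
    envelopes <- purrr::pmap(combos, function(proxy, corrected) {
      bootstrap_envelope(medians,
        proxy = proxy, corrected = corrected, model = model,
        frac = config$bootstrap$frac, n_iter = config$bootstrap$n_iter,
        alpha = config$alpha, seed = config$seed
      )
    })
    names(envelopes) <- paste0(combos$proxy, ifelse(combos$corrected, "_corrected", "_observed"))
    log_stage(
      "[6/7] taphonomic correction + bootstrap envelopes (%d iterations)",
      config$bootstrap$n_iter
    )
  } else {
    log_stage("[6/7] taphonomic correction applied; bootstrap disabled")
  }

  analysis <- analyze_all(proxies,
    alpha = config$alpha, basis_dim = config$basis_dim,
    simultaneous = config$simultaneous
  )
  log_stage("[7/7] trend fits and derivative significance (alpha = %g)", config$alpha)

  proxies_out <- proxies
  if (!is.null(envelopes)) {
    env_tab <- purrr::imap_dfr(envelopes, function(e, nm) {
      tibble::tibble(
        cal_bp = e$cal_bp, lo = e$lo, hi = e$hi,
        proxy = attr(e, "proxy"), corrected = attr(e, "corrected")
      )
    })
    proxies_out <- dplyr::left_join(
      proxies, env_tab,
      by = c("cal_bp", "proxy", "corrected")
    )
  }
  readr::write_csv(proxies_out, file.path(config$out_dir, "proxies.csv"), progress = FALSE)

  fit_summaries <- purrr::pmap(analysis, function(proxy, corrected, glm, gam, derivative, periods, error) {
    if (!is.na(error)) {
      return(list(proxy = proxy, corrected = corrected, error = error))
    }
    list(
      proxy = proxy, corrected = corrected,
      glm = as.list(glance(glm)), gam = as.list(glance(gam)),
      periods = as.data.frame(periods)
    )
  })
  trend_report <- list(
    alpha = config$alpha, basis_dim = config$basis_dim,
    simultaneous = config$simultaneous, proxies = fit_summaries
  )
  jsonlite::write_json(trend_report, file.path(config$out_dir, "trend_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  if (config$make_plot) {
    row <- which(analysis$proxy == "kde_density" & analysis$corrected)
    if (length(row) == 1 && is.na(analysis$error[row])) {
      p <- plot_trend_panel(
        analysis$gam[[row]], analysis$derivative[[row]], analysis$periods[[row]]
      )
      ggplot2::ggsave(file.path(config$out_dir, "fig_trend.png"), p,
        width = 9, height = 5, dpi = 150
      )
    }
  }

  report <- structure(
    list(
      hygiene = hyg,
      n_in_study_area = nrow(in_area),
      n_calibrated = nrow(medians),
      n_calibration_failed = n_failed,
      date_summary = list(
        min = min(medians$median_cal_bp), max = max(medians$median_cal_bp),
        q1 = unname(quantile(medians$median_cal_bp, 0.25)),
        median = unname(quantile(medians$median_cal_bp, 0.5)),
        q3 = unname(quantile(medians$median_cal_bp, 0.75))
      ),
      alpha = config$alpha,
      fits = fit_summaries,
      provenance = list(
        package_version = as.character(utils::packageVersion("chronopop")),
        seed = config$seed,
        config_hash = rlang::hash(unclass(config))
      )
    ),
    class = "run_report"
  )
  report_json <- report
  report_json$hygiene <- list(
    n_input = hyg$n_input, n_after_dedup = hyg$n_after_dedup,
    n_after_context = hyg$n_after_context, n_after_anomaly = hyg$n_after_anomaly,
    removed = as.data.frame(hyg$removed)
  )
  jsonlite::write_json(unclass(report_json), file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("chronopop run report\n")
  cat(sprintf(
    "  hygiene: %d -> %d records\n",
    x$hygiene$n_input, x$hygiene$n_after_anomaly
  ))
  cat(sprintf("  in study area: %d; calibrated: %d\n", x$n_in_study_area, x$n_calibrated))
  cat(sprintf(
    "  median cal BP range: %.0f - %.0f (Q1 %.0f, Q3 %.0f)\n",
    x$date_summary$min, x$date_summary$max, x$date_summary$q1, x$date_summary$q3
  ))
  cat(sprintf("  derivative significance level used: alpha = %g\n", x$alpha))
  for (f in x$fits) {
    if (!is.null(f$error)) {
      cat(sprintf(
        "  %s (%s): FAILED: %s\n", f$proxy,
        if (f$corrected) "corrected" else "observed", f$error
      ))
      next
    }
    per <- f$periods
    cat(sprintf(
      "  %s (%s): GAM edf %.2f, dev.expl %.2f; %d significant period(s)\n",
      f$proxy, if (f$corrected) "corrected" else "observed",
      f$gam$edf, f$gam$pseudo_r2, nrow(per)
    ))
    if (nrow(per) > 0) {
      for (i in seq_len(nrow(per))) {
        cat(sprintf("      %s %.0f-%.0f cal BP\n", per$direction[i], per$start[i], per$end[i]))
      }
    }
  }
  invisible(x)
}
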