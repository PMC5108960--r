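#' Synthetic calibration curve
#'
#' An identity-like calibration curve with a low-amplitude sinusoidal
#' wiggle and constant curve error: \eqn{\mu(t) = t + A \sin(2\pi t / P)},
#' \eqn{\sigma(t) = \sigma}. With the default amplitude/period the curve
#' remains strictly monotone, while still exercising interpolation and the
#' non-trivial likelihood geometry of real curves. The support extends
#' beyond the analysis grid on both sides so measurement noise near the
#' grid edges stays inside the curve.
#'
#' @param cal_min,cal_max Calendar support, years cal BP.
#' @param knot_step Knot spacing in years.
#' @param amplitude Sinusoid amplitude in \eqn{^{14}}C years.
#' @param period Sinusoid period in calendar years.
#' @param sigma Constant 1-sigma curve error in years.
#' @return A [cal_curve()].
#' @export
make_synthetic_curve <- function(cal_min = -500, cal_max = 16500, knot_step = 5,
                                 amplitude = 20, period = 1200, sigma = 10) {
  grid <- seq(cal_min, cal_max, by = knot_step)
  cal_curve(grid, grid + amplitude * sin(2 * pi * grid / period), rep(sigma, length(grid)))
}

#' Idealized population scenarios
#'
#' Deterministic relative-population curves on the standard analysis grid,
#' used to generate synthetic radiocarbon records with known structure:
#'
#' * `constant`: flat population, no true change events.
#' * `exponential`: `rel_pop(t) = exp(rate * t)` (`t` in cal BP, so a
#'   negative `rate` grows toward the present).
#' * `logistic`: population rising toward the present to a plateau `K`,
#'   midpoint `t_mid`, time constant `tau` (years).
#' * `step_growth`: flat at `base` before `step_start`, flat at
#'   `base * factor` after `step_end`, log-linear ramp in between. The
#'   default doubles the population over the 1700 years from 6900 to
#'   5200 cal BP.
#' * `paper_like`: long stasis punctuated by several log-linear growth and
#'   decline windows, qualitatively mimicking an Eastern North American
#'   Holocene record.
#'
#' @param kind Scenario family.
#' @param level Constant level (kind `constant`).
#' @param rate Exponential rate per calendar year (kind `exponential`).
#' @param K,t_mid,tau Logistic parameters (kind `logistic`).
#' @param step_start,step_end,factor,base Ramp parameters (kind
#'   `step_growth`): ramp runs from `step_start` (older) to `step_end`
#'   (younger) cal BP and multiplies the population by `factor`.
#' @param grid Analysis grid.
#' @return A tibble of class `pop_scenario` with columns `cal_bp`,
#'   `rel_pop`; the known change windows are in `attr(, "true_events")`
#'   (tibble `start`, `end`, `direction`) and the scenario name in
#'   `attr(, "name")`.
#' @export
make_scenario <- function(kind = c(
                            "constant", "exponential", "logistic",
                            "step_growth", "paper_like"
                          ),
                          level = 1, rate = -1e-4,
                          K = 1, t_mid = 5000, tau = 800,
                          step_start = 6900, step_end = 5200, factor = 2, base = 1,
                          grid = cal_grid()) {
  kind <- match.arg(kind)
  t <- grid
  ev <- tibble::tibble(start = numeric(0), end = numeric(0), direction = character(0))
  rel <- switch(kind,
    constant = {
      if (level <= 0) abort("level must be positive.", class = "chronopop_usage_error")
      rep(level, length(t))
    },
    exponential = exp(rate * t),
    logistic = {
      if (K <= 0 || tau <= 0) abort("K and tau must be positive.", class = "chronopop_usage_error")
      ev <- tibble::tibble(
        start = min(t_mid + 2 * tau, max(t)),
        end = max(t_mid - 2 * tau, min(t)),
        direction = "increase"
      )
      K / (1 + exp((t - t_mid) / tau))
    },
    step_growth = {
      if (base <= 0 || factor <= 0) {
        abort("base and factor must be positive.", class = "chronopop_usage_error")
      }
      if (step_end >= step_start) {
        abort("step_end must be younger (smaller cal BP) than step_start.",
          class = "chronopop_usage_error"
        )
      }
      ev <- tibble::tibble(
        start = step_start, end = step_end,
        direction = if (factor > 1) "increase" else "decrease"
      )
      ramp <- pmin(pmax((step_start - t) / (step_start - step_end), 0), 1)
      base * factor^ramp
    },
    paper_like = {
      events <- tibble::tibble(
        start = c(14100, 10400, 8200, 6400, 3400, 1100),
        end = c(13000, 9100, 7300, 5500, 1500, 0),
        factor = c(1.6, 1.6, 0.7, 1.6, 2.5, 0.6)
      )
      ev <- tibble::tibble(
        start = events$start, end = events$end,
        direction = ifelse(events$factor > 1, "increase", "decrease")
      )
      logp <- rep(0, length(t))
      for (i in seq_len(nrow(events))) {
        ramp <- pmin(pmax((events$start[i] - t) / (events$start[i] - events$end[i]), 0), 1)
        logp <- logp + ramp * log(events$factor[i])
      }
      exp(logp)
    }
  )
  if (any(rel <= 0)) {
    abort("Scenario produced non-positive population values.", class = "chronopop_usage_error")
  }
  out <- tibble::tibble(cal_bp = t, rel_pop = rel)
  attr(out, "true_events") <- ev
  attr(out, "name") <- kind
  class(out) <- c("pop_scenario", class(out))
  out
}

#' Sample calendar ages from a population scenario
#'
#' Draws i.i.d. calendar ages with probability proportional to
#' `rel_pop(t)`, optionally thinned by the taphonomic survival function
#' (loss applied at the sampling stage, mimicking the physical process the
#' correction inverts). Sampling is by inverse-CDF on a 1-year
#' interpolation of the scenario, with sub-year jitter.
#'
#' @param scenario A [make_scenario()] object.
#' @param n Number of dates to draw.
#' @param taph_loss Apply taphonomic thinning (default `FALSE`).
#' @param model Taphonomic model used for thinning.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` calendar ages, years cal BP.
#' @export
sample_calendar_dates <- function(scenario, n, taph_loss = FALSE,
                                  model = taph_model(), seed = NULL) {
  stopifnot(inherits(scenario, "pop_scenario"), n >= 1)
  fine <- seq(min(scenario$cal_bp), max(scenario$cal_bp), by = 1)
  w <- approx(scenario$cal_bp, scenario$rel_pop, xout = fine, ties = "ordered")$y
  if (taph_loss) w <- w * taph_survival(fine, model)
  draw <- function() {
    ages <- fine[sample.int(length(fine), n, replace = TRUE, prob = w)] +
      runif(n, -0.5, 0.5)
    pmin(pmax(ages, min(fine)), max(fine))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a radiocarbon measurement from a calendar age
#'
#' The inverse of calibration, used to generate synthetic determinations:
#' the measured \eqn{^{14}}C age is a Gaussian draw centred on the curve
#' mean at the true calendar age, with the lab error and curve error added
#' in quadrature.
#'
#' @param cal_age True calendar age(s), years cal BP (inside curve
#'   support).
#' @param curve A [cal_curve()].
#' @param lab_error Reported 1-sigma lab error(s), years (recycled).
#' @param seed Optional integer seed.
#' @return A tibble with columns `c14_age`, `c14_error`.
#' @export
uncalibrate <- function(cal_age, curve, lab_error, seed = NULL) {
  at <- curve_at(curve, cal_age)
  lab_error <- rep_len(lab_error, length(cal_age))
  if (any(lab_error <= 0)) abort("lab_error must be positive.", class = "chronopop_usage_error")
  draw <- function() rnorm(length(cal_age), at$mu, sqrt(lab_error^2 + at$sigma^2))
  c14 <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(c14_age = pmax(c14, 0), c14_error = lab_error)
}

random_trinomials <- function(n_sites) {
  state <- sample(1:48, n_sites, replace = TRUE)
  county <- paste0(
    sample(LETTERS, n_sites, replace = TRUE),
    sample(LETTERS, n_sites, replace = TRUE)
  )
  num <- sample(1:999, n_sites, replace = TRUE)
  ids <- sprintf("%d%s%d", state, county, num)
  while (anyDuplicated(ids)) {
    d <- duplicated(ids)
    num[d] <- sample(1:9999, sum(d), replace = TRUE)
    ids <- sprintf("%d%s%d", state, county, num)
  }
  ids
}

# Uniform points inside (or on a ring outside) the ellipse, returned as
# lon/lat via the inverse of the equirectangular projection.
points_in_ellipse <- function(ellipse, n, radius_min = 0, radius_max = 1) {
  r <- sqrt(runif(n, radius_min^2, radius_max^2))
  phi <- runif(n, 0, 2 * pi)
  u <- r * cos(phi) * ellipse$scale * ellipse$sd_x
  v <- r * sin(phi) * ellipse$scale * ellipse$sd_y
  th <- ellipse$rotation
  x <- ellipse$center_x + u * cos(th) - v * sin(th)
  y <- ellipse$center_y + u * sin(th) + v * cos(th)
  tibble::tibble(lon = x / cos(ellipse$ref_lat * pi / 180), lat = y)
}

#' Generate a CARD-like synthetic radiocarbon table
#'
#' The stand-in for a restricted-database export: `n_dates` dated samples
#' whose calendar-age frequency follows a known population scenario
#' (optionally thinned by taphonomic loss), measured against a calibration
#' curve with Gaussian error, assigned to synthetic trinomial sites with
#' geometric-like size variation and per-site coordinates inside a
#' reference study ellipse. Contaminant records of the kinds that
#' chronometric hygiene and spatial filtering remove can be injected at
#' configurable rates: duplicated lab numbers, anomalous flags,
#' palaeobiological/geological contexts, incomplete trinomials, and
#' off-area coordinates.
#'
#' @param scenario A [make_scenario()] object.
#' @param n_dates Number of clean dated samples.
#' @param n_sites Number of synthetic sites.
#' @param curve Calibration curve used to "measure" the samples.
#' @param error_range Range of 1-sigma lab errors (years), sampled
#'   uniformly per date.
#' @param taph_loss Thin the calendar ages by taphonomic survival.
#' @param model Taphonomic model for the thinning.
#' @param contamination Named list of rates in `[0, 1]`: `duplicate`,
#'   `anomalous`, `context` (fractions of `n_dates` added as contaminant
#'   records), `incomplete_trinomial` and `outside_area` (fractions of
#'   sites whose identifier is truncated / whose coordinates are placed
#'   outside the ellipse).
#' @param anchors Anchor sites defining the reference ellipse.
#' @param ellipse_scale Scale of the reference ellipse (s.d. units).
#' @param seed Integer seed; the whole table is reproducible given the
#'   same configuration and seed.
#' @return A list with elements `dates` (the record tibble, contaminants
#'   shuffled in deterministically) and `truth` (scenario name, true
#'   change windows, the clean records' true calendar ages, the
#'   contaminant manifest, and per-site metadata).
#' @export
make_card_like_table <- function(scenario, n_dates = 2000, n_sites = 400,
                                 curve = make_synthetic_curve(),
                                 error_range = c(20, 80),
                                 taph_loss = FALSE, model = taph_model(),
                                 contamination = list(),
                                 anchors = domestication_anchors(),
                                 ellipse_scale = 2, seed = NULL) {
  rates <- utils::modifyList(
    list(
      duplicate = 0, anomalous = 0, context = 0,
      incomplete_trinomial = 0, outside_area = 0
    ),
    contamination
  )
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    abort("Contamination rates must lie in [0, 1].", class = "chronopop_usage_error")
  }
  ell <- study_ellipse(anchors, scale = ellipse_scale)
  build <- function() {
    ages <- sample_calendar_dates(scenario, n_dates, taph_loss = taph_loss, model = model)
    meas <- uncalibrate(ages, curve, runif(n_dates, error_range[1], error_range[2]))
    site_ids <- random_trinomials(n_sites)
    # geometric site-size variation: a few rich sites, many small ones
    sizes <- stats::rgeom(n_sites, prob = 1 / 5) + 1
    site_of <- sample.int(n_sites, n_dates, replace = TRUE, prob = sizes)
    coords <- points_in_ellipse(ell, n_sites, 0, 0.98)
    n_out <- round(rates$outside_area * n_sites)
    if (n_out > 0) {
      out_sites <- sample.int(n_sites, n_out)
      coords[out_sites, ] <- points_in_ellipse(ell, n_out, 1.1, 1.6)
    } else {
      out_sites <- integer(0)
    }
    shown_id <- site_ids
    n_inc <- round(rates$incomplete_trinomial * n_sites)
    if (n_inc > 0) {
      inc_sites <- sample.int(n_sites, n_inc)
      shown_id[inc_sites] <- sub("[0-9]+$", "", site_ids[inc_sites])
    } else {
      inc_sites <- integer(0)
    }
    clean <- tibble::tibble(
      lab_id = sprintf("SIM-%05d", seq_len(n_dates)),
      c14_age = meas$c14_age,
      c14_error = meas$c14_error,
      site_id = shown_id[site_of],
      lon = coords$lon[site_of],
      lat = coords$lat[site_of],
      context = "archaeological",
      anomalous = FALSE,
      true_cal_bp = ages
    )
    contam <- list()
    n_dup <- round(rates$duplicate * n_dates)
    if (n_dup > 0) {
      dup <- clean[sample.int(n_dates, n_dup, replace = FALSE), , drop = FALSE]
      contam$duplicate <- dup
    }
    extra_record <- function(k, context, anomalous, prefix) {
      ages_k <- sample_calendar_dates(scenario, k, taph_loss = taph_loss, model = model)
      meas_k <- uncalibrate(ages_k, curve, runif(k, error_range[1], error_range[2]))
      s_k <- sample.int(n_sites, k, replace = TRUE, prob = sizes)
      tibble::tibble(
        lab_id = sprintf("%s-%05d", prefix, seq_len(k)),
        c14_age = meas_k$c14_age,
        c14_error = meas_k$c14_error,
        site_id = shown_id[s_k],
        lon = coords$lon[s_k],
        lat = coords$lat[s_k],
        context = context,
        anomalous = anomalous,
        true_cal_bp = ages_k
      )
    }
    n_anom <- round(rates$anomalous * n_dates)
    if (n_anom > 0) {
      contam$anomalous <- extra_record(n_anom, "archaeological", TRUE, "ANOM")
    }
    n_ctx <- round(rates$context * n_dates)
    if (n_ctx > 0) {
      ctx <- extra_record(n_ctx, "archaeological", FALSE, "CTX")
      ctx$context <- sample(c("palaeobiological", "geological"), n_ctx, replace = TRUE)
      contam$context <- ctx
    }
    all_rows <- dplyr::bind_rows(c(list(clean = clean), contam), .id = "origin")
    all_rows <- all_rows[sample.int(nrow(all_rows)), , drop = FALSE]
    dates <- all_rows[, c(
      "lab_id", "c14_age", "c14_error", "site_id", "lon", "lat",
      "context", "anomalous"
    )]
    manifest <- tibble::tibble(
      lab_id = all_rows$lab_id[all_rows$origin != "clean"],
      kind = all_rows$origin[all_rows$origin != "clean"]
    )
    list(
      dates = dates,
      truth = list(
        scenario = attr(scenario, "name"),
        true_events = attr(scenario, "true_events"),
        true_cal_bp = all_rows$true_cal_bp[all_rows$origin == "clean"][
          order(all_rows$lab_id[all_rows$origin == "clean"])
        ],
        n_clean = n_dates,
        manifest = manifest,
        sites = tibble::tibble(
          site_id = site_ids, shown_id = shown_id,
          lon = coords$lon, lat = coords$lat,
          incomplete = seq_len(n_sites) %in% inc_sites,
          outside = seq_len(n_sites) %in% out_sites
        ),
        ellipse = ell
      )
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
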