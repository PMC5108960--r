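#' The standard analysis grid
#'
#' Calendar years BP from 0 to 15,000 in 100-year steps (151 points), the
#' grid on which all population proxies are sampled.
#'
#' @return A numeric vector of length 151.
#' @export
cal_grid <- function() seq(0, 15000, by = 100)

new_grid_series <- function(cal_bp, value, proxy, corrected, n_dates = NA_integer_) {
  out <- tibble::tibble(
    cal_bp = cal_bp, value = value,
    proxy = proxy, corrected = corrected
  )
  attr(out, "n_dates") <- n_dates
  class(out) <- c("grid_series", class(out))
  out
}

check_grid_series <- function(series) {
  stopifnot(is.data.frame(series))
  need <- c("cal_bp", "value", "proxy", "corrected")
  if (!all(need %in% names(series))) {
    abort(
      paste0("A grid series needs columns ", paste(need, collapse = ", "), "."),
      class = "chronopop_usage_error"
    )
  }
  if (length(unique(series$proxy)) != 1 || length(unique(series$corrected)) != 1) {
    abort("Expected a single proxy series; got a mixed table.",
      class = "chronopop_usage_error"
    )
  }
  invisible(series)
}

#' Sheather-Jones plug-in bandwidth
#'
#' Solve-the-equation Sheather-Jones bandwidth for a Gaussian kernel, the
#' bandwidth selector used for the date-density proxy.
#'
#' @param medians Numeric vector of median calibrated ages (years cal BP);
#'   at least 10 distinct values.
#' @return Bandwidth in years.
#' @export
sj_bandwidth <- function(medians) {
  medians <- medians[is.finite(medians)]
  if (length(unique(medians)) < 10) {
    abort("Sheather-Jones bandwidth needs at least 10 distinct values.",
      class = "chronopop_degenerate_error"
    )
  }
  # default search interval of the selector; fine pairwise-distance binning
  # and a tight root tolerance so discretization error stays well below
  # bandwidth precision
  n <- length(medians)
  hmax <- 1.144 * sqrt(stats::var(medians)) * n^(-1 / 5)
  stats::bw.SJ(medians,
    method = "ste", nb = 10000L, lower = 0.1 * hmax, upper = hmax,
    tol = 1e-4 * hmax
  )
}

#' Kernel density proxy of median calibrated dates
#'
#' Gaussian kernel density estimate of the median calibrated ages,
#' evaluated at each point of the analysis grid. Density units are
#' 1/years; no boundary correction is applied at either end of the grid.
#'
#' @param medians Median calibrated ages, years cal BP.
#' @param bw Bandwidth in years; defaults to [sj_bandwidth()] of the data.
#' @param grid Evaluation grid, default [cal_grid()].
#' @return A `grid_series` tibble (`proxy = "kde_density"`,
#'   `corrected = FALSE`) carrying the sample size in `attr(, "n_dates")`.
#' @export
kde_series <- function(medians, bw = NULL, grid = cal_grid()) {
  medians <- medians[is.finite(medians)]
  if (length(medians) == 0) {
    abort("No dates to estimate a density from.", class = "chronopop_usage_error")
  }
  bw <- bw %||% sj_bandwidth(medians)
  if (bw <= 0) abort("Bandwidth must be positive.", class = "chronopop_usage_error")
  value <- vapply(grid, function(g) mean(dnorm(g, mean = medians, sd = bw)), numeric(1))
  out <- new_grid_series(grid, value,
    proxy = "kde_density", corrected = FALSE,
    n_dates = length(medians)
  )
  attr(out, "bw") <- bw
  out
}

#' Validate Smithsonian trinomials
#'
#' A complete trinomial has all three parts: a 1-2 digit state number, a
#' county abbreviation of letters, and a site number (e.g. `40CF111`).
#'
#' @param site_id Character vector of site identifiers.
#' @return Logical vector, `TRUE` for complete trinomials.
#' @export
is_complete_trinomial <- function(site_id) {
  !is.na(site_id) & grepl("^\\s*[0-9]{1,2}[A-Za-z]{2,3}[0-9]+\\s*$", site_id)
}

#' Dated-site-count proxy
#'
#' Number of distinct sites with at least one median calibrated date in
#' each 100-year interval of the analysis grid. Bins are half-open
#' `[t, t+100)` labelled by their lower edge; the final bin (15,000) is
#' closed above. Only rows whose site identifier is a complete Smithsonian
#' trinomial are counted, and a site is counted at most once per bin
#' however many of its dates fall there (but is counted again in every
#' other bin it is dated to).
#'
#' @param medians A data frame with columns `site_id` and `median_cal_bp`
#'   (e.g. from [calibrate_batch()]).
#' @param grid Analysis grid, default [cal_grid()].
#' @param validator Function returning `TRUE` for countable site IDs;
#'   default [is_complete_trinomial()].
#' @return A `grid_series` tibble (`proxy = "site_count"`,
#'   `corrected = FALSE`).
#' @export
site_count_series <- function(medians, grid = cal_grid(),
                              validator = is_complete_trinomial) {
  stopifnot(all(c("site_id", "median_cal_bp") %in% names(medians)))
  step <- if (length(grid) > 1) grid[2] - grid[1] else 100
  dat <- medians[validator(medians$site_id), , drop = FALSE]
  hi <- max(grid) + step
  dat <- dat[dat$median_cal_bp >= min(grid) & dat$median_cal_bp <= hi, , drop = FALSE]
  bin <- pmin(floor(dat$median_cal_bp / step) * step, max(grid))
  counts <- dplyr::distinct(tibble::tibble(bin = bin, site = dat$site_id)) |>
    dplyr::count(.data$bin)
  value <- counts$n[match(grid, counts$bin)]
  value[is.na(value)] <- 0
  new_grid_series(grid, as.numeric(value),
    proxy = "site_count", corrected = FALSE,
    n_dates = nrow(medians)
  )
}

#' Build the four standard population proxies
#'
#' From a table of median calibrated dates, builds the kernel-density and
#' dated-site-count proxies, each observed and taphonomically corrected:
#' four series on the 151-point analysis grid.
#'
#' @param medians A data frame with columns `site_id` and `median_cal_bp`.
#' @param model Taphonomic model for the corrected pair.
#' @param bw KDE bandwidth; default Sheather-Jones.
#' @param grid Analysis grid.
#' @return A long tibble: the four series bound by rows, with columns
#'   `cal_bp`, `value`, `proxy`, `corrected`.
#' @export
build_proxies <- function(medians, model = taph_model(), bw = NULL, grid = cal_grid()) {
  kde <- kde_series(medians$median_cal_bp, bw = bw, grid = grid)
  sites <- site_count_series(medians, grid = grid)
  out <- dplyr::bind_rows(
    kde, apply_taph_correction(kde, model),
    sites, apply_taph_correction(sites, model)
  )
  attr(out, "n_dates") <- nrow(medians)
  attr(out, "bw") <- attr(kde, "bw")
  out
}

# Pull one (proxy, corrected) series out of a long proxy table, restoring
# the n_dates attribute the trend fits use for count scaling.
pick_proxy <- function(proxies, proxy, corrected) {
  out <- proxies[proxies$proxy == proxy & proxies$corrected == corrected, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(sprintf("No %s (corrected = %s) series in table.", proxy, corrected),
      class = "chronopop_usage_error"
    )
  }
  attr(out, "n_dates") <- attr(proxies, "n_dates")
  class(out) <- unique(c("grid_series", class(out)))
  out
}

#' Bootstrap confidence envelope for a proxy
#'
#' Subsampling bootstrap: each iteration draws `floor(frac * n)` dates
#' without replacement, rebuilds the proxy from scratch (including the
#' Sheather-Jones bandwidth for the density proxy), and the envelope is
#' the pointwise `alpha/2` and `1 - alpha/2` percentile at each grid point.
#' Count-type proxies are rescaled by `1/frac` so the envelope sits on the
#' full-sample scale. The default 50% subsample over 1000 iterations
#' matches standard practice for assessing sample-size sensitivity of
#' dates-as-data proxies.
#'
#' @param medians A data frame with columns `site_id` and `median_cal_bp`.
#' @param proxy `"kde_density"` or `"site_count"`.
#' @param corrected If `TRUE`, apply the taphonomic correction inside each
#'   replicate.
#' @param model Taphonomic model (used when `corrected = TRUE`).
#' @param frac Subsample fraction in (0, 1].
#' @param n_iter Number of bootstrap iterations.
#' @param alpha Two-sided envelope level (default 0.05 for 95%).
#' @param seed Optional integer seed for reproducible resampling.
#' @param grid Analysis grid.
#' @return A tibble of class `bootstrap_envelope` with columns `cal_bp`,
#'   `lo`, `hi`; `n_iter` and `frac` are stored as attributes.
#' @export
bootstrap_envelope <- function(medians, proxy = c("kde_density", "site_count"),
                               corrected = FALSE, model = taph_model(),
                               frac = 0.5, n_iter = 1000, alpha = 0.05,
                               seed = NULL, grid = cal_grid()) {
  proxy <- match.arg(proxy)
  if (n_iter < 1) abort("n_iter must be >= 1.", class = "chronopop_usage_error")
  if (frac <= 0 || frac > 1) abort("frac must be in (0, 1].", class = "chronopop_usage_error")
  n <- nrow(medians)
  m <- floor(frac * n)
  if (m < 2) {
    abort("Subsample size frac * n must be at least 2.", class = "chronopop_usage_error")
  }
  build <- function(dat) {
    s <- if (proxy == "kde_density") {
      kde_series(dat$median_cal_bp, grid = grid)
    } else {
      site_count_series(dat, grid = grid)
    }
    if (corrected) s <- apply_taph_correction(s, model)
    v <- s$value
    if (proxy == "site_count") v <- v / frac
    v
  }
  run <- function() {
    reps <- matrix(NA_real_, nrow = length(grid), ncol = n_iter)
    for (b in seq_len(n_iter)) {
      idx <- sample.int(n, m, replace = FALSE)
      reps[, b] <- build(medians[idx, , drop = FALSE])
    }
    reps
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  qs <- apply(reps, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- tibble::tibble(cal_bp = grid, lo = qs[1, ], hi = qs[2, ])
  attr(out, "n_iter") <- n_iter
  attr(out, "frac") <- frac
  attr(out, "alpha") <- alpha
  attr(out, "proxy") <- proxy
  attr(out, "corrected") <- corrected
  class(out) <- c("bootstrap_envelope", class(out))
  out
}
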