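# Internal time axis: calendar-forward years, t = -cal_bp, so that a
# positive slope means population increase toward the present.

# Response used by the count-family fits. KDE densities are rescaled to
# expected counts per 100-yr bin (density * n_dates * 100); site counts are
# used as-is. Quasi-likelihood absorbs any remaining scale.
trend_response <- function(series) {
  y <- series$value
  if (series$proxy[1] == "kde_density") {
    n <- attr(series, "n_dates")
    step <- if (nrow(series) > 1) abs(series$cal_bp[2] - series$cal_bp[1]) else 100
    sc <- if (!is.null(n) && is.finite(n)) n * step else step
    y <- y * sc
  }
  y
}

new_trend_fit <- function(model, kind, series, y, edf, pseudo_r2, r2_adj, dispersion,
                          basis_dim = NA_integer_) {
  grid <- tibble::tibble(
    cal_bp = series$cal_bp,
    t = -series$cal_bp,
    y = y
  )
  pr <- predict(model, newdata = data.frame(t = grid$t), type = "link", se.fit = TRUE)
  grid$fitted <- exp(as.numeric(pr$fit))
  grid$se_fit <- as.numeric(pr$se.fit)
  z <- qnorm(0.975)
  grid$lo <- exp(as.numeric(pr$fit) - z * grid$se_fit)
  grid$hi <- exp(as.numeric(pr$fit) + z * grid$se_fit)
  grid <- dplyr::arrange(grid, .data$cal_bp) # grid-series convention
  structure(
    list(
      model = model, kind = kind, grid = grid,
      proxy = series$proxy[1], corrected = series$corrected[1],
      edf = edf, pseudo_r2 = pseudo_r2, r2_adj = r2_adj,
      dispersion = dispersion, basis_dim = basis_dim
    ),
    class = "trend_fit"
  )
}

check_series_for_fit <- function(series) {
  check_grid_series(series)
  if (sum(is.finite(series$value)) < 3) {
    abort("Trend fitting needs at least 3 finite grid values.",
      class = "chronopop_usage_error"
    )
  }
  if (all(series$value == 0)) {
    abort("All-zero series: trend fit is degenerate.",
      class = "chronopop_degenerate_error"
    )
  }
  invisible(series)
}

#' Global (log-linear) trend fit of a proxy
#'
#' Quasi-Poisson GLM of the proxy value on calendar time with a log link
#' and a single linear time term: the "global" exponential trend model.
#' Dispersion is estimated from the Pearson statistic, so significance is
#' invariant to a positive rescaling of the series.
#'
#' @param series A `grid_series` (one proxy, observed or corrected).
#' @return A `trend_fit` object (`kind = "glm"`): fitted values and
#'   pointwise 95% intervals on the response scale, deviance-explained
#'   `pseudo_r2`, and the dispersion estimate. See [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_glm <- function(series) {
  check_series_for_fit(series)
  series <- dplyr::arrange(series, dplyr::desc(.data$cal_bp))
  y <- trend_response(series)
  dat <- data.frame(y = y, t = -series$cal_bp)
  m <- glm(y ~ t, family = quasipoisson(link = "log"), data = dat)
  s <- summary(m)
  new_trend_fit(
    m, "glm", series, y,
    edf = 2,
    pseudo_r2 = 1 - m$deviance / m$null.deviance,
    r2_adj = NA_real_,
    dispersion = s$dispersion
  )
}

#' Local (penalized-spline) trend fit of a proxy
#'
#' Quasi-Poisson GAM of the proxy value on calendar time: a penalized
#' regression spline with log link, smoothness selected by minimizing the
#' generalized cross-validation (GCV) score. Reports the effective degrees
#' of freedom (edf) of the smooth, deviance explained (`pseudo_r2`), the
#' adjusted variance-based r-squared, and the quasi-likelihood dispersion.
#'
#' @param series A `grid_series`.
#' @param basis_dim Maximum basis dimension `k` of the smooth (default 10,
#'   allowing edf up to about 9).
#' @param sp Optional fixed smoothing parameter; `NULL` (default) selects
#'   it by GCV. A very large value forces the smooth into its linear null
#'   space, reproducing the global GLM fit.
#' @return A `trend_fit` object (`kind = "gam"`).
#' @export
fit_gam <- function(series, basis_dim = 10, sp = NULL) {
  check_series_for_fit(series)
  if (basis_dim < 2) abort("basis_dim must be >= 2.", class = "chronopop_usage_error")
  if (nrow(series) <= basis_dim) {
    abort("Grid length must exceed basis_dim.", class = "chronopop_usage_error")
  }
  series <- dplyr::arrange(series, dplyr::desc(.data$cal_bp))
  y <- trend_response(series)
  dat <- data.frame(y = y, t = -series$cal_bp)
  m <- mgcv::gam(y ~ s(t, k = basis_dim, bs = "tp"),
    family = quasipoisson(link = "log"), data = dat,
    method = "GCV.Cp", sp = sp
  )
  if (!m$converged) {
    abort(
      paste0(
        "Penalized IRLS did not converge (",
        m$iter %||% NA, " iterations); consider a smaller basis_dim."
      ),
      class = "chronopop_convergence_error"
    )
  }
  s <- summary(m)
  new_trend_fit(
    m, "gam", series, y,
    edf = 1 + sum(s$edf),
    pseudo_r2 = s$dev.expl,
    r2_adj = s$r.sq,
    dispersion = s$dispersion,
    basis_dim = basis_dim
  )
}

#' First derivative of a fitted trend with confidence bounds
#'
#' Finite-difference first derivative of the fitted trend on the response
#' scale, per 100-year grid step: central differences at interior grid
#' points, one-sided differences at the two ends. Confidence bounds are
#' obtained by propagating the fit's coefficient covariance through the
#' same finite-difference contrast (delta method on the log link).
#' With `simultaneous = TRUE` the critical value is instead taken from the
#' simulated distribution of the maximum standardized deviation across the
#' grid, giving a simultaneous band.
#'
#' @param fit A `trend_fit`.
#' @param alpha Significance level for the interval (default 0.05).
#' @param simultaneous Use a simultaneous critical value (default
#'   `FALSE`: pointwise intervals).
#' @param nsim Coefficient draws used for the simultaneous critical value.
#' @param seed Optional seed for the simultaneous simulation.
#' @return A tibble of class `deriv_series`: `cal_bp`, `slope` (change in
#'   fitted value per 100 years, positive = increase toward the present),
#'   `se`, `lo`, `hi`; `alpha` stored as an attribute.
#' @export
derivative <- function(fit, alpha = 0.05, simultaneous = FALSE,
                       nsim = 10000, seed = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  grid <- dplyr::arrange(fit$grid, .data$t)
  n <- nrow(grid)
  if (n < 3) abort("Derivative needs at least 3 grid points.", class = "chronopop_usage_error")
  nd <- data.frame(t = grid$t)
  Xp <- if (fit$kind == "gam") {
    predict(fit$model, newdata = nd, type = "lpmatrix")
  } else {
    model.matrix(~t, data = nd)
  }
  beta <- coef(fit$model)
  V <- vcov(fit$model)
  mu <- as.numeric(exp(Xp %*% beta))
  # finite-difference contrast matrix on the response vector (per step)
  D <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    D[i, i + 1] <- 0.5
    D[i, i - 1] <- -0.5
  }
  D[1, 1:2] <- c(-1, 1)
  D[n, (n - 1):n] <- c(-1, 1)
  slope <- as.numeric(D %*% mu)
  J <- D %*% (mu * Xp) # d(slope)/d(beta), since d mu_j / d beta = mu_j * Xp_j
  se <- sqrt(pmax(rowSums((J %*% V) * J), 0))
  crit <- if (!simultaneous) {
    qnorm(1 - alpha / 2)
  } else {
    draw <- function() {
      L <- chol(V)
      B <- matrix(rnorm(nsim * length(beta)), nsim) %*% L # deviations around beta
      dev <- abs(B %*% t(J)) # linearized slope deviations
      mx <- apply(sweep(dev, 2, pmax(se, 1e-300), "/"), 1, max)
      as.numeric(quantile(mx, 1 - alpha))
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  out <- tibble::tibble(
    cal_bp = -grid$t,
    slope = slope, se = se,
    lo = slope - crit * se,
    hi = slope + crit * se
  )
  out <- dplyr::arrange(out, .data$cal_bp)
  attr(out, "alpha") <- alpha
  attr(out, "simultaneous") <- simultaneous
  attr(out, "kind") <- fit$kind
  class(out) <- c("deriv_series", class(out))
  out
}

#' Significant periods of population change
#'
#' Extracts maximal runs of consecutive grid points where the derivative's
#' confidence interval excludes zero: `lo > 0` is an increase (toward the
#' present), `hi < 0` a decrease. Periods are reported older bound first
#' (cal BP convention, e.g. a growth period "6400-5500"). Runs of a single
#' grid point span no grid step and are not reported as periods.
#'
#' @param deriv A `deriv_series` from [derivative()].
#' @return A tibble of class `significance_periods` with columns `start`
#'   (older bound), `end` (younger bound), `direction`
#'   (`"increase"`/`"decrease"`), ordered oldest first.
#' @export
significant_periods <- function(deriv) {
  stopifnot(is.data.frame(deriv), all(c("cal_bp", "lo", "hi") %in% names(deriv)))
  d <- dplyr::arrange(deriv, dplyr::desc(.data$cal_bp)) # older -> younger
  state <- ifelse(d$lo > 0, "increase", ifelse(d$hi < 0, "decrease", "none"))
  r <- rle(state)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  keep <- r$values != "none" & r$lengths >= 2
  out <- tibble::tibble(
    start = d$cal_bp[starts[keep]],
    end = d$cal_bp[stops[keep]],
    direction = r$values[keep]
  )
  attr(out, "alpha") <- attr(deriv, "alpha")
  class(out) <- c("significance_periods", class(out))
  out
}

#' Fit trends and extract change periods for all four proxies
#'
#' For each (proxy, corrected) series in a long proxy table: fits the
#' global quasi-Poisson GLM and the GCV-penalized GAM, takes the first
#' derivative of the GAM fit, and extracts the significant periods of
#' increase and decrease. Per-proxy failures are captured and reported
#' without aborting the remaining proxies.
#'
#' @param proxies A long proxy table from [build_proxies()] (exactly four
#'   (proxy, corrected) series).
#' @param alpha Significance level for the derivative intervals.
#' @param basis_dim GAM basis dimension.
#' @param simultaneous Use simultaneous derivative intervals.
#' @return A nested tibble with one row per proxy: `proxy`, `corrected`,
#'   and list-columns `glm`, `gam`, `derivative`, `periods`, `error`.
#'   `attr(, "alpha")` records the level used.
#' @export
analyze_all <- function(proxies, alpha = 0.05, basis_dim = 10, simultaneous = FALSE) {
  combos <- dplyr::distinct(proxies[, c("proxy", "corrected")])
  if (nrow(combos) == 0) {
    abort("Empty proxy table.", class = "chronopop_usage_error")
  }
  res <- purrr::pmap(combos, function(proxy, corrected) {
    tryCatch(
      {
        s <- pick_proxy(proxies, proxy, corrected)
        g <- fit_glm(s)
        a <- fit_gam(s, basis_dim = basis_dim)
        d <- derivative(a, alpha = alpha, simultaneous = simultaneous)
        list(glm = g, gam = a, derivative = d, periods = significant_periods(d), error = NA_character_)
      },
      error = function(e) {
        list(glm = NULL, gam = NULL, derivative = NULL, periods = NULL, error = conditionMessage(e))
      }
    )
  })
  out <- dplyr::mutate(
    combos,
    glm = purrr::map(res, "glm"),
    gam = purrr::map(res, "gam"),
    derivative = purrr::map(res, "derivative"),
    periods = purrr::map(res, "periods"),
    error = purrr::map_chr(res, "error")
  )
  attr(out, "alpha") <- alpha
  attr(out, "basis_dim") <- basis_dim
  class(out) <- c("trend_analysis", class(out))
  out
}

#' Grid points where all proxies agree on significant growth
#'
#' Cross-proxy intersection of the significant-increase flags: the grid
#' points at which every analyzed proxy has its derivative interval
#' entirely above zero.
#'
#' @param analysis A `trend_analysis` from [analyze_all()].
#' @return A tibble `cal_bp`, `all_increase` (logical per grid point).
#' @export
common_growth <- function(analysis) {
  ds <- purrr::compact(analysis$derivative)
  if (length(ds) == 0) {
    abort("No successful derivative series in analysis.", class = "chronopop_usage_error")
  }
  flags <- purrr::map(ds, function(d) {
    d <- dplyr::arrange(d, .data$cal_bp)
    d$lo > 0
  })
  tibble::tibble(
    cal_bp = sort(ds[[1]]$cal_bp),
    all_increase = purrr::reduce(flags, `&`)
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Quasi-Poisson %s trend of %s (%s)\n",
    toupper(x$kind), x$proxy, if (x$corrected) "taphonomically corrected" else "observed"
  ))
  cat(sprintf(
    "  edf = %.3f, deviance explained = %.3f, dispersion = %.3f\n",
    x$edf, x$pseudo_r2, x$dispersion
  ))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    cal_bp = x$grid$cal_bp,
    estimate = x$grid$fitted,
    se_link = x$grid$se_fit,
    conf_low = x$grid$lo,
    conf_high = x$grid$hi
  )
}

#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    proxy = x$proxy,
    corrected = x$corrected,
    edf = x$edf,
    pseudo_r2 = x$pseudo_r2,
    r2_adj = x$r2_adj,
    dispersion = x$dispersion,
    n = nrow(x$grid)
  )
}
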