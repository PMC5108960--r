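#' Calibrate a radiocarbon determination
#'
#' Grid-based probability calibration of a single \eqn{^{14}}C
#' determination. For each calendar year \eqn{t} on the grid the
#' unnormalized posterior mass is the Gaussian likelihood
#' \deqn{p(t) \propto N(a; \mu(t), \sqrt{e^2 + \sigma(t)^2})}
#' where \eqn{a} and \eqn{e} are the measured age and its 1-sigma lab error
#' and \eqn{\mu(t)}, \eqn{\sigma(t)} are the linearly interpolated curve
#' mean and error. The grid is truncated where the cumulative tail mass
#' falls below `1e-6` per side and the result is renormalized to sum to 1.
#' This is the single-date likelihood used by standard calibration software;
#' no reservoir correction or sequence modelling is applied.
#'
#' @param c14_age Measured radiocarbon age, years \eqn{^{14}}C BP.
#' @param c14_error 1-sigma measurement error in years, `> 0`.
#' @param curve A [cal_curve()].
#' @param step Grid step in calendar years (default 1).
#' @return A tibble of class `cal_dist` with columns `cal_bp` (ascending,
#'   uniform step) and `mass` (sums to 1).
#' @export
#' @examples
#' crv <- cal_curve(0:160 * 100, 0:160 * 100, rep(10, 161))
#' d <- calibrate(3000, 25, crv)
#' median_cal(d)
calibrate <- function(c14_age, c14_error, curve, step = 1) {
  if (!is.finite(c14_age) || c14_age < 0) {
    abort("c14_age must be finite and non-negative.", class = "chronopop_usage_error")
  }
  if (!is.finite(c14_error) || c14_error <= 0) {
    abort("c14_error must be positive.", class = "chronopop_usage_error")
  }
  sup <- curve_support(curve, step)
  calibrate_on_support(c14_age, c14_error, sup)
}

# Precompute the interpolated curve on a uniform grid (shared by batch runs).
curve_support <- function(curve, step = 1) {
  grid <- seq(ceiling(min(curve$cal_bp) / step) * step, max(curve$cal_bp), by = step)
  at <- curve_at(curve, grid)
  list(
    grid = grid, mu = at$mu, sigma = at$sigma, step = step,
    monotone = !is.unsorted(at$mu, strictly = TRUE)
  )
}

calibrate_on_support <- function(c14_age, c14_error, sup) {
  stot_max <- sqrt(c14_error^2 + max(sup$sigma)^2)
  # restrict to calendar years whose curve mean lies within 8 combined sigma
  if (sup$monotone) {
    i0 <- findInterval(c14_age - 8 * stot_max, sup$mu) + 1L
    i1 <- findInterval(c14_age + 8 * stot_max, sup$mu)
    if (i1 < i0) {
      idx <- integer(0)
    } else {
      idx <- i0:i1
    }
  } else {
    idx <- which(abs(sup$mu - c14_age) < 8 * stot_max)
  }
  if (length(idx) == 0) {
    abort(
      sprintf("Posterior mass for %g +/- %g BP lies outside curve support.",
        c14_age, c14_error
      ),
      class = "chronopop_range_error"
    )
  }
  idx <- min(idx):max(idx)
  stot <- sqrt(c14_error^2 + sup$sigma[idx]^2)
  dens <- dnorm(c14_age, mean = sup$mu[idx], sd = stot)
  tot <- sum(dens)
  if (!is.finite(tot) || tot <= 0) {
    abort("Calibration produced no posterior mass inside curve support.",
      class = "chronopop_range_error"
    )
  }
  mass <- dens / tot
  lo_tail <- cumsum(mass)
  hi_tail <- rev(cumsum(rev(mass)))
  keep <- which(lo_tail >= 1e-6 & hi_tail >= 1e-6)
  if (length(keep) == 0) keep <- which.max(mass)
  mass <- mass[keep] / sum(mass[keep])
  out <- tibble::tibble(cal_bp = sup$grid[idx][keep], mass = mass)
  class(out) <- c("cal_dist", class(out))
  out
}

#' Median of a calibrated distribution
#'
#' The point estimate used for the dates-as-data proxies: the smallest grid
#' year at which the cumulative posterior mass reaches 0.5 (a deterministic
#' tie-break under multimodality).
#'
#' @param dist A `cal_dist` from [calibrate()].
#' @return Median calendar age, years cal BP.
#' @export
median_cal <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("cal_bp", "mass") %in% names(dist)))
  dist$cal_bp[which(cumsum(dist$mass) >= 0.5)[1]]
}

#' Calibrate a table of radiocarbon records
#'
#' Calibrates each record against `curve` and returns the per-record median
#' calibrated age. Records whose posterior falls outside the curve support
#' are reported in the `failed` attribute; the rest of the batch proceeds.
#'
#' @param records A record tibble (normally after [apply_hygiene()]).
#' @param curve A [cal_curve()].
#' @param step Calibration grid step in calendar years.
#' @return A tibble with columns `lab_id`, `site_id`, `median_cal_bp`, and
#'   an `attr(, "failed")` tibble of `lab_id`, `reason` for records that
#'   could not be calibrated.
#' @export
calibrate_batch <- function(records, curve, step = 1) {
  empty <- tibble::tibble(
    lab_id = character(0), site_id = character(0),
    median_cal_bp = numeric(0)
  )
  if (nrow(records) == 0) {
    attr(empty, "failed") <- tibble::tibble(lab_id = character(0), reason = character(0))
    return(empty)
  }
  sup <- curve_support(curve, step)
  med <- rep(NA_real_, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- tryCatch(
      median_cal(calibrate_on_support(records$c14_age[i], records$c14_error[i], sup)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      reason[i] <- conditionMessage(res)
    } else {
      med[i] <- res
    }
  }
  ok <- !is.na(med)
  out <- tibble::tibble(
    lab_id = records$lab_id[ok],
    site_id = records$site_id[ok],
    median_cal_bp = med[ok]
  )
  attr(out, "failed") <- tibble::tibble(
    lab_id = records$lab_id[!ok],
    reason = reason[!ok]
  )
  out
}
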