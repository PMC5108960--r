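#' Construct a calibration curve object
#'
#' A calibration curve maps calendar age (cal BP) to the expected
#' radiocarbon age (\eqn{^{14}}C BP) with a 1-sigma uncertainty, as in the
#' IntCal family of curves. Between tabulated knots the curve is linearly
#' interpolated; evaluation outside the tabulated range is an error.
#'
#' @param cal_bp Calendar years BP at the knots (will be sorted ascending).
#' @param c14_age Radiocarbon years BP at the knots.
#' @param c14_sigma 1-sigma curve uncertainty in years, all `> 0`.
#' @return A tibble of class `cal_curve` with columns `cal_bp`, `c14_age`,
#'   `c14_sigma`, sorted by ascending `cal_bp`.
#' @export
#' @examples
#' cal_curve(0:10 * 100, 0:10 * 100, rep(10, 11))
cal_curve <- function(cal_bp, c14_age, c14_sigma) {
  if (length(cal_bp) < 2) {
    abort("A calibration curve needs at least 2 knots.", class = "chronopop_format_error")
  }
  if (length(c14_age) != length(cal_bp) || length(c14_sigma) != length(cal_bp)) {
    abort("cal_bp, c14_age and c14_sigma must have equal length.",
      class = "chronopop_format_error"
    )
  }
  if (any(!is.finite(cal_bp)) || any(!is.finite(c14_age)) || any(!is.finite(c14_sigma))) {
    abort("Calibration curve values must be finite.", class = "chronopop_format_error")
  }
  if (any(c14_sigma <= 0)) {
    abort("Calibration curve sigma values must be positive.", class = "chronopop_format_error")
  }
  ord <- order(cal_bp)
  cal_bp <- cal_bp[ord]
  if (any(diff(cal_bp) <= 0)) {
    abort("cal_bp knots must be distinct.", class = "chronopop_format_error")
  }
  out <- tibble::tibble(
    cal_bp = as.numeric(cal_bp),
    c14_age = as.numeric(c14_age[ord]),
    c14_sigma = as.numeric(c14_sigma[ord])
  )
  class(out) <- c("cal_curve", class(out))
  out
}

#' Read an IntCal-format calibration curve file
#'
#' IntCal curve files are plain text with `#` comment headers and
#' comma- or whitespace-separated columns, the first three being
#' calendar age (cal BP), \eqn{^{14}}C age (BP) and its 1-sigma error.
#' IntCal files list knots in descending calendar age; the returned curve is
#' always sorted ascending. Columns beyond the third are ignored.
#'
#' @param path Path to the curve file.
#' @return A [cal_curve()] object.
#' @export
#' @examples
#' crv <- read_curve(system.file("extdata", "synthetic_curve.14c",
#'   package = "chronopop"
#' ))
#' head(crv)
read_curve <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Curve file not found: ", path), class = "chronopop_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) {
    abort("Curve file has fewer than 2 data rows.", class = "chronopop_format_error")
  }
  fields <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 3)) {
    abort("Curve file rows must have at least 3 columns (cal BP, 14C age, sigma).",
      class = "chronopop_format_error"
    )
  }
  num <- function(k) as.numeric(vapply(fields, `[[`, character(1), k))
  cal_curve(num(1), num(2), num(3))
}

#' Write a calibration curve in IntCal layout
#'
#' Knots are written in descending cal BP order (the IntCal convention),
#' with a `#` comment header.
#'
#' @param curve A [cal_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  ord <- order(curve$cal_bp, decreasing = TRUE)
  lines <- c(
    "# calibration curve",
    "# CAL BP, 14C age BP, Sigma",
    sprintf("%.1f,%.1f,%.1f", curve$cal_bp[ord], curve$c14_age[ord], curve$c14_sigma[ord])
  )
  writeLines(lines, path)
  invisible(path)
}

# Linear interpolation of curve mean and sigma at calendar ages `t`.
# Errors if any t falls outside the tabulated range.
curve_at <- function(curve, t) {
  rng <- range(curve$cal_bp)
  if (any(t < rng[1] | t > rng[2])) {
    abort(
      sprintf(
        "Calendar age outside curve support [%g, %g] cal BP.",
        rng[1], rng[2]
      ),
      class = "chronopop_range_error"
    )
  }
  list(
    mu = approx(curve$cal_bp, curve$c14_age, xout = t, ties = "ordered")$y,
    sigma = approx(curve$cal_bp, curve$c14_sigma, xout = t, ties = "ordered")$y
  )
}
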