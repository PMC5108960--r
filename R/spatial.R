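#' Fit a standard deviational ellipse to planar points
#'
#' The standard deviational ellipse (SDE) summarizes the central tendency,
#' dispersion and directional trend of a point pattern: its centre is the
#' mean of the coordinates, its axes are the principal axes of the centred
#' coordinates' second-moment matrix, and its semi-axis lengths are the
#' standard deviations along those axes, multiplied by `scale`.
#'
#' @param points A data frame with columns `x` and `y` (planar units).
#' @param scale Number of standard deviations for the ellipse boundary
#'   (default 2; with Gaussian scatter a 2-s.d. ellipse is expected to
#'   enclose about 95% of the generating population).
#' @param denominator `"n"` (population, the classic SDE definition;
#'   default) or `"n-2"` (small-sample correction used by some GIS tools).
#' @param yuill If `TRUE`, multiply both axes by `sqrt(2)` (Yuill's
#'   correction). Default `FALSE`.
#' @return An object of class `study_ellipse`: centre, semi-axis standard
#'   deviations `sd_x >= sd_y`, rotation of the major axis in radians within
#'   `[-pi/2, pi/2)`, and `scale`.
#' @export
fit_sde <- function(points, scale = 2, denominator = c("n", "n-2"), yuill = FALSE) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  x <- points$x
  y <- points$y
  n <- length(x)
  if (n < 3) {
    abort("At least 3 points are required to fit an ellipse.",
      class = "chronopop_geometry_error"
    )
  }
  if (scale <= 0) abort("scale must be positive.", class = "chronopop_usage_error")
  cx <- mean(x)
  cy <- mean(y)
  dx <- x - cx
  dy <- y - cy
  denom <- if (denominator == "n") n else n - 2
  m <- matrix(
    c(sum(dx * dx), sum(dx * dy), sum(dx * dy), sum(dy * dy)) / denom,
    nrow = 2
  )
  eig <- eigen(m, symmetric = TRUE)
  if (eig$values[2] <= .Machine$double.eps * max(1, eig$values[1])) {
    abort("Points are collinear or coincident; ellipse is degenerate.",
      class = "chronopop_geometry_error"
    )
  }
  # eigenvalues are sorted decreasing: first axis is the major axis
  v <- eig$vectors[, 1]
  rotation <- atan2(v[2], v[1])
  if (rotation < -pi / 2) rotation <- rotation + pi
  if (rotation >= pi / 2) rotation <- rotation - pi
  sd_axes <- sqrt(eig$values) * if (yuill) sqrt(2) else 1
  structure(
    list(
      center_x = cx, center_y = cy,
      sd_x = sd_axes[1], sd_y = sd_axes[2],
      rotation = rotation, scale = scale,
      n_points = n, ref_lat = NA_real_
    ),
    class = "study_ellipse"
  )
}

# Equirectangular projection about a reference latitude: longitudes are
# scaled by cos(ref_lat) so one unit is comparable in x and y. Adequate for
# a mid-latitude, sub-continental study envelope.
project_planar <- function(lon, lat, ref_lat) {
  tibble::tibble(x = lon * cos(ref_lat * pi / 180), y = lat)
}

#' Build the study ellipse from anchor-site coordinates
#'
#' Projects longitude/latitude to a plane (equirectangular about the mean
#' anchor latitude) and fits the standard deviational ellipse at `scale`
#' standard deviations around the anchors. The default anchors are the
#' seven early-domestication sites of Eastern North America
#' ([domestication_anchors()]).
#'
#' @param anchors A data frame with columns `lon` and `lat` (decimal
#'   degrees).
#' @inheritParams fit_sde
#' @return A `study_ellipse` carrying the projection reference latitude so
#'   that date tables can be filtered with [filter_study_area()].
#' @export
study_ellipse <- function(anchors = domestication_anchors(), scale = 2,
                          denominator = c("n", "n-2"), yuill = FALSE) {
  stopifnot(all(c("lon", "lat") %in% names(anchors)))
  ref_lat <- mean(anchors$lat)
  ell <- fit_sde(project_planar(anchors$lon, anchors$lat, ref_lat),
    scale = scale, denominator = denominator, yuill = yuill
  )
  ell$ref_lat <- ref_lat
  ell
}

#' Test whether points fall inside a study ellipse
#'
#' A point is inside when, after centring and rotating into the ellipse
#' frame, \eqn{(u/(s\,sd_x))^2 + (v/(s\,sd_y))^2 \le 1} with
#' \eqn{s} the ellipse scale. The boundary is inclusive.
#'
#' @param ellipse A `study_ellipse`.
#' @param x,y Planar coordinates (same frame the ellipse was fitted in).
#' @return A logical vector.
#' @export
sde_contains <- function(ellipse, x, y) {
  stopifnot(inherits(ellipse, "study_ellipse"))
  dx <- x - ellipse$center_x
  dy <- y - ellipse$center_y
  th <- ellipse$rotation
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  q <- (u / (ellipse$scale * ellipse$sd_x))^2 + (v / (ellipse$scale * ellipse$sd_y))^2
  q <= 1 + 1e-9
}

#' Filter radiocarbon records to the study area
#'
#' Keeps records whose coordinates fall inside the ellipse (boundary
#' inclusive), preserving order. Records with missing coordinates are
#' excluded and reported in the `excluded` attribute.
#'
#' @param records A record tibble with `lon` and `lat` columns.
#' @param ellipse A `study_ellipse` from [study_ellipse()].
#' @return The subset tibble; `attr(, "excluded")` lists lab IDs dropped
#'   for missing coordinates.
#' @export
filter_study_area <- function(records, ellipse) {
  stopifnot(inherits(ellipse, "study_ellipse"))
  if (is.na(ellipse$ref_lat)) {
    abort("Ellipse lacks a projection reference; build it with study_ellipse().",
      class = "chronopop_usage_error"
    )
  }
  has_xy <- is.finite(records$lon) & is.finite(records$lat)
  pl <- project_planar(records$lon[has_xy], records$lat[has_xy], ellipse$ref_lat)
  inside <- sde_contains(ellipse, pl$x, pl$y)
  out <- records[which(has_xy)[inside], , drop = FALSE]
  attr(out, "excluded") <- tibble::tibble(
    lab_id = records$lab_id[!has_xy],
    reason = "missing coordinates"
  )
  out
}

#' @export
print.study_ellipse <- function(x, ...) {
  cat(sprintf(
    "Standard deviational ellipse (scale = %g s.d., n = %d)\n", x$scale, x$n_points
  ))
  cat(sprintf("  centre:   (%.4f, %.4f)\n", x$center_x, x$center_y))
  cat(sprintf("  sd axes:  %.4f x %.4f\n", x$sd_x, x$sd_y))
  cat(sprintf("  rotation: %.4f rad\n", x$rotation))
  invisible(x)
}

#' Anchor sites with the earliest domestication evidence
#'
#' Approximate coordinates for the seven Eastern North American sites with
#' the earliest dated evidence of plant domestication (Cloudsplitter and
#' Newt Kash, KY; Hayes, TN; Marble Bluff, AR; Phillips Spring, MO;
#' Napoleon Hollow and Riverton, IL). Used as the default anchors for the
#' study ellipse and as the reference area for the synthetic generator.
#' Coordinates are approximate public values, sufficient to define a
#' realistic sub-continental envelope.
#'
#' @return A tibble with columns `site`, `lon`, `lat`.
#' @export
domestication_anchors <- function() {
  tibble::tibble(
    site = c(
      "Cloudsplitter", "Newt Kash", "Hayes", "Marble Bluff",
      "Phillips Spring", "Napoleon Hollow", "Riverton"
    ),
    lon = c(-83.60, -83.72, -87.10, -94.20, -93.40, -90.60, -87.57),
    lat = c(37.80, 37.86, 35.90, 35.95, 37.80, 39.40, 38.98)
  )
}

#' Calendar markers for the earliest domesticates
#'
#' Median ages for the earliest occurrence of each domesticate in the
#' study area: squash (*Cucurbita pepo*) 5025, sunflower 4840, marshelder
#' 4400 and chenopod 3800 cal BP. Used as default vertical markers in
#' [plot_trend_panel()].
#'
#' @return A tibble with columns `label`, `cal_bp`.
#' @export
domestication_markers <- function() {
  tibble::tibble(
    label = c("squash", "sunflower", "marshelder", "chenopod"),
    cal_bp = c(5025, 4840, 4400, 3800)
  )
}
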