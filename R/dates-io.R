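#' Column mapping for CARD-like date tables
#'
#' Describes which CSV columns hold each field of a radiocarbon record, so
#' exports with differing headers can be ingested without editing the file.
#' `lab_id`, `c14_age` and `c14_error` are required in the file; the
#' remaining fields fall back to defaults when their column is absent
#' (empty site, missing coordinates, `archaeological` context, not
#' anomalous).
#'
#' @param lab_id,c14_age,c14_error,site_id,lon,lat,context,anomalous
#'   Column names in the CSV file.
#' @return A named list of class `card_dialect`.
#' @export
card_dialect <- function(lab_id = "lab_id", c14_age = "c14_age",
                         c14_error = "c14_error", site_id = "site_id",
                         lon = "lon", lat = "lat", context = "context",
                         anomalous = "anomalous") {
  structure(
    list(
      lab_id = lab_id, c14_age = c14_age, c14_error = c14_error,
      site_id = site_id, lon = lon, lat = lat, context = context,
      anomalous = anomalous
    ),
    class = "card_dialect"
  )
}

.contexts <- c("archaeological", "palaeobiological", "geological")

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(trimws(x)) %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[tolower(trimws(x)) %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  out[is.na(x)] <- FALSE
  out
}

#' Read a CARD-like radiocarbon date table
#'
#' Reads a CSV export of radiocarbon determinations into the package's
#' standard record table: one row per dated sample with laboratory number,
#' uncalibrated \eqn{^{14}}C age and 1-sigma error, site identifier
#' (Smithsonian trinomial or empty), coordinates, depositional context and
#' an anomalous flag. Rows whose numeric fields cannot be parsed, or that
#' violate basic record invariants (empty lab ID, non-positive error,
#' negative or missing age), are dropped from the result and reported in the
#' `problems` attribute rather than silently discarded.
#'
#' @param path Path to the CSV file.
#' @param dialect A [card_dialect()] mapping field names to file columns.
#' @return A tibble with columns `lab_id`, `c14_age`, `c14_error`,
#'   `site_id`, `lon`, `lat`, `context`, `anomalous`. Malformed rows are
#'   reported in `attr(, "problems")` as a tibble of `row`, `lab_id`,
#'   `reason`.
#' @export
read_dates <- function(path, dialect = card_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("Date table not found: ", path), class = "chronopop_io_error")
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  required <- c("lab_id", "c14_age", "c14_error")
  miss <- vapply(required, function(f) !(dialect[[f]] %in% names(raw)), logical(1))
  if (any(miss)) {
    abort(
      paste0(
        "Required column(s) missing from ", path, ": ",
        paste(unlist(dialect[required][miss]), collapse = ", ")
      ),
      class = "chronopop_config_error"
    )
  }
  col_or <- function(f, default) {
    if (dialect[[f]] %in% names(raw)) raw[[dialect[[f]]]] else rep(default, nrow(raw))
  }
  suppressWarnings({
    out <- tibble::tibble(
      lab_id = trimws(col_or("lab_id", NA_character_)),
      c14_age = as.numeric(col_or("c14_age", NA_character_)),
      c14_error = as.numeric(col_or("c14_error", NA_character_)),
      site_id = dplyr::coalesce(trimws(col_or("site_id", "")), ""),
      lon = as.numeric(col_or("lon", NA_character_)),
      lat = as.numeric(col_or("lat", NA_character_)),
      context = tolower(dplyr::coalesce(trimws(col_or("context", "archaeological")), "archaeological")),
      anomalous = parse_flag(col_or("anomalous", "false"))
    )
  })
  bad_reason <- dplyr::case_when(
    is.na(out$lab_id) | out$lab_id == "" ~ "empty lab_id",
    is.na(out$c14_age) ~ "unparseable c14_age",
    is.na(out$c14_error) ~ "unparseable c14_error",
    out$c14_age < 0 ~ "negative c14_age",
    out$c14_error <= 0 ~ "non-positive c14_error",
    !(out$context %in% .contexts) ~ "unknown context",
    is.na(out$anomalous) ~ "unparseable anomalous flag",
    .default = NA_character_
  )
  problems <- tibble::tibble(
    row = which(!is.na(bad_reason)),
    lab_id = out$lab_id[which(!is.na(bad_reason))],
    reason = bad_reason[!is.na(bad_reason)]
  )
  out <- out[is.na(bad_reason), ]
  attr(out, "problems") <- problems
  out
}

#' Write a radiocarbon date table as CSV
#'
#' @param dates A record tibble as produced by [read_dates()] or
#'   [make_card_like_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dates <- function(dates, path) {
  readr::write_csv(dates, path, progress = FALSE)
  invisible(path)
}

#' Apply chronometric hygiene to a radiocarbon date table
#'
#' Three filters, in order: (1) duplicate laboratory numbers are removed,
#' keeping the first occurrence in table order (comparison is
#' case-insensitive with surrounding whitespace stripped); (2) dates from
#' palaeobiological and geological contexts are removed; (3) dates flagged
#' anomalous are removed. No record is removed on account of its age or the
#' magnitude of its standard error, and survivors are never altered. The
#' operation is idempotent.
#'
#' @param dates A record tibble.
#' @return The filtered tibble, with a hygiene report attached as
#'   `attr(, "hygiene")` (see [hygiene_report()]).
#' @export
apply_hygiene <- function(dates) {
  n_input <- nrow(dates)
  key <- toupper(trimws(dates$lab_id))
  dup <- duplicated(key)
  after_dedup <- dates[!dup, , drop = FALSE]
  bad_ctx <- after_dedup$context %in% c("palaeobiological", "geological")
  after_ctx <- after_dedup[!bad_ctx, , drop = FALSE]
  anom <- after_ctx$anomalous
  out <- after_ctx[!anom, , drop = FALSE]
  removed <- dplyr::bind_rows(
    tibble::tibble(lab_id = dates$lab_id[dup], reason = "duplicate lab_id"),
    tibble::tibble(
      lab_id = after_dedup$lab_id[bad_ctx],
      reason = paste0(after_dedup$context[bad_ctx], " context")
    ),
    tibble::tibble(lab_id = after_ctx$lab_id[anom], reason = "anomalous")
  )
  report <- structure(
    list(
      n_input = n_input,
      n_after_dedup = nrow(after_dedup),
      n_after_context = nrow(after_ctx),
      n_after_anomaly = nrow(out),
      removed = removed
    ),
    class = "hygiene_report"
  )
  attr(out, "hygiene") <- report
  attr(out, "problems") <- NULL
  out
}

#' Retrieve the hygiene report from a filtered date table
#'
#' @param dates A tibble returned by [apply_hygiene()].
#' @return A `hygiene_report`: counts of records surviving each filter and a
#'   tibble of removed lab IDs with reasons.
#' @export
hygiene_report <- function(dates) {
  rep <- attr(dates, "hygiene")
  if (is.null(rep)) {
    abort("No hygiene report attached; run apply_hygiene() first.",
      class = "chronopop_usage_error"
    )
  }
  rep
}

#' @export
print.hygiene_report <- function(x, ...) {
  cat("Chronometric hygiene report\n")
  cat(sprintf("  input records:      %d\n", x$n_input))
  cat(sprintf("  after deduplication: %d\n", x$n_after_dedup))
  cat(sprintf("  after context filter: %d\n", x$n_after_context))
  cat(sprintf("  after anomaly filter: %d\n", x$n_after_anomaly))
  invisible(x)
}
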