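#' Event catalogs
#'
#' An event catalog is a tibble with one row per event and numeric columns
#' `t` (occurrence time), `x` and `y` (planar coordinates, km by convention).
#' Rows are kept sorted by `t`; ties keep their input order. All user-facing
#' functions in hawkesmix accept any data frame with these three columns and
#' return tibbles, so catalogs compose with dplyr verbs and the pipe.
#'
#' @param t,x,y Numeric vectors of equal length: occurrence times and planar
#'   coordinates. All values must be finite.
#' @return A tibble with columns `t`, `x`, `y`, sorted by `t` (stable sort,
#'   so events with equal times keep their relative input order).
#' @examples
#' event_catalog(t = c(2, 1, 3), x = c(0.1, 0.2, 0.3), y = c(1, 1, 1))
#' @export
event_catalog <- function(t, x, y) {
  if (length(t) != length(x) || length(t) != length(y)) {
    abort("`t`, `x` and `y` must have the same length.")
  }
  cat <- tibble(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  validate_catalog(cat, sorted = FALSE)
  cat[order(cat$t), , drop = FALSE]
}

#' Coerce a data frame to an event catalog
#'
#' @param data A data frame with numeric columns `t`, `x`, `y`.
#' @return A tibble sorted by `t`.
#' @export
as_event_catalog <- function(data) {
  cols <- c("t", "x", "y")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing column(s): ", paste(missing, collapse = ", ")))
  }
  event_catalog(data$t, data$x, data$y)
}

# internal: check catalog invariants
validate_catalog <- function(cat, sorted = TRUE) {
  for (col in c("t", "x", "y")) {
    v <- cat[[col]]
    if (!is.numeric(v)) abort(paste0("catalog column `", col, "` must be numeric"))
    if (anyNA(v) || any(!is.finite(v))) {
      abort(paste0("catalog column `", col, "` contains non-finite values"))
    }
  }
  if (sorted && is.unsorted(cat$t)) abort("catalog times must be nondecreasing")
  invisible(cat)
}

#' Rectangular spatial region
#'
#' The observation region S = \[x_lo, x_hi\] x \[y_lo, y_hi\] over which the
#' process is observed and the likelihood compensator is integrated.
#'
#' @param x_lo,x_hi,y_lo,y_hi Region bounds (km); lower bounds must be
#'   strictly below upper bounds. Infinite bounds are allowed where an
#'   operation supports them (e.g. full-plane compensators).
#' @return An object of class `spatial_region`.
#' @export
spatial_region <- function(x_lo, x_hi, y_lo, y_hi) {
  if (!(x_lo < x_hi) || !(y_lo < y_hi)) {
    abort("spatial_region requires x_lo < x_hi and y_lo < y_hi")
  }
  structure(list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
            class = "spatial_region")
}

#' @export
print.spatial_region <- function(x, ...) {
  cat(sprintf("<spatial_region [%g, %g] x [%g, %g]>\n", x$x_lo, x$x_hi, x$y_lo, x$y_hi))
  invisible(x)
}

#' Half-open observation time window
#'
#' The window D = \[t_lo, t_hi) over which events are observed. The window is
#' half-open: an event exactly at `t_hi` is outside D.
#'
#' @param t_lo,t_hi Window bounds with `t_lo < t_hi`.
#' @return An object of class `time_window`.
#' @export
time_window <- function(t_lo, t_hi) {
  if (!(t_lo < t_hi)) abort("time_window requires t_lo < t_hi")
  structure(list(t_lo = t_lo, t_hi = t_hi), class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window [%g, %g)>\n", x$t_lo, x$t_hi))
  invisible(x)
}

#' Area of a spatial region
#' @param region A [spatial_region()].
#' @return Area in km^2.
#' @export
region_area <- function(region) {
  (region$x_hi - region$x_lo) * (region$y_hi - region$y_lo)
}

#' Length of a time window
#' @param window A [time_window()].
#' @return Window length in time units.
#' @export
window_length <- function(window) window$t_hi - window$t_lo

#' Bounding region and window of a catalog
#'
#' Convenience accessors: the tight axis-aligned region containing all events,
#' and the window from the first to the last event time.
#'
#' @param data An event catalog (data frame with `t`, `x`, `y`).
#' @return A [spatial_region()] or [time_window()].
#' @export
catalog_region <- function(data) {
  data <- as_event_catalog(data)
  spatial_region(min(data$x), max(data$x), min(data$y), max(data$y))
}

#' @rdname catalog_region
#' @export
catalog_window <- function(data) {
  data <- as_event_catalog(data)
  time_window(min(data$t), max(data$t))
}
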