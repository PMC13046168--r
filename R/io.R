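#' Read an event catalog from CSV
#'
#' Expects a header with columns `t`, `x`, `y` (any order, extra columns
#' ignored), '.' decimal separator, UTF-8. The returned catalog is sorted
#' by time. Parse problems are reported with the offending file line.
#'
#' @param path Path to a CSV file.
#' @return An event catalog tibble.
#' @export
read_catalog <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = TRUE,
                    fileEncoding = "UTF-8"),
    error = function(e) abort(paste0("cannot parse '", path, "': ", conditionMessage(e))))
  if (nrow(raw) == 0) abort(paste0("'", path, "' contains no events"))
  missing <- setdiff(c("t", "x", "y"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("'", path, "' is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  num <- lapply(c(t = "t", x = "x", y = "y"), function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      # header occupies line 1, so data row i sits on file line i + 1
      abort(sprintf("non-numeric value '%s' in column '%s' at line %d of '%s'",
                    raw[[col]][bad[1]], col, bad[1] + 1L, path))
    }
    v
  })
  event_catalog(t = num$t, x = num$x, y = num$y)
}

#' Write an event catalog to CSV
#'
#' Columns `t`, `x`, `y` at full double precision, so a write/read
#' round-trip is lossless.
#'
#' @param data Event catalog.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_catalog <- function(data, path) {
  data <- as_event_catalog(data)
  readr::write_csv(data[, c("t", "x", "y")], path)
  invisible(data)
}

#' Project a geographic catalog to planar kilometers
#'
#' Locally scaled equirectangular projection:
#' `x = R cos(phi_ref) (lon - lon_ref) pi/180`,
#' `y = R (lat - phi_ref) pi/180`, with Earth radius R = 6371.0088 km and
#' the reference latitude/longitude at the midpoint of the input ranges.
#' Both axes are then shifted so their minima are zero. The projection
#' metadata (R, references, shifts) is attached as attribute
#' `"projection"` and suffices to invert the mapping.
#'
#' @param geo A data frame with columns `lon`, `lat` (degrees) and `t`.
#' @return An event catalog tibble with attribute `"projection"`.
#' @export
project_equirectangular <- function(geo) {
  for (col in c("lon", "lat", "t")) {
    if (!col %in% names(geo)) abort(paste0("geographic catalog needs column '", col, "'"))
  }
  if (nrow(geo) == 0) abort("geographic catalog is empty")
  if (any(geo$lon < -180 | geo$lon > 180)) abort("lon out of [-180, 180]")
  if (any(geo$lat < -90 | geo$lat > 90)) abort("lat out of [-90, 90]")
  R <- 6371.0088
  phi_ref <- (min(geo$lat) + max(geo$lat)) / 2
  lon_ref <- (min(geo$lon) + max(geo$lon)) / 2
  deg <- pi / 180
  x_raw <- R * cos(phi_ref * deg) * (geo$lon - lon_ref) * deg
  y_raw <- R * (geo$lat - phi_ref) * deg
  meta <- list(R = R, phi_ref = phi_ref, lon_ref = lon_ref,
               x_shift = min(x_raw), y_shift = min(y_raw))
  out <- event_catalog(t = geo$t, x = x_raw - meta$x_shift,
                       y = y_raw - meta$y_shift)
  attr(out, "projection") <- meta
  out
}

#' Invert an equirectangular projection
#'
#' @param data A projected catalog.
#' @param meta Projection metadata; defaults to the `"projection"`
#'   attribute of `data`.
#' @return A tibble with columns `t`, `lon`, `lat`.
#' @export
unproject_equirectangular <- function(data, meta = attr(data, "projection")) {
  if (is.null(meta)) abort("projection metadata missing")
  deg <- pi / 180
  tibble(t = data$t,
         lon = (data$x + meta$x_shift) / (meta$R * cos(meta$phi_ref * deg) * deg) +
           meta$lon_ref,
         lat = (data$y + meta$y_shift) / (meta$R * deg) + meta$phi_ref)
}
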