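# Gridded field containers and plain-text storage.
#
# Fields are stored as a time x cell matrix; cells are ordered latitude-fastest
# (cell = (ilon - 1) * n_lat + ilat), so a per-cell vector reshapes to an
# n_lat x n_lon matrix with matrix(x, n_lat, n_lon).

.cell_lat <- function(lat, lon) rep(lat, times = length(lon))
.cell_lon <- function(lat, lon) rep(lon, each = length(lat))

.check_grid <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
    stop("latitude centers must be finite and within [-90, 90]")
  }
  if (any(!is.finite(lon))) stop("longitude centers must be finite")
  invisible(TRUE)
}

#' Construct a daily gridded field
#'
#' A daily field holds one variable on a regular lat/lon grid over complete
#' no-leap years (365 values per year), together with the metadata the
#' extreme-day analysis needs: units, the extreme tail (`"upper"` for SST,
#' H+ and pCO2, `"lower"` for the aragonite saturation state) and the year
#' range covered.
#'
#' @param values Numeric matrix, time (365 x number of years rows) x cell.
#' @param variable Variable name (e.g. `"tos"`, `"hplus"`, `"spco2"`,
#'   `"omega"`).
#' @param units Physical units string.
#' @param tail `"upper"` or `"lower"`: which tail of the distribution is the
#'   stressful one.
#' @param years Length-2 integer vector, first and last year covered.
#' @param lat,lon Numeric vectors of cell-centre coordinates (degrees).
#' @return An object of class `daily_field`.
#' @export
daily_field <- function(values, variable, units, tail = c("upper", "lower"),
                        years, lat, lon) {
  tail <- match.arg(tail)
  .check_grid(lat, lon)
  values <- as.matrix(values)
  ny <- years[2] - years[1] + 1L
  if (ny < 1L) stop("years must be increasing")
  if (nrow(values) != 365L * ny) {
    stop("daily field must have 365 rows per year (noleap calendar): expected ",
         365L * ny, ", got ", nrow(values))
  }
  if (ncol(values) != length(lat) * length(lon)) {
    stop("values must have one column per grid cell")
  }
  structure(
    list(values = values, variable = variable, units = units, tail = tail,
         years = as.integer(years), lat = lat, lon = lon,
         calendar = "noleap"),
    class = "daily_field"
  )
}

#' Construct a monthly archive
#'
#' Monthly-mean fields over a long span of complete years; the source for
#' adaptive rolling baselines and detrended climatologies, mirroring archives
#' where daily output exists only for selected time slices.
#'
#' @inheritParams daily_field
#' @param values Numeric matrix, month-time (12 rows per year) x cell.
#' @return An object of class `monthly_archive`.
#' @export
monthly_archive <- function(values, variable, units, tail = c("upper", "lower"),
                            years, lat, lon) {
  tail <- match.arg(tail)
  .check_grid(lat, lon)
  values <- as.matrix(values)
  ny <- years[2] - years[1] + 1L
  if (ny < 1L) stop("years must be increasing")
  if (nrow(values) != 12L * ny) {
    stop("monthly archive must have 12 rows per year: expected ",
         12L * ny, ", got ", nrow(values))
  }
  if (ncol(values) != length(lat) * length(lon)) {
    stop("values must have one column per grid cell")
  }
  structure(
    list(values = values, variable = variable, units = units, tail = tail,
         years = as.integer(years), lat = lat, lon = lon,
         calendar = "noleap"),
    class = "monthly_archive"
  )
}

#' @export
print.daily_field <- function(x, ...) {
  cat(sprintf("<daily_field> %s [%s], tail=%s, years %d-%d, grid %d x %d\n",
              x$variable, x$units, x$tail, x$years[1], x$years[2],
              length(x$lat), length(x$lon)))
  invisible(x)
}

#' @export
print.monthly_archive <- function(x, ...) {
  cat(sprintf("<monthly_archive> %s [%s], tail=%s, years %d-%d, grid %d x %d\n",
              x$variable, x$units, x$tail, x$years[1], x$years[2],
              length(x$lat), length(x$lon)))
  invisible(x)
}

# --- time axis helpers -------------------------------------------------------

#' Per-time-step year / day-of-year / decimal-year vectors of a field
#' @param field A `daily_field` or `monthly_archive`.
#' @return List with `year`, `doy` (daily) or `month` (monthly), and `time`
#'   (decimal years).
#' @export
field_time <- function(field) {
  if (inherits(field, "daily_field")) {
    ax <- .daily_axis(field$years)
    ax$time <- decimal_year(ax$year, ax$doy)
  } else if (inherits(field, "monthly_archive")) {
    ax <- .monthly_axis(field$years)
    ax$time <- .decimal_year_month(ax$year, ax$month)
  } else {
    stop("field must be a daily_field or monthly_archive")
  }
  ax
}

#' Calendar-month means of a daily field
#'
#' @param field A `daily_field`.
#' @return A `monthly_archive` over the same years, each month the mean of its
#'   days.
#' @export
monthly_means <- function(field) {
  stopifnot(inherits(field, "daily_field"))
  ax <- .daily_axis(field$years)
  grp <- (ax$year - field$years[1]) * 12L + month_of_doy()[ax$doy]
  mv <- rowsum(field$values, grp, reorder = TRUE) /
    as.vector(table(grp))
  dimnames(mv) <- NULL
  monthly_archive(mv, field$variable, field$units, field$tail,
                  field$years, field$lat, field$lon)
}

# --- storage -----------------------------------------------------------------

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a gridded field to a plain-text file
#'
#' Self-describing ASCII storage: a header carrying the variable name, units,
#' tail, noleap calendar, days per year, year range and grid coordinates,
#' followed by one row per time step (explicit time index then cell values,
#' latitude-fastest ordering).  Values round-trip at full double precision.
#'
#' @param field A `daily_field` or `monthly_archive`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  kind <- if (inherits(field, "daily_field")) "daily" else
    if (inherits(field, "monthly_archive")) "monthly" else
      stop("field must be a daily_field or monthly_archive")
  per_year <- if (kind == "daily") 365L else 12L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "oax_field 1",
    paste("kind", kind),
    paste("variable", field$variable),
    paste("units", field$units),
    paste("tail", field$tail),
    paste("calendar", field$calendar),
    paste("steps_per_year", per_year),
    paste("years", field$years[1], field$years[2]),
    paste("nlat", length(field$lat)),
    paste("nlon", length(field$lon)),
    paste("lat", paste(.fmt_num(field$lat), collapse = " ")),
    paste("lon", paste(.fmt_num(field$lon), collapse = " ")),
    "data"
  ), con)
  body <- cbind(seq_len(nrow(field$values)), field$values)
  writeLines(apply(body, 1L, function(r) paste(.fmt_num(r), collapse = " ")),
             con)
  invisible(path)
}

#' Read a gridded field written by [write_field()]
#'
#' Validates the container invariants on read: the calendar must be the
#' 365-day no-leap calendar (366-day files are rejected as an unsupported
#' calendar), the time axis must be strictly increasing and complete, and the
#' grid must match the declared shape.
#'
#' @param path File path.
#' @return A `daily_field` or `monthly_archive` depending on the stored kind.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 13L || lines[1] != "oax_field 1") {
    stop("not an oax_field file: ", path)
  }
  hdr <- list()
  i <- 2L
  while (lines[i] != "data") {
    tok <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    hdr[[tok[1]]] <- tok[-1]
    i <- i + 1L
    if (i > length(lines)) stop("malformed header (no data section)")
  }
  if (hdr$calendar != "noleap") {
    stop("unsupported calendar: ", hdr$calendar, " (only noleap is supported)")
  }
  per_year <- as.integer(hdr$steps_per_year)
  kind <- hdr$kind
  if ((kind == "daily" && per_year != 365L) ||
      (kind == "monthly" && per_year != 12L)) {
    stop("unsupported calendar: ", per_year, " steps per year for kind ", kind)
  }
  years <- as.integer(hdr$years)
  nlat <- as.integer(hdr$nlat); nlon <- as.integer(hdr$nlon)
  lat <- as.numeric(hdr$lat); lon <- as.numeric(hdr$lon)
  stopifnot(length(lat) == nlat, length(lon) == nlon)
  body <- lines[(i + 1L):length(lines)]
  n_expect <- per_year * (years[2] - years[1] + 1L)
  if (length(body) != n_expect) {
    stop("incomplete time axis: expected ", n_expect, " steps, got ",
         length(body))
  }
  mat <- matrix(as.numeric(scan(text = body, what = "character",
                                quiet = TRUE)),
                nrow = n_expect, byrow = TRUE)
  tidx <- mat[, 1L]
  if (any(is.na(tidx)) || any(diff(tidx) <= 0)) {
    stop("time axis must be strictly increasing")
  }
  vals <- mat[, -1L, drop = FALSE]
  ctor <- if (kind == "daily") daily_field else monthly_archive
  ctor(vals, hdr$variable, paste(hdr$units, collapse = " "), hdr$tail,
       years, lat, lon)
}

# --- area weighting ----------------------------------------------------------

#' Cosine-latitude area weights
#'
#' Weights proportional to the cosine of the cell-centre latitude, normalised
#' to sum to one over non-missing cells.
#'
#' @param lat Latitude centres (degrees).
#' @param nlon Number of longitudes (weights are replicated across longitude
#'   in the package's latitude-fastest cell order). Default 1 treats `lat` as
#'   already per-cell.
#' @param missing Optional logical vector flagging cells to exclude.
#' @return Numeric per-cell weight vector summing to 1.
#' @export
area_weights <- function(lat, nlon = 1L, missing = NULL) {
  .check_grid(lat, 0)
  w <- rep(cos(lat * pi / 180), times = nlon)
  if (!is.null(missing)) {
    stopifnot(length(missing) == length(w))
    w[missing] <- 0
  }
  s <- sum(w)
  if (s <= 0) stop("all cells missing: cannot form area weights")
  w / s
}

#' Area-weighted global mean of a per-cell quantity
#'
#' Cells with missing values are dropped and the weights renormalised.
#'
#' @param x Per-cell numeric vector.
#' @param lat,lon Grid coordinate vectors (cell order latitude-fastest).
#' @return Scalar weighted mean.
#' @export
global_mean <- function(x, lat, lon) {
  w <- area_weights(lat, length(lon), missing = !is.finite(x))
  sum(w * ifelse(is.finite(x), x, 0))
}

#' Area-weighted spatial mean and standard deviation
#' @inheritParams global_mean
#' @return List with `mean` and `sd` (weighted, denominator `sum(w) = 1`).
#' @export
global_mean_sd <- function(x, lat, lon) {
  w <- area_weights(lat, length(lon), missing = !is.finite(x))
  x0 <- ifelse(is.finite(x), x, 0)
  m <- sum(w * x0)
  list(mean = m, sd = sqrt(sum(w * (x0 - m)^2)))
}

# --- sites -------------------------------------------------------------------

#' Construct a site set
#'
#' Named lat/lon points (e.g. marine protected areas) and/or named boolean
#' cell masks (e.g. coral-reef cells) used for site-level reporting.
#'
#' @param points Data frame with columns `name`, `lat`, `lon`, or `NULL`.
#' @param masks Named list of logical per-cell vectors, or `NULL`.
#' @return An object of class `site_set`.
#' @export
site_set <- function(points = NULL, masks = NULL) {
  if (!is.null(points)) {
    stopifnot(all(c("name", "lat", "lon") %in% names(points)))
  }
  if (!is.null(masks)) stopifnot(is.list(masks), !is.null(names(masks)))
  structure(list(points = points, masks = masks), class = "site_set")
}

#' Read a site table (name, lat, lon CSV) into a site set
#' @param path CSV path with header `name,lat,lon`.
#' @return A `site_set` with points only.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  site_set(points = df)
}

#' Map site points to grid cells
#'
#' Nearest-cell lookup by rectangular distance in (lat, lon); ties break
#' toward the lower cell index.  Points outside the grid's outer cell edges
#' are an error.
#'
#' @param sites A `site_set` with points.
#' @param lat,lon Grid coordinate vectors.
#' @return Integer vector of cell indices, named by site.
#' @export
site_cells <- function(sites, lat, lon) {
  stopifnot(inherits(sites, "site_set"), !is.null(sites$points))
  half <- function(v) if (length(v) > 1L) max(diff(sort(v))) / 2 else 0.5
  la <- .cell_lat(lat, lon); lo <- .cell_lon(lat, lon)
  out <- integer(nrow(sites$points))
  for (k in seq_len(nrow(sites$points))) {
    p <- sites$points[k, ]
    if (p$lat < min(lat) - half(lat) || p$lat > max(lat) + half(lat) ||
        p$lon < min(lon) - half(lon) || p$lon > max(lon) + half(lon)) {
      stop("site '", p$name, "' lies outside the grid")
    }
    d2 <- (la - p$lat)^2 + (lo - p$lon)^2
    out[k] <- which.min(d2) # which.min returns the first (lowest) index on ties
  }
  names(out) <- sites$points$name
  out
}

#' Extract per-site time series and mask cell collections from a field
#'
#' @param field A `daily_field` or `monthly_archive`.
#' @param sites A `site_set`.
#' @return List with `points` (time x site matrix of nearest-cell series) and
#'   `masks` (named list of time x cell sub-matrices).
#' @export
extract_sites <- function(field, sites) {
  stopifnot(inherits(sites, "site_set"))
  out <- list(points = NULL, masks = NULL)
  if (!is.null(sites$points)) {
    idx <- site_cells(sites, field$lat, field$lon)
    out$points <- field$values[, idx, drop = FALSE]
    colnames(out$points) <- names(idx)
  }
  if (!is.null(sites$masks)) {
    out$masks <- lapply(sites$masks, function(m) {
      stopifnot(length(m) == ncol(field$values))
      field$values[, m, drop = FALSE]
    })
  }
  out
}
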