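#' Gridded surface-current field
#'
#' Regular time x lat x lon grids of eastward (`u`) and northward (`v`)
#' surface current in m/s. Missing/masked cells (e.g. land) are `NA`.
#' Axes are stored ascending; inputs with descending axes are reordered.
#'
#' @param times POSIXct (UTC), regular and increasing.
#' @param lats,lons Monotone numeric axes (degrees).
#' @param u,v Numeric arrays, dim `c(length(times), length(lats),
#'   length(lons))`, units m/s.
#' @return Object of class `gridded_field`.
#' @export
gridded_field <- function(times, lats, lons, u, v) {
  times <- as.POSIXct(times, tz = "UTC")
  dm <- c(length(times), length(lats), length(lons))
  if (!identical(dim(u), as.integer(dm)) || !identical(dim(v), as.integer(dm)))
    stop("u/v dimensions do not match axes")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (length(lats) > 1 && diff(range(diff(order(lats)))) != 0 &&
      is.unsorted(lats) && is.unsorted(rev(lats)))
    stop("lats must be monotone")
  if (is.unsorted(lats)) { i <- rev(seq_along(lats))
    lats <- lats[i]; u <- u[, i, , drop = FALSE]; v <- v[, i, , drop = FALSE] }
  if (is.unsorted(lons)) { j <- rev(seq_along(lons))
    lons <- lons[j]; u <- u[, , j, drop = FALSE]; v <- v[, , j, drop = FALSE] }
  bad <- (!is.finite(u) & !is.na(u)) | (!is.finite(v) & !is.na(v))
  if (any(bad)) stop("u/v must be finite or NA")
  structure(list(times = times, lats = lats, lons = lons, u = u, v = v),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf(
    "Gridded u/v field: %d times x %d lats x %d lons, %.1f%% cells missing\n",
    length(x$times), length(x$lats), length(x$lons),
    100 * mean(is.na(x$u))))
  invisible(x)
}

.read_grid_header <- function(path) {
  meta <- character(0)
  con <- file(path, "r"); on.exit(close(con))
  n <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    n <- n + 1L
    kv <- sub("^#\\s*", "", ln)
    if (grepl(":", kv, fixed = TRUE)) {
      key <- trimws(sub(":.*", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[key] <- val
    }
  }
  list(meta = meta, skip = n)
}

.speed_unit_factor <- function(u) {
  u <- tolower(gsub("[ ^]", "", u %||% "m/s"))
  switch(u,
         "m/s" = , "ms-1" = , "meterspersecond" = 1,
         "cm/s" = , "cms-1" = 0.01,
         stop("unrecognised speed unit: ", u))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Read a gridded u/v current field from a plain-text grid file
#'
#' The format is a long-format CSV with columns `time, lat, lon, u, v` and
#' optional `# key: value` header lines; recognised keys `units_u` /
#' `units_v` (`m/s` default, `cm/s` converted). Empty `u`/`v` entries mark
#' masked cells. Every time/lat/lon combination must appear exactly once.
#'
#' @param path Path to the grid CSV.
#' @return A [gridded_field].
#' @export
read_gridded_field <- function(path) {
  h <- .read_grid_header(path)
  d <- utils::read.table(path, header = TRUE, sep = ",", skip = h$skip,
                         stringsAsFactors = FALSE)
  for (must in c("time", "lat", "lon", "u", "v"))
    if (!must %in% names(d)) stop("missing variable '", must, "' in grid file")
  fu <- .speed_unit_factor(h$meta["units_u"])
  fv <- .speed_unit_factor(h$meta["units_v"])
  times <- sort(unique(.parse_utc(d$time)))
  lats <- sort(unique(d$lat)); lons <- sort(unique(d$lon))
  dm <- c(length(times), length(lats), length(lons))
  if (nrow(d) != prod(dm)) stop("grid file is not a complete lattice")
  it <- match(.parse_utc(d$time), times)
  il <- match(d$lat, lats); io <- match(d$lon, lons)
  u <- array(NA_real_, dm); v <- array(NA_real_, dm)
  idx <- cbind(it, il, io)
  u[idx] <- d$u * fu
  v[idx] <- d$v * fv
  gridded_field(times, lats, lons, u, v)
}

#' Write a gridded field to the plain-text grid format
#'
#' @param field A [gridded_field].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gridded_field <- function(field, path) {
  g <- expand.grid(lon = field$lons, lat = field$lats, time = field$times,
                   KEEP.OUT.ATTRS = FALSE)
  idx <- cbind(match(g$time, field$times), match(g$lat, field$lats),
               match(g$lon, field$lons))
  d <- data.frame(time = format(g$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                  lat = g$lat, lon = g$lon,
                  u = field$u[idx], v = field$v[idx])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# gridded_field: surface currents",
               "# units_u: m/s", "# units_v: m/s"), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Bathymetry grid
#'
#' Depth in meters, positive down; cells with depth <= 0 or missing depth
#' are land.
#'
#' @param lats,lons Monotone axes (degrees); stored ascending.
#' @param depth Matrix `length(lats) x length(lons)` of depths (m).
#' @return Object of class `depth_grid` with a logical `land` mask.
#' @export
depth_grid <- function(lats, lons, depth) {
  if (!identical(dim(depth), c(length(lats), length(lons))))
    stop("depth dimensions do not match axes")
  if (is.unsorted(lats)) { lats <- rev(lats); depth <- depth[rev(seq_len(nrow(depth))), , drop = FALSE] }
  if (is.unsorted(lons)) { lons <- rev(lons); depth <- depth[, rev(seq_len(ncol(depth))), drop = FALSE] }
  structure(list(lats = lats, lons = lons, depth = depth,
                 land = is.na(depth) | depth <= 0),
            class = "depth_grid")
}

#' Read a bathymetry grid from a plain-text CSV (`lat, lon, depth`)
#'
#' @param path Path to the CSV (optional `#` header lines are skipped).
#' @return A [depth_grid].
#' @export
read_depth_grid <- function(path) {
  h <- .read_grid_header(path)
  d <- utils::read.table(path, header = TRUE, sep = ",", skip = h$skip,
                         stringsAsFactors = FALSE)
  for (must in c("lat", "lon", "depth"))
    if (!must %in% names(d)) stop("missing variable '", must, "' in depth file")
  lats <- sort(unique(d$lat)); lons <- sort(unique(d$lon))
  z <- matrix(NA_real_, length(lats), length(lons))
  z[cbind(match(d$lat, lats), match(d$lon, lons))] <- d$depth
  depth_grid(lats, lons, z)
}

#' Write a bathymetry grid as CSV
#' @param grid A [depth_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_grid <- function(grid, path) {
  g <- expand.grid(lon = grid$lons, lat = grid$lats, KEEP.OUT.ATTRS = FALSE)
  d <- data.frame(lat = g$lat, lon = g$lon,
                  depth = grid$depth[cbind(match(g$lat, grid$lats),
                                           match(g$lon, grid$lons))])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
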