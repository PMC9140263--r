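# Header aliases for CLS/Argos CSV exports; matched case-insensitively after
# squashing spaces, dots and underscores.
.ARGOS_ALIASES <- list(
  timestamp = c("timestamp", "date", "datetime", "datetime", "locdate",
                "locationdate", "time"),
  lon = c("lon", "longitude", "long"),
  lat = c("lat", "latitude"),
  quality_class = c("lc", "locquality", "locationquality", "qualityclass",
                    "quality", "class", "locclass", "locationclass"),
  ellipse_semi_major = c("smaj", "semimajor", "ellipsesemimajor",
                         "errorsemimajoraxis", "semimajoraxis"),
  ellipse_semi_minor = c("smin", "semiminor", "ellipsesemiminor",
                         "errorsemiminoraxis", "semiminoraxis"),
  ellipse_orientation = c("eor", "orientation", "ellipseorientation",
                          "errorellipseorientation")
)

.squash <- function(x) gsub("[ ._-]", "", tolower(x))

.parse_utc <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("Z$", "", sub("T", " ", x))
  fmts <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M:%S",
            "%d/%m/%Y %H:%M:%S", "%d.%m.%Y %H:%M:%S", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  left <- seq_along(x)
  for (f in fmts) {
    if (!length(left)) break
    p <- as.POSIXct(x[left], format = f, tz = "UTC")
    hit <- !is.na(p)
    out[left[hit]] <- p[hit]
    left <- left[!hit]
  }
  out
}

#' Construct a set of Argos observations
#'
#' Validates and orders raw satellite fixes. Timestamps are normalised to
#' UTC; duplicate timestamps are collapsed keeping the fix with the better
#' quality class (3 > 2 > 1 > 0 > A > B > Z).
#'
#' @param timestamp POSIXct (UTC) vector.
#' @param lon,lat Decimal degrees (WGS84).
#' @param quality_class Argos classes among 3, 2, 1, 0, A, B, Z.
#' @param ellipse_semi_major,ellipse_semi_minor Error-ellipse semi-axes in
#'   meters (NA when the export carries none).
#' @param ellipse_orientation Ellipse orientation, degrees clockwise from
#'   north.
#' @return A `data.frame` of class `argos_obs`, sorted by time.
#' @export
argos_obs <- function(timestamp, lon, lat, quality_class,
                      ellipse_semi_major = NA_real_,
                      ellipse_semi_minor = NA_real_,
                      ellipse_orientation = NA_real_) {
  n <- length(timestamp)
  d <- data.frame(
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    lon = as.numeric(lon), lat = as.numeric(lat),
    quality_class = as.character(quality_class),
    ellipse_semi_major = rep_len(as.numeric(ellipse_semi_major), n),
    ellipse_semi_minor = rep_len(as.numeric(ellipse_semi_minor), n),
    ellipse_orientation = rep_len(as.numeric(ellipse_orientation), n),
    stringsAsFactors = FALSE)
  attr(d$timestamp, "tzone") <- "UTC"
  bad <- !d$quality_class %in% .ARGOS_CLASSES
  if (any(bad))
    stop("unknown Argos quality class: ",
         paste(unique(d$quality_class[bad]), collapse = ", "))
  if (any(is.na(d$lat)) || any(abs(d$lat) > 90))
    stop("latitude out of [-90, 90]")
  if (any(is.na(d$lon)) || any(abs(d$lon) > 180))
    stop("longitude out of [-180, 180]")
  swap <- !is.na(d$ellipse_semi_major) & !is.na(d$ellipse_semi_minor) &
    d$ellipse_semi_major < d$ellipse_semi_minor
  if (any(swap))
    stop("ellipse semi-major axis smaller than semi-minor axis")
  neg <- (!is.na(d$ellipse_semi_major) & d$ellipse_semi_major < 0) |
    (!is.na(d$ellipse_semi_minor) & d$ellipse_semi_minor < 0)
  if (any(neg)) stop("negative ellipse axis")
  d <- d[order(d$timestamp, .class_rank(d$quality_class)), , drop = FALSE]
  d <- d[!duplicated(d$timestamp), , drop = FALSE]   # keeps best class
  rownames(d) <- NULL
  class(d) <- c("argos_obs", "data.frame")
  d
}

#' Read an Argos location CSV
#'
#' Accepts comma- or semicolon-separated exports; header names are matched
#' case-insensitively against a documented alias table (e.g. `lc`,
#' `Loc. quality` or `Location class` all map to the quality class). Unknown
#' columns are ignored. Rows are sorted by timestamp and duplicate
#' timestamps collapsed keeping the better quality class.
#'
#' @param path Path to the CSV file.
#' @return An [argos_obs] data frame, with attributes `n_input` (rows read)
#'   and `n_rejected` (rows dropped, with reasons in attribute `rejected`).
#' @export
read_argos <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(hdr, gregexpr(";", hdr))) >
             lengths(regmatches(hdr, gregexpr(",", hdr)))) ";" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  keymap <- character(0)
  for (canon in names(.ARGOS_ALIASES)) {
    hit <- which(.squash(names(raw)) %in% .ARGOS_ALIASES[[canon]])
    if (length(hit)) keymap[[canon]] <- names(raw)[hit[1]]
  }
  for (must in c("timestamp", "lon", "lat", "quality_class"))
    if (is.na(keymap[must]) || !must %in% names(keymap))
      stop(sprintf("missing mandatory column '%s' (aliases: %s)", must,
                   paste(.ARGOS_ALIASES[[must]], collapse = ", ")))
  ts <- .parse_utc(raw[[keymap["timestamp"]]])
  bad_ts <- which(is.na(ts))
  if (length(bad_ts))
    stop(sprintf("unparseable timestamp at data line(s) %s (e.g. '%s')",
                 paste(head(bad_ts, 5), collapse = ", "),
                 raw[[keymap["timestamp"]]][bad_ts[1]]))
  pick <- function(canon) {
    if (canon %in% names(keymap)) raw[[keymap[canon]]] else NA_real_
  }
  obs <- argos_obs(ts, pick("lon"), pick("lat"), pick("quality_class"),
                   pick("ellipse_semi_major"), pick("ellipse_semi_minor"),
                   pick("ellipse_orientation"))
  dup <- nrow(raw) - nrow(obs)
  attr(obs, "n_input") <- nrow(raw)
  attr(obs, "n_rejected") <- dup
  attr(obs, "rejected") <-
    if (dup > 0) data.frame(reason = rep("duplicate timestamp", dup))
    else data.frame(reason = character(0))
  obs
}

#' @export
print.argos_obs <- function(x, ...) {
  cat(sprintf("Argos observations: %d fixes, %s to %s\n", nrow(x),
              format(min(x$timestamp), "%Y-%m-%d %H:%M"),
              format(max(x$timestamp), "%Y-%m-%d %H:%M")))
  print(table(factor(x$quality_class, levels = .ARGOS_CLASSES)))
  invisible(x)
}
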