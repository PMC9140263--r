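#' Write a predicted track to CSV or GeoJSON
#'
#' CSV output round-trips exactly through [read_track()]: coordinates keep
#' at least 6 decimal places and all label columns are preserved. GeoJSON
#' output contains one `LineString` for the path plus one point `Feature`
#' per step carrying the step's properties.
#'
#' @param track A `track_steps` data frame (regular predicted states, as
#'   returned by [predict_path()] and extended downstream).
#' @param path Output path.
#' @param format `"csv"` (default) or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (!is.data.frame(track) || nrow(track) == 0)
    stop("track is empty: nothing to write")
  d <- as.data.frame(track)
  d$timestamp <- format(d$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.8f", x))
  d[num] <- lapply(d[num], function(x) ifelse(x == "NA", "", x))
  if (format == "csv") {
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    feats <- lapply(seq_len(nrow(d)), function(i) {
      props <- as.list(d[i, setdiff(names(d), c("lon", "lat")), drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(as.numeric(d$lon[i]),
                                           as.numeric(d$lat[i]))),
           properties = props)
    })
    line <- list(type = "Feature",
                 geometry = list(
                   type = "LineString",
                   coordinates = lapply(seq_len(nrow(d)), function(i)
                     c(as.numeric(d$lon[i]), as.numeric(d$lat[i])))),
                 properties = list(name = "predicted_path"))
    gj <- list(type = "FeatureCollection", features = c(list(line), feats))
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a track CSV written by [write_track()]
#'
#' @param path Path to the CSV.
#' @return A `track_steps` data frame.
#' @export
read_track <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
  d$timestamp <- .parse_utc(d$timestamp)
  class(d) <- c("track_steps", "data.frame")
  d
}

#' @export
print.track_steps <- function(x, ...) {
  cat(sprintf("Predicted track: %d steps at regular intervals, %s to %s\n",
              nrow(x), format(min(x$timestamp), "%Y-%m-%d"),
              format(max(x$timestamp), "%Y-%m-%d")))
  if (!is.null(x$speed_ground))
    cat(sprintf("  speed over ground: median %.2f m/s\n",
                stats::median(x$speed_ground, na.rm = TRUE)))
  if (!is.null(x$gamma))
    cat(sprintf("  movement persistence: median %.2f\n",
                stats::median(x$gamma, na.rm = TRUE)))
  invisible(x)
}
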