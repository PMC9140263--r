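#' Azimuthal equidistant projection (ellipsoidal)
#'
#' Projects lon/lat to planar meters so that the geodesic distance and
#' azimuth from the projection center are preserved exactly:
#' `x = d sin(az)`, `y = d cos(az)` with `d`/`az` the WGS84 geodesic
#' distance and forward azimuth from the center.
#'
#' @param lon,lat Coordinates to project (degrees).
#' @param center `c(lon, lat)` of the projection center.
#' @return Matrix with columns `x`, `y` (meters).
#' @seealso [unproject_azimuthal_equidistant()]
#' @export
project_azimuthal_equidistant <- function(lon, lat, center) {
  stopifnot(length(center) == 2, all(is.finite(center)))
  p <- cbind(as.numeric(lon), as.numeric(lat))
  inv <- geosphere::geodesic_inverse(rbind(center), p)
  d <- inv[, "distance"]
  if (any(d > 2.0e7))
    stop("point at/near the antipode of the projection center: ",
         "azimuthal equidistant projection is singular there")
  az <- inv[, "azimuth1"] * pi / 180
  out <- cbind(x = d * sin(az), y = d * cos(az))
  out[d == 0, ] <- 0
  out
}

#' Inverse azimuthal equidistant projection
#'
#' @param x,y Planar coordinates (meters) from
#'   [project_azimuthal_equidistant()].
#' @param center `c(lon, lat)` used for the forward projection.
#' @return Matrix with columns `lon`, `lat` (degrees).
#' @export
unproject_azimuthal_equidistant <- function(x, y, center) {
  d <- sqrt(x^2 + y^2)
  az <- atan2(x, y) * 180 / pi
  out <- cbind(lon = rep(center[1], length(d)),
               lat = rep(center[2], length(d)))
  nz <- d > 0
  if (any(nz)) {
    g <- geosphere::geodesic(rbind(center), az[nz], d[nz])
    out[nz, 1] <- g[, "longitude"]
    out[nz, 2] <- g[, "latitude"]
  }
  out
}

#' Settings for the speed/distance/angle pre-filter
#'
#' @param vmax Maximum plausible sustained speed (m/s), default 9.
#' @param spike_angles Internal angles (degrees) below which a fix is a
#'   candidate "spike", paired with `spike_distances`; defaults 15 and 25.
#' @param spike_distances Minimum leg lengths (m) for the paired angle
#'   test; defaults 2500 and 5000.
#' @param drop_classes Argos classes removed unconditionally, default `"Z"`.
#' @return Object of class `filter_settings`.
#' @export
filter_settings <- function(vmax = 9, spike_angles = c(15, 25),
                            spike_distances = c(2500, 5000),
                            drop_classes = "Z") {
  stopifnot(vmax > 0, length(spike_angles) == length(spike_distances),
            all(spike_angles >= 0), all(spike_distances >= 0))
  structure(list(vmax = vmax, spike_angles = spike_angles,
                 spike_distances = spike_distances,
                 drop_classes = as.character(drop_classes)),
            class = "filter_settings")
}

.geo_dist <- function(lon1, lat1, lon2, lat2)
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2))

# internal angle (deg, in [0, 180]) at vertex i between the legs to the
# previous and next fix; small angle = out-and-back spike
.turn_angle <- function(lon, lat) {
  n <- length(lon)
  if (n < 3) return(numeric(0))
  b1 <- geosphere::bearing(cbind(lon[2:(n - 1)], lat[2:(n - 1)]),
                           cbind(lon[1:(n - 2)], lat[1:(n - 2)]))
  b2 <- geosphere::bearing(cbind(lon[2:(n - 1)], lat[2:(n - 1)]),
                           cbind(lon[3:n], lat[3:n]))
  a <- abs(((b1 - b2) %% 360))
  pmin(a, 360 - a)
}

# among candidate indices pick the one to drop: worst quality class first,
# then the latest fix (deterministic tie-breaking)
.pick_removal <- function(cand, lc) {
  r <- .class_rank(lc[cand])
  cand <- cand[r == max(r)]
  max(cand)
}

#' Speed/distance/angle filter for Argos fixes
#'
#' Removes implausible fixes before state-space modelling. Class-Z fixes
#' (and any class in `drop_classes`) are removed first. Then fixes for
#' which the transit speed both from the previous and to the next retained
#' fix exceeds `vmax` are removed iteratively (one per pass, worst quality
#' class then latest first), so that no retained triple implies an
#' above-`vmax` speed into and out of any fix. Finally internal "spikes"
#' (turning angle below `spike_angles[k]` with both adjacent legs longer
#' than `spike_distances[k]`) are removed the same way. Speeds and leg
#' lengths use WGS84 geodesic distances.
#'
#' @param obs An [argos_obs] data frame (time-sorted).
#' @param settings A [filter_settings] object.
#' @return A list with `kept` (an [argos_obs] subset, same order) and
#'   `report` (data frame: original row `index`, `timestamp`, `reason`,
#'   one of `"class"`, `"speed"`, `"spike"`).
#' @export
sda_filter <- function(obs, settings = filter_settings()) {
  if (nrow(obs) < 3) stop("insufficient data: need at least 3 observations")
  keep <- !(obs$quality_class %in% settings$drop_classes)
  report <- data.frame(index = which(!keep),
                       timestamp = obs$timestamp[!keep],
                       reason = rep("class", sum(!keep)))
  if (sum(keep) < 3)
    stop("insufficient data: fewer than 3 usable observations ",
         "after class filtering")
  drop_pass <- function(keep, candidates_fun, reason) {
    repeat {
      idx <- which(keep)
      cand <- candidates_fun(idx)
      if (!length(cand)) break
      out <- .pick_removal(cand, obs$quality_class)
      keep[out] <- FALSE
      report <<- rbind(report,
                       data.frame(index = out, timestamp = obs$timestamp[out],
                                  reason = reason))
      if (sum(keep) < 3) break
    }
    keep
  }
  speed_cands <- function(idx) {
    lon <- obs$lon[idx]; lat <- obs$lat[idx]
    tt <- as.numeric(obs$timestamp[idx])
    d <- .geo_dist(lon[-length(lon)], lat[-length(lat)], lon[-1], lat[-1])
    sp <- d / pmax(diff(tt), 1e-9)
    bad <- which(sp[-length(sp)] > settings$vmax &
                   sp[-1] > settings$vmax) + 1L
    idx[bad]
  }
  keep <- drop_pass(keep, speed_cands, "speed")
  spike_cands <- function(idx) {
    lon <- obs$lon[idx]; lat <- obs$lat[idx]
    if (length(idx) < 3) return(integer(0))
    ang <- .turn_angle(lon, lat)
    d <- .geo_dist(lon[-length(lon)], lat[-length(lat)], lon[-1], lat[-1])
    din <- d[-length(d)]; dout <- d[-1]
    bad <- rep(FALSE, length(ang))
    for (k in seq_along(settings$spike_angles))
      bad <- bad | (ang < settings$spike_angles[k] &
                      din > settings$spike_distances[k] &
                      dout > settings$spike_distances[k])
    idx[which(bad) + 1L]
  }
  keep <- drop_pass(keep, spike_cands, "spike")
  kept <- obs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(obs)
  report <- report[order(report$index), , drop = FALSE]
  rownames(report) <- NULL
  list(kept = kept, report = report)
}
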