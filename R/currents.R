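#' Sample the surface current at a track step
#'
#' Nearest-neighbour extraction, time first then space. Ties are broken
#' toward the earlier time record and the lower cell index. When the
#' nearest cell is masked (land/missing) the search expands in rings of
#' grid cells up to `radius` cells, recording the great-circle distance to
#' the cell actually used; when no valid cell exists within the radius the
#' step is flagged missing and treated as zero current.
#'
#' @param field A [gridded_field].
#' @param lon,lat,time Step position (degrees) and POSIXct time.
#' @param radius Maximum fallback search radius in cells, default 3.
#' @return List: `u`, `v` (m/s), `missing` flag, `time_offset` (s, signed
#'   step time minus record time), `cell` (lat/lon indices used),
#'   `fallback_distance` (m, 0 when the nearest cell was valid).
#' @export
sample_current <- function(field, lon, lat, time, radius = 3) {
  dt <- as.numeric(time) - as.numeric(field$times)
  it <- which.min(abs(dt) - 1e-9 * (dt > 0))   # tie -> earlier record
  il <- which.min(abs(field$lats - lat))
  io <- which.min(abs(field$lons - lon))
  miss <- list(u = 0, v = 0, missing = TRUE, time_offset = dt[it],
               cell = c(NA_integer_, NA_integer_), fallback_distance = NA_real_)
  found <- NULL
  for (r in 0:radius) {
    ii <- max(1, il - r):min(length(field$lats), il + r)
    jj <- max(1, io - r):min(length(field$lons), io + r)
    cand <- expand.grid(i = ii, j = jj)
    cand <- cand[pmax(abs(cand$i - il), abs(cand$j - io)) == r, , drop = FALSE]
    ok <- !is.na(field$u[cbind(it, cand$i, cand$j)]) &
      !is.na(field$v[cbind(it, cand$i, cand$j)])
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      d <- .geo_dist(lon, lat, field$lons[cand$j], field$lats[cand$i])
      k <- which(d == min(d))
      # lowest (lat, lon) index among equidistant cells
      k <- k[order(cand$i[k], cand$j[k])][1]
      found <- list(i = cand$i[k], j = cand$j[k],
                    d = if (r == 0) 0 else d[k])
      break
    }
  }
  if (is.null(found)) return(miss)
  list(u = field$u[it, found$i, found$j], v = field$v[it, found$i, found$j],
       missing = FALSE, time_offset = dt[it],
       cell = c(found$i, found$j), fallback_distance = found$d)
}

#' Correct speed over ground for the ambient current
#'
#' Subtracts the current vector from the over-ground velocity to obtain the
#' swim (through-water) velocity: `swim = ground - current`. Also
#' decomposes the current into a support component (projection onto the
#' over-ground travel direction; positive = current pushes along the
#' track) and a signed cross component (positive = current points to the
#' left of the travel direction).
#'
#' @param dx,dy Over-ground displacement over the step (meters, east/north).
#' @param u,v Current vector (m/s).
#' @param dt_s Step duration (s), > 0.
#' @return List: `speed_water` (m/s), `swim_u`, `swim_v`, `support`,
#'   `cross`, `undefined_direction` (TRUE for a zero ground displacement,
#'   where support/cross are set to 0).
#' @export
correct_speed <- function(dx, dy, u, v, dt_s) {
  if (dt_s <= 0) stop("step duration must be > 0")
  gx <- dx / dt_s; gy <- dy / dt_s
  sx <- gx - u; sy <- gy - v
  gn <- sqrt(gx^2 + gy^2)
  if (gn == 0) {
    return(list(speed_water = sqrt(u^2 + v^2), swim_u = sx, swim_v = sy,
                support = 0, cross = 0, undefined_direction = TRUE))
  }
  ex <- gx / gn; ey <- gy / gn
  list(speed_water = sqrt(sx^2 + sy^2), swim_u = sx, swim_v = sy,
       support = u * ex + v * ey,
       cross = -u * ey + v * ex,
       undefined_direction = FALSE)
}

#' Classify a step as resting or transiting
#'
#' Inclusive boundary on the resting side: a swim speed exactly at the
#' threshold counts as resting.
#'
#' @param speed_water Swim speed through water (m/s, >= 0); vectorised.
#' @param threshold Threshold (m/s), default 0.5.
#' @return Character vector, `"resting"` or `"transiting"`.
#' @export
classify_behavior <- function(speed_water, threshold = 0.5) {
  if (any(speed_water < 0, na.rm = TRUE)) stop("negative swim speed")
  ifelse(speed_water <= threshold, "resting", "transiting")
}

#' Attach currents and swim speeds to a predicted track
#'
#' For every step (row i to row i+1) samples the current at the step's
#' start position and time, computes the through-water speed and the
#' support/cross decomposition, and classifies behaviour. Step quantities
#' are attached to the step's starting row; the final row keeps `NA`s.
#'
#' The over-ground velocity vector for a step is built from the geodesic
#' distance and initial bearing between the step's endpoints, so its
#' magnitude equals the speed over ground exactly (and with a zero-current
#' field the through-water speed reproduces the over-ground speed
#' identically).
#'
#' @param track A `track_steps` data frame with `lon`, `lat` and
#'   timestamps on a regular grid.
#' @param field A [gridded_field], or NULL for a zero-current ocean.
#' @param threshold Resting/transiting threshold (m/s).
#' @param radius Fallback search radius (cells) for masked cells.
#' @return The track with columns `u`, `v`, `support`, `cross`,
#'   `speed_water`, `current_missing`, `behavior` added, plus an attribute
#'   `n_current_missing`.
#' @export
attach_currents <- function(track, field = NULL, threshold = 0.5,
                            radius = 3) {
  n <- nrow(track)
  dt_s <- as.numeric(diff(track$timestamp[1:2]), units = "secs")
  u <- v <- sup <- crs <- vw <- su <- sv <- rep(NA_real_, n)
  miss <- rep(NA, n)
  p1 <- cbind(track$lon[-n], track$lat[-n])
  p2 <- cbind(track$lon[-1], track$lat[-1])
  dgeo <- geosphere::distGeo(p1, p2)
  az <- geosphere::bearing(p1, p2) * pi / 180
  az[dgeo == 0] <- 0
  dx <- dgeo * sin(az); dy <- dgeo * cos(az)
  for (i in seq_len(n - 1)) {
    cur <- if (is.null(field)) list(u = 0, v = 0, missing = FALSE)
           else sample_current(field, track$lon[i], track$lat[i],
                               track$timestamp[i], radius)
    cc <- correct_speed(dx[i], dy[i], cur$u, cur$v, dt_s)
    u[i] <- cur$u; v[i] <- cur$v
    sup[i] <- cc$support; crs[i] <- cc$cross
    vw[i] <- cc$speed_water
    su[i] <- cc$swim_u; sv[i] <- cc$swim_v
    miss[i] <- cur$missing
  }
  track$u <- u; track$v <- v
  track$support <- sup; track$cross <- crs
  track$speed_water <- vw
  track$swim_u <- su; track$swim_v <- sv
  track$current_missing <- miss
  track$behavior <- c(classify_behavior(vw[-n], threshold), NA)
  attr(track, "n_current_missing") <- sum(miss, na.rm = TRUE)
  track
}
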