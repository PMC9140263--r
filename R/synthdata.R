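#' Synthetic deployment scenario specification
#'
#' Defines a multi-phase movement scenario with known ground truth: an
#' ordered phase plan (duration, true persistence, true mean swim speed,
#' optional waypoint steering transit headings), a calving event encoded
#' as the boundary in front of a named phase, the Argos sampling model
#' (fix rate, quality-class mix, class-dependent error-ellipse scales,
#' outlier and class-Z injection), and toy current/depth grids.
#'
#' A single scenario seed governs all randomness; each component (truth,
#' observation, currents, depth) draws from its own derived sub-seed so
#' that, e.g., changing the observation noise does not perturb the truth.
#'
#' @param phases Data frame with columns `name`, `days`, `gamma`,
#'   `speed` (m/s), and optional `to_lon`, `to_lat` (waypoint; `NA` for
#'   area-restricted residence phases).
#' @param start_time POSIXct deployment start (UTC).
#' @param start Deployment start position `c(lon, lat)`.
#' @param calving_phase Name of the phase whose start is the calving
#'   event (or `NA` for none).
#' @param interval_hours Truth step interval, default 6.
#' @param speed_cv Coefficient of variation of within-phase speed
#'   fluctuations, default 0.25.
#' @param argos List: `fixes_per_day` (13), `class_probs` (named over
#'   3,2,1,0,A,B), `ellipse_scale` (named semi-major means, m),
#'   `error_scale` (1; 0 gives noiseless fixes), `outlier_rate` (0.01),
#'   `outlier_km` (c(150, 400)), `z_rate` (0.01).
#' @param current List: `amplitude` (m/s, 0.1), `wavelength_deg` (18),
#'   `resolution_deg` (1), `n_times` (8).
#' @param depth List: `default_depth` (3000 m), `resolution_deg` (1),
#'   `land` (list of lon/lat polygon matrices).
#' @param projection_center Working projection center, default
#'   `c(-20, 45)`.
#' @param seed Integer scenario seed.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(phases, start_time, start,
                          calving_phase = NA_character_,
                          interval_hours = 6, speed_cv = 0.25,
                          argos = list(), current = list(), depth = list(),
                          projection_center = c(-20, 45), seed = 42L) {
  stopifnot(is.data.frame(phases),
            all(c("name", "days", "gamma", "speed") %in% names(phases)))
  if (any(phases$days <= 0)) stop("phase durations must be > 0")
  if (any(phases$speed < 0)) stop("phase speeds must be >= 0")
  if (any(phases$speed > 9))
    stop("impossible spec: phase mean speed above 9 m/s")
  if (any(phases$gamma < 0 | phases$gamma > 1))
    stop("phase gamma must lie in [0, 1]")
  adef <- list(fixes_per_day = 13,
               class_probs = c("3" = 0.05, "2" = 0.10, "1" = 0.15,
                               "0" = 0.15, "A" = 0.25, "B" = 0.30),
               # typical Kalman-era CLS ellipse semi-major magnitudes;
               # coarser than the legacy class-SD fallback table because
               # modern A/B fixes carry usable ellipses of a few km
               ellipse_scale = c("3" = 250, "2" = 500, "1" = 1000,
                                 "0" = 3000, "A" = 2000, "B" = 4000),
               error_scale = 1, outlier_rate = 0.01,
               outlier_km = c(150, 400), z_rate = 0.01)
  adef[names(argos)] <- argos
  if (abs(sum(adef$class_probs) - 1) > 1e-8)
    stop("class mix must sum to 1")
  cdef <- list(amplitude = 0.1, wavelength_deg = 18, resolution_deg = 1,
               n_times = 8)
  cdef[names(current)] <- current
  ddef <- list(default_depth = 3000, resolution_deg = 1, land = list())
  ddef[names(depth)] <- depth
  structure(list(phases = phases,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 start = start, calving_phase = calving_phase,
                 interval_hours = interval_hours, speed_cv = speed_cv,
                 argos = adef, current = cdef, depth = ddef,
                 projection_center = projection_center,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# derived sub-seeds keep component RNG streams independent
.sub_seed <- function(spec, k) (spec$seed * 7L + k * 1009L) %% 2147483647L

#' Paper-scale default scenario
#'
#' A 321-day round-trip deployment emulating the structure of a tracked
#' NEA humpback migration: winter residence in coastal Norway, a fast
#' transit to Iceland (1.9 m/s), an Iceland stopover, the southbound
#' transit to the West Indies with a calving event dropping the mean
#' speed from 1.7 to 1.3 m/s, a breeding-ground residence, a 71-day
#' northbound transit at 1.5 m/s, and a Barents Sea feeding residence.
#' Persistence is high (0.9) in transit and low (0.25-0.3) in residence.
#'
#' @param seed Scenario seed, default 42.
#' @param ... Overrides passed on to [scenario_spec()] (`argos`,
#'   `current`, `depth`, ...).
#' @return A [scenario_spec()].
#' @export
paper_like_scenario <- function(seed = 42L, ...) {
  phases <- data.frame(
    name = c("norway_residence", "migration_south1", "iceland_residence",
             "migration_south2_pre", "migration_south2_post",
             "westindies_residence", "migration_north",
             "barents_residence"),
    days = c(30, 7, 15, 24, 37, 16, 71, 121),
    gamma = c(0.05, 0.90, 0.05, 0.90, 0.90, 0.05, 0.90, 0.05),
    speed = c(0.40, 1.90, 0.40, 1.70, 1.30, 0.35, 1.50, 0.45),
    to_lon = c(NA, -13.5, NA, -49, -68.9, NA, 9, NA),
    to_lat = c(NA, 65, NA, 39, 20.1, NA, 73, NA))
  scenario_spec(phases, start_time = as.POSIXct("2019-01-08 00:00:00",
                                                tz = "UTC"),
                start = c(19.5, 70), calving_phase = "migration_south2_post",
                seed = seed, ...)
}

#' Simulate the true 6-hourly track of a scenario
#'
#' Displacements follow a per-phase vector AR(1) around a mean
#' displacement: transit phases steer with a constant heading towards the
#' phase waypoint (set at phase entry), residence phases have zero mean
#' displacement, and the AR coefficient is the phase's true persistence.
#' Noise is calibrated so the realized mean speed matches the phase's
#' target speed (Rayleigh mean for residence phases).
#'
#' @param spec A [scenario_spec()].
#' @return A `truth_track` data frame: `timestamp`, `x`, `y` (projected
#'   meters), `lon`, `lat`, `phase`, `gamma_true`, `speed_true` (m/s, the
#'   step leaving each row; last row `NA`), `calving` flag (TRUE from the
#'   calving event onward).
#' @export
simulate_truth <- function(spec) {
  set.seed(.sub_seed(spec, 1L))
  dt <- spec$interval_hours * 3600
  spd <- 24 / spec$interval_hours
  p0 <- project_azimuthal_equidistant(spec$start[1], spec$start[2],
                                      spec$projection_center)
  pos <- c(p0[1, 1], p0[1, 2])
  X <- list(); ph_lab <- list(); gam <- list(); calv <- list()
  after_calving <- FALSE
  for (r in seq_len(nrow(spec$phases))) {
    ph <- spec$phases[r, ]
    if (identical(ph$name, spec$calving_phase)) after_calving <- TRUE
    nst <- round(ph$days * spd)
    transit <- !is.na(ph$to_lon)
    if (transit) {
      # directed phase: mean displacement towards the waypoint plus
      # independent per-step fluctuations; persistence comes from the
      # directedness itself.  |m + e| has mean ~ |m| (1 + cv^2/2), so the
      # mean vector is shrunk by that factor to keep the realized mean
      # speed on target
      w <- project_azimuthal_equidistant(ph$to_lon, ph$to_lat,
                                         spec$projection_center)
      dirv <- c(w[1, 1] - pos[1], w[1, 2] - pos[2])
      dirv <- dirv / sqrt(sum(dirv^2))
      m <- dirv * ph$speed * dt / (1 + spec$speed_cv^2 / 2)
      tau <- spec$speed_cv * ph$speed * dt
      ar <- 0
    } else {
      # area-restricted residence: zero-mean AR(1) displacements whose
      # Rayleigh mean magnitude matches the phase's target speed
      m <- c(0, 0)
      tau <- ph$speed * dt / sqrt(pi / 2)
      ar <- ph$gamma
    }
    s <- tau * sqrt(1 - ar^2)
    D <- matrix(0, nst, 2)
    # regime switches are abrupt: restart the displacement process at the
    # phase mean
    prev <- m
    for (i in seq_len(nst)) {
      d <- m + ar * (prev - m) + rnorm(2, 0, max(s, 1e-9))
      D[i, ] <- d
      prev <- d
    }
    X[[r]] <- D
    ph_lab[[r]] <- rep(ph$name, nst)
    gam[[r]] <- rep(ph$gamma, nst)
    calv[[r]] <- rep(after_calving, nst)
    pos <- pos + colSums(D)
  }
  D <- do.call(rbind, X)
  n <- nrow(D) + 1
  xy <- rbind(c(p0[1, 1], p0[1, 2]),
              sweep(apply(D, 2, cumsum), 2, -c(p0[1, 1], p0[1, 2])))
  ll <- unproject_azimuthal_equidistant(xy[, 1], xy[, 2],
                                        spec$projection_center)
  # true step speeds are geodesic (real-world), not planar: the working
  # projection distorts distances between points away from its center
  dgeo <- geosphere::distGeo(ll[-n, , drop = FALSE], ll[-1, , drop = FALSE])
  out <- data.frame(
    timestamp = spec$start_time + (seq_len(n) - 1) * dt,
    x = xy[, 1], y = xy[, 2], lon = ll[, 1], lat = ll[, 2],
    phase = c(unlist(ph_lab), tail(unlist(ph_lab), 1)),
    gamma_true = c(unlist(gam), tail(unlist(gam), 1)),
    speed_true = c(dgeo / dt, NA_real_),
    calving = c(unlist(calv), tail(unlist(calv), 1)))
  class(out) <- c("truth_track", "data.frame")
  out
}

#' Generate Argos observations of a true track
#'
#' Fix times are a Poisson process at the configured rate; positions are
#' linearly interpolated along the true 6-hourly path and perturbed with
#' anisotropic Gaussian error drawn from a class-dependent error ellipse
#' (semi-major axis lognormal around the class scale, aspect ratio
#' uniform in 0.4-0.9, orientation uniform). Gross outliers (uniform
#' 150-400 km displacements) and class-Z rows are injected at the
#' configured rates.
#'
#' @param truth A `truth_track` from [simulate_truth()].
#' @param spec The [scenario_spec()].
#' @return An [argos_obs] data frame.
#' @export
observe_argos <- function(truth, spec) {
  set.seed(.sub_seed(spec, 2L))
  a <- spec$argos
  t0 <- as.numeric(truth$timestamp[1])
  t1 <- as.numeric(tail(truth$timestamp, 1))
  ndays <- (t1 - t0) / 86400
  nfix <- rpois(1, a$fixes_per_day * ndays)
  tf <- round(sort(t0 + runif(nfix) * (t1 - t0)))
  tf <- unique(tf)
  nfix <- length(tf)
  px <- approx(as.numeric(truth$timestamp), truth$x, xout = tf)$y
  py <- approx(as.numeric(truth$timestamp), truth$y, xout = tf)$y
  cls <- sample(names(a$class_probs), nfix, TRUE, a$class_probs)
  smaj <- a$ellipse_scale[cls] * exp(rnorm(nfix, 0, 0.3)) * a$error_scale
  smin <- smaj * runif(nfix, 0.4, 0.9)
  th <- runif(nfix, 0, 180)
  thr <- th * pi / 180
  e1 <- rnorm(nfix); e2 <- rnorm(nfix)
  ex <- smaj * e1 * sin(thr) + smin * e2 * cos(thr)
  ey <- smaj * e1 * cos(thr) - smin * e2 * sin(thr)
  x <- px + ex; y <- py + ey
  is_out <- runif(nfix) < a$outlier_rate
  if (any(is_out)) {
    dd <- runif(sum(is_out), a$outlier_km[1], a$outlier_km[2]) * 1000
    an <- runif(sum(is_out), 0, 2 * pi)
    x[is_out] <- x[is_out] + dd * sin(an)
    y[is_out] <- y[is_out] + dd * cos(an)
    cls[is_out] <- "B"
  }
  is_z <- !is_out & runif(nfix) < a$z_rate
  cls[is_z] <- "Z"
  ll <- unproject_azimuthal_equidistant(x, y, spec$projection_center)
  if (a$error_scale == 0) { smaj[] <- 0; smin[] <- 0 }
  obs <- argos_obs(as.POSIXct(round(tf), origin = "1970-01-01", tz = "UTC"),
                   ll[, 1], ll[, 2], cls, smaj, smin, th)
  attr(obs, "outlier_times") <- round(tf[is_out])
  obs
}

#' Toy divergence-free surface-current field for a scenario
#'
#' Currents derive from a smooth doubly periodic streamfunction on a
#' fixed local-meter metric, so the field is non-divergent by
#' construction; amplitude 0 gives an all-zero field. The grid covers the
#' track bounding box plus a margin, replicated over a coarse regular
#' time axis.
#'
#' @param spec A [scenario_spec()].
#' @param truth The `truth_track` (sets the bounding box).
#' @return A [gridded_field].
#' @export
make_current_field <- function(spec, truth) {
  set.seed(.sub_seed(spec, 3L))
  cs <- spec$current
  lats <- seq(floor(min(truth$lat)) - 2, ceiling(max(truth$lat)) + 2,
              by = cs$resolution_deg)
  lons <- seq(floor(min(truth$lon)) - 2, ceiling(max(truth$lon)) + 2,
              by = cs$resolution_deg)
  times <- seq(truth$timestamp[1], tail(truth$timestamp, 1),
               length.out = cs$n_times)
  lat0 <- mean(range(lats))
  my <- 111320                       # meters per degree latitude
  mx <- 111320 * cos(lat0 * pi / 180)
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  Lx <- cs$wavelength_deg * mx; Ly <- cs$wavelength_deg * my
  G <- expand.grid(lat = lats, lon = lons)
  xs <- G$lon * mx; ys <- G$lat * my
  u0 <- -cs$amplitude * sin(2 * pi * xs / Lx + ph1) *
    cos(2 * pi * ys / Ly + ph2)
  v0 <- cs$amplitude * (Ly / Lx) * cos(2 * pi * xs / Lx + ph1) *
    sin(2 * pi * ys / Ly + ph2)
  dm <- c(length(times), length(lats), length(lons))
  u <- array(rep(matrix(u0, length(lats), length(lons)), each = dm[1]), dm)
  v <- array(rep(matrix(v0, length(lats), length(lons)), each = dm[1]), dm)
  gridded_field(times, lats, lons, u, v)
}

# even-odd ray casting; poly is a matrix with columns lon, lat
.point_in_poly <- function(lon, lat, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(lon))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Toy bathymetry grid for a scenario
#'
#' Constant default depth with land polygons rasterized to land (depth 0).
#'
#' @param spec A [scenario_spec()].
#' @param truth The `truth_track` (sets the bounding box), or NULL with
#'   explicit `lats`/`lons`.
#' @param lats,lons Optional explicit axes.
#' @return A [depth_grid].
#' @export
make_depth_grid <- function(spec, truth = NULL, lats = NULL, lons = NULL) {
  ds <- spec$depth
  if (is.null(lats)) {
    lats <- seq(floor(min(truth$lat)) - 2, ceiling(max(truth$lat)) + 2,
                by = ds$resolution_deg)
    lons <- seq(floor(min(truth$lon)) - 2, ceiling(max(truth$lon)) + 2,
                by = ds$resolution_deg)
  }
  z <- matrix(ds$default_depth, length(lats), length(lons))
  G <- expand.grid(lat = lats, lon = lons)
  for (poly in ds$land) {
    inside <- .point_in_poly(G$lon, G$lat, poly)
    z[matrix(inside, length(lats), length(lons))] <- 0
  }
  depth_grid(lats, lons, z)
}
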