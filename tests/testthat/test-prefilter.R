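test_that("azimuthal equidistant projection preserves center distance", {
  ctr <- c(-20, 45)
  expect_equal(unname(project_azimuthal_equidistant(-20, 45, ctr)[1, ]),
               c(0, 0))
  # a point 100 km due north of the center
  p <- geosphere::geodesic(rbind(ctr), 0, 1e5)
  xy <- project_azimuthal_equidistant(p[1, 1], p[1, 2], ctr)
  expect_equal(xy[1, "x"], 0, tolerance = 1e-6)
  expect_equal(xy[1, "y"], 1e5, tolerance = 1e-3)

  # round trip over scattered points
  set.seed(1)
  lon <- runif(50, -80, 30); lat <- runif(50, 10, 75)
  xy <- project_azimuthal_equidistant(lon, lat, ctr)
  ll <- unproject_azimuthal_equidistant(xy[, 1], xy[, 2], ctr)
  expect_lt(max(abs(ll[, 1] - lon)), 1e-6)
  expect_lt(max(abs(ll[, 2] - lat)), 1e-6)
  # distance from center preserved
  d_geo <- geosphere::distGeo(rbind(ctr), cbind(lon, lat))
  expect_equal(sqrt(xy[, 1]^2 + xy[, 2]^2), d_geo, tolerance = 1e-9)

  expect_error(project_azimuthal_equidistant(160, -45, ctr), "antipode")
})

make_track_obs <- function(lon, lat, lc = NULL, dt_h = 6) {
  n <- length(lon)
  argos_obs(as.POSIXct("2019-01-08", tz = "UTC") + (0:(n - 1)) * dt_h * 3600,
            lon, lat, if (is.null(lc)) rep("3", n) else lc)
}

test_that("sda filter keeps clean tracks and drops speed outliers", {
  # straight track at ~0.3 m/s: nothing removed
  lon <- seq(0, by = 0.06, length.out = 10)
  obs <- make_track_obs(lon, rep(60, 10))
  out <- sda_filter(obs)
  expect_equal(nrow(out$kept), 10)
  expect_equal(nrow(out$report), 0)

  # middle fix of a 3-point track requiring ~12 m/s in and out (vmax 9)
  obs3 <- make_track_obs(c(0, 1.55, 0.1), rep(60, 3), dt_h = 2)
  out3 <- sda_filter(obs3)
  expect_false(1.55 %in% out3$kept$lon)
  expect_equal(out3$report$reason, "speed")

  # class-Z rows always removed regardless of geometry
  obsz <- make_track_obs(seq(0, 0.5, length.out = 6), rep(60, 6),
                         lc = c("3", "Z", "3", "3", "Z", "3"))
  outz <- sda_filter(obsz)
  expect_equal(nrow(outz$kept), 4)
  expect_true(all(outz$report$reason == "class"))
  expect_false("Z" %in% outz$kept$quality_class)
})

test_that("sda filter is idempotent and returns a subsequence", {
  set.seed(42)
  lon <- cumsum(c(0, rnorm(19, 0.03, 0.05)))
  lat <- cumsum(c(60, rnorm(19, 0, 0.04)))
  obs <- make_track_obs(lon, lat, lc = sample(c("3", "1", "B"), 20, TRUE))
  out1 <- sda_filter(obs)
  out2 <- sda_filter(out1$kept)
  expect_equal(nrow(out2$report), 0)
  expect_equal(out2$kept, out1$kept)
  # subsequence: kept rows appear in the input, in order
  key <- paste(obs$timestamp, obs$lon)
  expect_true(all(paste(out1$kept$timestamp, out1$kept$lon) %in% key))
  expect_false(is.unsorted(match(paste(out1$kept$timestamp, out1$kept$lon),
                                 key)))
})

test_that("speed criterion matches the brute-force oracle on random tracks", {
  set.seed(7)
  settings <- filter_settings(spike_angles = numeric(0),
                              spike_distances = numeric(0))
  for (rep in 1:30) {
    n <- 20
    lon <- cumsum(c(runif(1, -10, 10), rnorm(n - 1, 0.02, 0.08)))
    lat <- cumsum(c(runif(1, 50, 65), rnorm(n - 1, 0, 0.06)))
    # inject 0-3 wild outliers
    k <- sample(0:3, 1)
    if (k > 0) {
      at <- sample(2:(n - 1), k)
      lon[at] <- lon[at] + runif(k, 2, 5) * sample(c(-1, 1), k, TRUE)
    }
    lc <- sample(c("3", "2", "1", "0", "A", "B"), n, TRUE)
    obs <- make_track_obs(lon, lat, lc, dt_h = 2)
    got <- sda_filter(obs, settings)
    keep <- oracle_speed_filter(obs, vmax = 9)
    expect_equal(got$kept$timestamp, obs$timestamp[keep],
                 info = paste("replicate", rep))
  }
})

test_that("angle/distance spikes are removed", {
  # sharp out-and-back excursion: ~25 km out and back at < 15 degrees,
  # but transit speeds stay below vmax
  lon <- c(0, 0.05, 0.1, 0.1, 0.15, 0.2)
  lat <- c(60, 60, 60, 60.25, 60, 60)
  obs <- make_track_obs(lon, lat, dt_h = 6)
  out <- sda_filter(obs)
  expect_true("spike" %in% out$report$reason)
  expect_false(60.25 %in% out$kept$lat)
})

test_that("too few usable observations raise an error", {
  obs <- make_track_obs(c(0, 0.1), c(60, 60))
  expect_error(sda_filter(obs), "insufficient")
  obs2 <- make_track_obs(c(0, 0.1, 0.2, 0.3), c(60, 60, 60, 60),
                         lc = c("Z", "Z", "3", "3"))
  expect_error(sda_filter(obs2), "insufficient")
})
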