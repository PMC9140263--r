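test_that("scenario specification validates its inputs", {
  ph <- data.frame(name = "a", days = 10, gamma = 0.5, speed = 1,
                   to_lon = NA, to_lat = NA)
  expect_s3_class(scenario_spec(ph, "2019-01-01", c(0, 60)),
                  "scenario_spec")
  ph$speed <- 10
  expect_error(scenario_spec(ph, "2019-01-01", c(0, 60)), "impossible")
  ph$speed <- 1; ph$days <- 0
  expect_error(scenario_spec(ph, "2019-01-01", c(0, 60)), "> 0")
  expect_error(scenario_spec(data.frame(name = "a", days = 1, gamma = 0.5,
                                        speed = 1),
                             "2019-01-01", c(0, 60),
                             argos = list(class_probs = c("3" = 0.5))),
               "sum to 1")
})

test_that("simulated truth realizes target speeds and is reproducible", {
  spec <- scenario_spec(
    phases = data.frame(name = "transit", days = 30, gamma = 0.9,
                        speed = 1.5, to_lon = -40, to_lat = 50),
    start_time = "2019-01-01", start = c(-20, 62), seed = 5)
  tr <- simulate_truth(spec)
  expect_equal(nrow(tr), 121)
  # law-of-large-numbers check at n = 120 steps
  expect_lt(abs(mean(tr$speed_true, na.rm = TRUE) / 1.5 - 1), 0.05)
  tr2 <- simulate_truth(spec)
  expect_identical(tr, tr2)
})

test_that("the seven-phase plan is carried into labels and calving flag", {
  spec <- paper_like_scenario(seed = 2)
  tr <- simulate_truth(spec)
  expect_equal(nrow(tr), 321 * 4 + 1)
  expect_equal(rle(tr$phase)$values, spec$phases$name)
  expect_equal(unname(rle(tr$phase)$lengths[1:7]),
               spec$phases$days[1:7] * 4)
  # calving flag flips exactly at the declared phase boundary
  expect_equal(min(which(tr$calving)), (30 + 7 + 15 + 24) * 4 + 1)
})

test_that("argos observation of a track behaves to contract", {
  spec <- scenario_spec(
    phases = data.frame(name = "t", days = 10, gamma = 0.9, speed = 1.5,
                        to_lon = -30, to_lat = 55),
    start_time = "2019-01-01", start = c(-20, 60), seed = 8,
    argos = list(fixes_per_day = 12, outlier_rate = 0, z_rate = 0))
  tr <- simulate_truth(spec)
  obs <- observe_argos(tr, spec)
  # Poisson rate contract: ~120 fixes over 10 days
  expect_gt(nrow(obs), 120 - 4 * sqrt(120))
  expect_lt(nrow(obs), 120 + 4 * sqrt(120))

  # noiseless limit: observations sit on the interpolated truth
  spec0 <- scenario_spec(
    phases = spec$phases, start_time = "2019-01-01", start = c(-20, 60),
    seed = 8, argos = list(error_scale = 0, outlier_rate = 0, z_rate = 0))
  tr0 <- simulate_truth(spec0)
  obs0 <- observe_argos(tr0, spec0)
  xy <- project_azimuthal_equidistant(obs0$lon, obs0$lat,
                                      spec0$projection_center)
  px <- approx(as.numeric(tr0$timestamp), tr0$x,
               as.numeric(obs0$timestamp))$y
  py <- approx(as.numeric(tr0$timestamp), tr0$y,
               as.numeric(obs0$timestamp))$y
  expect_lt(max(abs(xy[, 1] - px)), 2)
  expect_lt(max(abs(xy[, 2] - py)), 2)
})

test_that("injected gross outliers are caught by the pre-filter", {
  caught <- 0; total <- 0
  for (seed in 1:25) {
    spec <- scenario_spec(
      phases = data.frame(name = "t", days = 12, gamma = 0.9, speed = 1.5,
                          to_lon = -30, to_lat = 55),
      start_time = "2019-01-01", start = c(-20, 60), seed = seed,
      argos = list(outlier_rate = 0.05, z_rate = 0))
    tr <- simulate_truth(spec)
    obs <- observe_argos(tr, spec)
    out_t <- attr(obs, "outlier_times")
    if (!length(out_t)) next
    filt <- sda_filter(obs)
    kept_t <- as.numeric(filt$kept$timestamp)
    caught <- caught + sum(!(out_t %in% kept_t))
    total <- total + length(out_t)
  }
  expect_gt(total, 20)
  expect_gte(caught / total, 0.95)
})

test_that("toy current field is divergence-free and scales with amplitude", {
  spec <- scenario_spec(
    phases = data.frame(name = "t", days = 5, gamma = 0.9, speed = 1.5,
                        to_lon = -25, to_lat = 58),
    start_time = "2019-01-01", start = c(-20, 60), seed = 3,
    current = list(resolution_deg = 0.25))
  tr <- simulate_truth(spec)
  f <- make_current_field(spec, tr)
  # finite-difference divergence on the construction metric
  lat0 <- mean(range(f$lats))
  mx <- 111320 * cos(lat0 * pi / 180); my <- 111320
  u <- f$u[1, , ]; v <- f$v[1, , ]
  dudx <- (u[, -1] - u[, -ncol(u)]) / (diff(f$lons)[1] * mx)
  dvdy <- (v[-1, ] - v[-nrow(v), ]) / (diff(f$lats)[1] * my)
  div <- dudx[-nrow(dudx), ] + dvdy[, -ncol(dvdy)]
  # central-difference truncation only: small relative to |u| scale
  expect_lt(max(abs(div)), 1e-6)

  spec0 <- spec; spec0$current$amplitude <- 0
  f0 <- make_current_field(spec0, tr)
  expect_true(all(f0$u == 0) && all(f0$v == 0))
})

test_that("land polygons mask the depth grid", {
  spec <- scenario_spec(
    phases = data.frame(name = "t", days = 5, gamma = 0.9, speed = 1.5,
                        to_lon = -25, to_lat = 58),
    start_time = "2019-01-01", start = c(-20, 60), seed = 3,
    depth = list(land = list(cbind(c(-24, -22, -22, -24),
                                   c(57, 57, 59, 59)))))
  tr <- simulate_truth(spec)
  g <- make_depth_grid(spec, tr)
  inside <- which(g$lats > 57 & g$lats < 59)
  jnside <- which(g$lons > -24 & g$lons < -22)
  expect_true(all(g$land[inside, jnside]))
  expect_false(all(g$land))
})
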