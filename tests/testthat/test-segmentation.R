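test_that("constant series yields a single segment", {
  s <- lavielle_segment(rep(0.5, 40), Kmax = 4, Lmin = 8)
  expect_equal(s$K, 1)
  expect_length(s$breakpoints, 0)
  expect_equal(s$segment_means, 0.5)
})

test_that("a clean step change is located within one index", {
  set.seed(3)
  y <- c(rnorm(20, 0.1, 0.02), rnorm(20, 0.9, 0.02))
  s <- lavielle_segment(y, Kmax = 4, Lmin = 5)
  expect_equal(s$K, 2)
  expect_lte(abs(s$breakpoints - 20), 1)
  # oracle: exhaustive search over all single-breakpoint placements
  costs <- vapply(5:35, function(b)
    sum((y[1:b] - mean(y[1:b]))^2) +
      sum((y[(b + 1):40] - mean(y[(b + 1):40]))^2), numeric(1))
  expect_equal(s$breakpoints, (5:35)[which.min(costs)])
})

test_that("DP contrast equals exhaustive enumeration (n<=30, K<=3)", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    y <- rnorm(n) + rep(c(0, 2, -1), each = ceiling(n / 3))[1:n]
    lmin <- sample(2:3, 1)
    s <- lavielle_segment(y, Kmax = 3, Lmin = lmin)
    for (K in 1:3) {
      if (!is.finite(s$contrast[K])) next
      expect_equal(s$contrast[K], oracle_exhaustive_contrast(y, K, lmin),
                   tolerance = 1e-10, info = paste("rep", rep, "K", K))
    }
  }
})

test_that("contrast is non-increasing in K", {
  set.seed(13)
  for (rep in 1:10) {
    y <- cumsum(rnorm(60))
    s <- lavielle_segment(y, Kmax = 6, Lmin = 4)
    J <- s$contrast[is.finite(s$contrast)]
    expect_true(all(diff(J) <= 1e-9))
  }
})

test_that("segment means equal the arithmetic means of their values", {
  set.seed(21)
  y <- c(rnorm(30, 0), rnorm(30, 3))
  s <- lavielle_segment(y, Kmax = 4, Lmin = 8)
  bounds <- c(0, s$breakpoints, s$n)
  for (k in seq_len(s$K))
    expect_equal(s$segment_means[k],
                 mean(y[(bounds[k] + 1):bounds[k + 1]]))
})

test_that("input validation", {
  expect_error(lavielle_segment(rnorm(10), Kmax = 2, Lmin = 8), "2\\*Lmin")
  expect_error(lavielle_segment(rnorm(30), Kmax = 10, Lmin = 8), "exceeds")
  expect_error(lavielle_segment(c(rnorm(30), NA), Kmax = 2, Lmin = 5),
               "missing")
})

test_that("migration phases alternate by persistence level", {
  set.seed(8)
  gam <- c(rnorm(60, 0.2, 0.04), rnorm(80, 0.9, 0.04), rnorm(60, 0.25, 0.04))
  tr <- data.frame(
    timestamp = as.POSIXct("2019-01-01", tz = "UTC") + (0:199) * 21600,
    gamma = pmin(pmax(gam, 0.01), 0.99))
  ph <- detect_migration_phases(tr, refine_with_speed = FALSE)
  expect_equal(ph$segmentation$K, 3)
  expect_equal(ph$phases$label, c("residence", "transit", "residence"))
  expect_lte(abs(ph$phases$end_index[1] - 60), 2)
  # all-transit track: one segment, warned
  tr2 <- tr
  tr2$gamma <- pmin(pmax(rnorm(200, 0.9, 0.03), 0.01), 0.99)
  expect_warning(ph2 <- detect_migration_phases(tr2,
                                                refine_with_speed = FALSE),
                 "fewer than 2")
  expect_equal(ph2$segmentation$K, 1)
})

test_that("speed refinement re-dates a late persistence breakpoint", {
  set.seed(12)
  n <- 160
  sp <- c(rnorm(80, 1.7, 0.2), rnorm(80, 0.4, 0.1))
  gam <- c(rnorm(90, 0.9, 0.03), rnorm(70, 0.3, 0.03))  # 10 steps late
  tr <- data.frame(
    timestamp = as.POSIXct("2019-01-01", tz = "UTC") + (0:(n - 1)) * 21600,
    gamma = pmin(pmax(gam, 0.01), 0.99),
    speed_ground = pmax(sp, 0.01))
  raw <- detect_migration_phases(tr, refine_with_speed = FALSE)
  ref <- detect_migration_phases(tr)
  expect_gte(abs(raw$breakpoints[1] - 80), 8)
  expect_lte(abs(ref$breakpoints[1] - 80), 2)
})

test_that("calving change-point and medians are recovered", {
  set.seed(19)
  # 25 days at 1.7 m/s then 35 days at 1.3 m/s, 6-h steps
  sp <- c(rnorm(100, 1.7, 0.25), rnorm(140, 1.3, 0.25))
  tr <- data.frame(
    timestamp = as.POSIXct("2019-03-01", tz = "UTC") + (0:239) * 21600,
    speed_water = pmax(sp, 0.05),
    speed_ground = pmax(sp, 0.05) + 0.05)
  cal <- detect_calving(tr)
  expect_true(cal$change_detected)
  expect_equal(cal$speed_source, "water")
  expect_lte(abs(cal$breakpoint_index - 100), 4)   # within one day
  expect_equal(cal$median_pre, 1.7, tolerance = 0.08)
  expect_equal(cal$median_post, 1.3, tolerance = 0.08)

  # K = 2 optimum equals the best single split by exhaustive search
  seg <- lavielle_segment(tr$speed_water, Kmax = 2, Lmin = 8)
  expect_equal(seg$contrast[2],
               oracle_exhaustive_contrast(tr$speed_water, 2, 8),
               tolerance = 1e-9)
})

test_that("constant-speed leg reports no change", {
  tr <- data.frame(
    timestamp = as.POSIXct("2019-03-01", tz = "UTC") + (0:99) * 21600,
    speed_water = rep(1.5, 100), speed_ground = rep(1.5, 100))
  cal <- detect_calving(tr)
  expect_false(cal$change_detected)
  # too short for any admissible breakpoint: explicit no-change result
  cal2 <- detect_calving(tr[1:10, ])
  expect_false(cal2$change_detected)
})
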