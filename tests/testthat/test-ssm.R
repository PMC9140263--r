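line_obs <- function(n = 40, speed = 1.5, dt_h = 3, heading = 90,
                     lat0 = 55, lon0 = -20, smaj = 50) {
  tt <- (0:(n - 1)) * dt_h * 3600
  p <- geosphere::geodesic(cbind(lon0, lat0), heading, speed * tt)
  argos_obs(as.POSIXct("2019-03-01", tz = "UTC") + tt, p[, 1], p[, 2],
            rep("3", n), smaj, smaj * 0.8, 30)
}

test_that("noiseless constant-velocity fixes reproduce the line", {
  obs <- line_obs()
  fit <- fit_crw(obs, center = c(-20, 55), estimate_psi = FALSE)
  expect_equal(fit$convergence, 0)
  path <- predict_path(fit, 6)
  # linear interpolation oracle in projected plane
  xy_obs <- project_azimuthal_equidistant(obs$lon, obs$lat, c(-20, 55))
  tt <- as.numeric(obs$timestamp)
  ref_x <- approx(tt, xy_obs[, 1], as.numeric(path$timestamp))$y
  ref_y <- approx(tt, xy_obs[, 2], as.numeric(path$timestamp))$y
  expect_lt(max(abs(path$x - ref_x)), 1)
  expect_lt(max(abs(path$y - ref_y)), 1)
  # speed over ground = displacement / interval
  expect_equal(median(path$speed_ground, na.rm = TRUE), 1.5,
               tolerance = 0.01)
})

test_that("prediction grid has one state per interval from the first fix", {
  obs <- line_obs(n = 81, dt_h = 6)          # exactly 20 days
  fit <- fit_crw(obs, center = c(-20, 55), estimate_psi = FALSE)
  path <- predict_path(fit, 6)
  expect_equal(nrow(path), 4 * 20 + 1)
  expect_equal(as.numeric(diff(path$timestamp), units = "hours"),
               rep(6, nrow(path) - 1))
  expect_error(predict_path(fit, 0), "interval")
})

test_that("Kalman smoother matches an independently coded R oracle", {
  set.seed(11)
  tt <- c(0, 3000, 7000, 15000, 26000, 40000)
  z <- matrix(rnorm(12, 0, 2000), 6, 2)
  R3 <- cbind(runif(6, 500, 3000)^2, runif(6, 500, 3000)^2, 0)
  a0 <- c(z[1, 1], 0, z[1, 2], 0)
  P0 <- c(1e8, 9, 1e8, 9)
  beta <- 1e-4; s2 <- 2e-4; psi <- 1.3
  got <- cetatrack:::.ctcrw_kalman_cpp(tt, z, R3, beta, s2, psi, a0, P0,
                                       TRUE)
  want <- oracle_kalman_r(tt, z, R3, beta, s2, psi, a0, P0)
  expect_equal(got$loglik, want$loglik, tolerance = 1e-8)
  expect_lt(max(abs(got$smooth_mean - want$smooth_mean)), 1e-6)
  expect_lt(max(abs(got$smooth_cov - want$smooth_cov)), 1e-6)
})

test_that("parameters are recovered on simulated tracks", {
  set.seed(23)
  beta <- 1 / (8 * 3600)                 # 8 h velocity autocorrelation
  sigma2 <- 2 * beta * 1.2^2             # 1.2 m/s stationary speed scale
  tt <- sort(runif(300, 0, 20 * 86400))
  x <- sim_ctcrw_exact(tt, beta, sigma2)
  ctr <- c(-20, 55)
  ll <- unproject_azimuthal_equidistant(x[, 1] + rnorm(300, 0, 300),
                                        x[, 2] + rnorm(300, 0, 300), ctr)
  obs <- argos_obs(as.POSIXct("2019-03-01", tz = "UTC") + tt,
                   ll[, 1], ll[, 2], rep("3", 300), 300, 300, 0)
  fit <- fit_crw(obs, center = ctr, estimate_psi = FALSE)
  ci_lo <- exp(fit$log_par - 1.96 * fit$log_se)
  ci_hi <- exp(fit$log_par + 1.96 * fit$log_se)
  expect_gt(beta, ci_lo[1]); expect_lt(beta, ci_hi[1])
  expect_gt(sigma2, ci_lo[2]); expect_lt(sigma2, ci_hi[2])
})

test_that("fit_crw validates its inputs", {
  obs <- line_obs(n = 10)
  expect_error(fit_crw(obs[1:5, ]), "20 observations")
  obs2 <- line_obs(n = 30, dt_h = 0.5)
  expect_error(fit_crw(obs2), "2 days")
})

test_that("inflating observation error inflates positional uncertainty", {
  set.seed(5)
  obs <- line_obs(n = 50, smaj = 2000)
  fit <- fit_crw(obs, center = c(-20, 55), estimate_psi = FALSE)
  p1 <- predict_path(fit, 6)
  fit4 <- fit
  fit4$psi <- 4
  p4 <- predict_path(fit4, 6)
  expect_true(all(p4$x_se > p1$x_se))
  expect_true(all(p4$y_se > p1$y_se))
})

test_that("the smoothed state sequence has the highest joint density", {
  # the RTS-smoothed mean is the posterior mode of the whole state
  # sequence, so the joint (process + observation) log-density at the
  # smoothed sequence must dominate the filtered sequence on any fixture
  set.seed(9)
  beta <- 1e-4; s2 <- 3e-4
  tt <- sort(runif(80, 0, 10 * 86400))
  x <- sim_ctcrw_exact(tt, beta, s2)
  sd0 <- 1500
  z <- x + matrix(rnorm(160, 0, sd0), 80, 2)
  R3 <- cbind(rep(sd0^2, 80), rep(sd0^2, 80), 0)
  k <- cetatrack:::.ctcrw_kalman_cpp(tt, z, R3, beta, s2, 1,
                                     c(z[1, 1], 0, z[1, 2], 0),
                                     c(1e8, 9, 1e8, 9), TRUE)
  joint_ll <- function(m) {
    ll <- sum(dnorm(z[, 1], m[, 1], sd0, log = TRUE) +
                dnorm(z[, 2], m[, 3], sd0, log = TRUE))
    for (i in 2:80) {
      dt <- tt[i] - tt[i - 1]
      phi <- exp(-beta * dt)
      qvv <- s2 * (1 - phi^2) / (2 * beta)
      qxv <- s2 * (1 - phi)^2 / (2 * beta^2)
      qxx <- s2 * (dt - 2 * (1 - phi) / beta +
                     (1 - phi^2) / (2 * beta)) / beta^2
      Q <- matrix(c(qxx, qxv, qxv, qvv), 2)
      for (d in c(0, 2)) {
        pred <- c(m[i - 1, 1 + d] + m[i - 1, 2 + d] * (1 - phi) / beta,
                  m[i - 1, 2 + d] * phi)
        ll <- ll + mvn2_logdens(m[i, (1:2) + d] - pred, Q)
      }
    }
    ll
  }
  expect_gte(joint_ll(k$smooth_mean), joint_ll(k$filt_mean))
})

test_that("persistence hits the directed and meandering limits", {
  set.seed(31)
  # directed: constant heading, fluctuation sd = |m|/3 (gamma ~ 0.9)
  n <- 200
  m <- c(30000, 10000)
  D1 <- sweep(matrix(rnorm(2 * n, 0, sqrt(sum(m^2)) / 3), n, 2), 2, m, `+`)
  P1 <- apply(rbind(0, D1), 2, cumsum)
  g1 <- estimate_persistence(P1)
  expect_gt(mean(g1$gamma), 0.9 - 0.1)

  # meandering: independent jitter around a fixed point
  P2 <- matrix(rnorm(2 * n, 0, 5000), n, 2)
  g2 <- estimate_persistence(P2)
  expect_lt(mean(g2$gamma), 0.3)

  expect_error(estimate_persistence(matrix(1, 10, 2)), "no movement")
})

test_that("two-regime persistence is recovered within 0.15", {
  set.seed(77)
  n1 <- 150; n2 <- 150
  m <- c(25000, 5000)
  D1 <- sweep(matrix(rnorm(2 * n1, 0, sqrt(sum(m^2)) / 3), n1, 2), 2, m,
              `+`)                              # persistence ~ 0.9
  D2 <- matrix(0, n2, 2)                        # AR(0.2) jitter
  prev <- c(0, 0)
  for (i in seq_len(n2)) {
    prev <- 0.2 * prev + rnorm(2, 0, 6000)
    D2[i, ] <- prev
  }
  P <- apply(rbind(c(0, 0), D1, D2), 2, cumsum)
  g <- estimate_persistence(P)
  expect_lt(abs(mean(g$gamma[2:(n1 - 10)]) - 0.9), 0.15)
  expect_lt(abs(mean(g$gamma[(n1 + 20):(n1 + n2 - 10)]) - 0.2), 0.15)
})
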