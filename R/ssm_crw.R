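#' Error ellipse to 2x2 observation covariance
#'
#' Convention: variance `semi_major^2` along the major axis, `semi_minor^2`
#' along the minor axis, with the major-axis direction measured in degrees
#' clockwise from north (so a 0-degree ellipse is elongated north-south).
#' Fixes without an ellipse fall back to class-based isotropic standard
#' deviations ([argos_class_sd()]).
#'
#' @param obs An [argos_obs] data frame.
#' @param class_sd Named fallback SDs (m) by quality class.
#' @return n x 3 matrix with columns `rxx`, `ryy`, `rxy` (m^2), x = east,
#'   y = north.
#' @export
ellipse_covariance <- function(obs, class_sd = argos_class_sd()) {
  M <- obs$ellipse_semi_major
  m <- obs$ellipse_semi_minor
  th <- obs$ellipse_orientation * pi / 180
  have <- !is.na(M) & !is.na(m) & !is.na(th)
  rxx <- ryy <- rxy <- numeric(nrow(obs))
  if (any(have)) {
    s2 <- M[have]^2; n2 <- m[have]^2
    sth <- sin(th[have]); cth <- cos(th[have])
    rxx[have] <- s2 * sth^2 + n2 * cth^2
    ryy[have] <- s2 * cth^2 + n2 * sth^2
    rxy[have] <- (s2 - n2) * sth * cth
  }
  if (any(!have)) {
    sd0 <- class_sd[obs$quality_class[!have]]
    if (any(is.na(sd0)))
      stop("no fallback SD for class(es): ",
           paste(unique(obs$quality_class[!have][is.na(sd0)]), collapse = ", "))
    rxx[!have] <- ryy[!have] <- sd0^2
  }
  # a zero-variance fix would make the filter singular; floor at 1 m sd
  cbind(rxx = pmax(rxx, 1), ryy = pmax(ryy, 1), rxy = rxy)
}

#' Fit a continuous-time correlated random walk to Argos fixes
#'
#' Maximum-likelihood fit of an integrated Ornstein-Uhlenbeck velocity
#' process (velocity autocorrelation time scale `1/beta`, velocity
#' diffusion variance `sigma2`) observed through per-fix anisotropic
#' Gaussian error derived from each Argos error ellipse, optionally
#' inflated by a common factor `psi`. The likelihood is evaluated with an
#' exact-discretisation Kalman filter over the irregular fix times;
#' optimisation is run from three spread starting values (velocity
#' autocorrelation time scales of 1 h, 6 h and 24 h) and the best
#' likelihood wins.
#'
#' @param obs A filtered [argos_obs] data frame (>= 20 fixes spanning >= 2
#'   days).
#' @param center Projection center `c(lon, lat)` for the planar working
#'   frame; defaults to the track midpoint range center.
#' @param estimate_psi Estimate the observation-variance inflation factor
#'   (default TRUE); when FALSE `psi` is fixed at 1.
#' @param class_sd Fallback isotropic SDs for fixes without an ellipse.
#' @return Object of class `crw_fit`: parameters (`beta` 1/s, `sigma2`
#'   m^2/s^3, `psi`), their standard errors on the log scale, `loglik`,
#'   `convergence`, and the projected data reused by [predict_path()].
#' @export
fit_crw <- function(obs, center = NULL, estimate_psi = TRUE,
                    class_sd = argos_class_sd()) {
  if (nrow(obs) < 20) stop("need at least 20 observations to fit the CTCRW")
  tsec <- as.numeric(obs$timestamp)
  if (diff(range(tsec)) < 2 * 86400)
    stop("observations must span at least 2 days")
  if (all(diff(tsec) == 0)) stop("degenerate time axis: all fixes simultaneous")
  if (is.null(center))
    center <- c(mean(range(obs$lon)), mean(range(obs$lat)))
  xy <- project_azimuthal_equidistant(obs$lon, obs$lat, center)
  R <- ellipse_covariance(obs, class_sd)
  t0 <- tsec[1]
  tt <- tsec - t0
  dt1 <- max(tt[2] - tt[1], 60)
  a0 <- c(xy[1, 1], (xy[2, 1] - xy[1, 1]) / dt1,
          xy[1, 2], (xy[2, 2] - xy[1, 2]) / dt1)
  P0 <- c(1e8, 9, 1e8, 9)

  nll <- function(par) {
    beta <- exp(par[1]); s2 <- exp(par[2])
    psi <- if (length(par) > 2) exp(par[3]) else 1
    k <- .ctcrw_kalman_cpp(tt, xy, R, beta, s2, psi, a0, P0, FALSE)
    if (!isTRUE(k$ok)) return(1e10)
    -k$loglik
  }
  starts <- lapply(c(3600, 6 * 3600, 24 * 3600), function(tau) {
    beta <- 1 / tau
    c(log(beta), log(2 * beta * 1.0), if (estimate_psi) 0)
  })
  fits <- lapply(starts, function(p0)
    optim(p0, nll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (best$convergence != 0) {
    # simplex degeneracy on flat likelihood plateaus: restart once from
    # the incumbent and accept if no material improvement remains
    re <- optim(best$par, nll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
    impr <- best$value - re$value
    if (re$value <= best$value) best <- re
    if (best$convergence != 0 && impr > 1e-6 * (abs(re$value) + 1))
      stop("CTCRW optimisation did not converge (code ", best$convergence,
           "); trace: ", paste(signif(best$par, 4), collapse = ", "))
    best$convergence <- 0
  }
  H <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  se <- rep(NA_real_, length(best$par))
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  par <- best$par
  structure(list(
    beta = exp(par[1]), sigma2 = exp(par[2]),
    psi = if (estimate_psi) exp(par[3]) else 1,
    log_par = par, log_se = se,
    loglik = -best$value, convergence = best$convergence,
    n = nrow(obs), center = center, t0 = t0,
    data = list(tsec = tt, xy = xy, R = R, a0 = a0, P0 = P0,
                timestamp = obs$timestamp)),
    class = "crw_fit")
}

#' @export
print.crw_fit <- function(x, ...) {
  cat("Continuous-time correlated random walk fit\n")
  cat(sprintf("  n fixes: %d, log-likelihood: %.2f\n", x$n, x$loglik))
  cat(sprintf("  velocity autocorrelation time scale: %.2f h\n",
              1 / x$beta / 3600))
  cat(sprintf("  stationary speed scale (per axis):   %.2f m/s\n",
              sqrt(x$sigma2 / (2 * x$beta))))
  cat(sprintf("  observation variance inflation psi:  %.3f\n", x$psi))
  invisible(x)
}

#' @export
coef.crw_fit <- function(object, ...)
  c(beta = object$beta, sigma2 = object$sigma2, psi = object$psi)

#' @export
logLik.crw_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$log_par), class = "logLik")
}

#' @export
summary.crw_fit <- function(object, ...) {
  est <- object$log_par
  se <- object$log_se
  tab <- data.frame(
    estimate = exp(est),
    lower95 = exp(est - 1.96 * se),
    upper95 = exp(est + 1.96 * se),
    row.names = c("beta", "sigma2", if (length(est) > 2) "psi"))
  out <- list(coefficients = tab, loglik = object$loglik, n = object$n)
  class(out) <- "summary.crw_fit"
  out
}

#' @export
print.summary.crw_fit <- function(x, ...) {
  cat("CTCRW parameter estimates (Wald 95% intervals on the log scale):\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("log-likelihood %.2f on %d fixes\n", x$loglik, x$n))
  invisible(x)
}

#' Predict regular states along the fitted path
#'
#' Runs the Kalman smoother over the union of observation times and a
#' regular grid starting at the first fix, and returns the smoothed state
#' at each grid time: position (lon/lat and planar x/y), its standard
#' errors, and speed over ground computed as the geodesic displacement
#' between consecutive predicted positions divided by the interval (the
#' speed is attached to the step's starting row; the final row has `NA`).
#'
#' @param fit A converged [fit_crw()] object.
#' @param interval_hours Prediction interval in hours (> 0), default 6.
#' @return A `track_steps` data frame.
#' @export
predict_path <- function(fit, interval_hours = 6) {
  if (!inherits(fit, "crw_fit")) stop("fit must be a crw_fit")
  if (interval_hours <= 0) stop("interval must be > 0")
  dt <- interval_hours * 3600
  tt <- fit$data$tsec
  grid <- seq(0, max(tt), by = dt)
  allt <- sort(unique(c(round(tt), grid)))
  n <- length(allt)
  z <- matrix(NaN, n, 2)
  R <- matrix(0, n, 3)
  io <- match(round(tt), allt)
  # a fix and a grid node can share a (rounded) second; last fix wins, as
  # duplicates were already collapsed upstream
  z[io, ] <- fit$data$xy
  R[io, ] <- fit$data$R
  k <- .ctcrw_kalman_cpp(allt, z, R, fit$beta, fit$sigma2, fit$psi,
                         fit$data$a0, fit$data$P0, TRUE)
  if (!isTRUE(k$ok)) stop("Kalman smoother failed at the fitted parameters")
  ig <- match(grid, allt)
  sm <- k$smooth_mean[ig, , drop = FALSE]
  xse <- sqrt(pmax(k$smooth_cov[1, 1, ig], 0))
  yse <- sqrt(pmax(k$smooth_cov[3, 3, ig], 0))
  ll <- unproject_azimuthal_equidistant(sm[, 1], sm[, 3], fit$center)
  m <- length(grid)
  # posterior covariance of each 6-h displacement, via chained smoother
  # gains: Cov(a_i, a_j) = J_i ... J_{j-1} Psm_j
  dv <- matrix(NA_real_, m, 3,
               dimnames = list(NULL, c("dvar_xx", "dvar_yy", "dvar_xy")))
  pos <- c(1, 3)
  for (s in seq_len(m - 1)) {
    i <- ig[s]; j <- ig[s + 1]
    A <- diag(4)
    for (l in i:(j - 1)) A <- A %*% k$smooth_gain[, , l]
    Cross <- A %*% k$smooth_cov[, , j]
    S <- k$smooth_cov[, , i] + k$smooth_cov[, , j] - Cross - t(Cross)
    dv[s, ] <- c(max(S[1, 1], 0), max(S[3, 3], 0), S[1, 3])
  }
  d <- .geo_dist(ll[-m, 1], ll[-m, 2], ll[-1, 1], ll[-1, 2])
  out <- data.frame(
    timestamp = as.POSIXct(fit$t0 + grid, origin = "1970-01-01", tz = "UTC"),
    lon = ll[, 1], lat = ll[, 2],
    x = sm[, 1], y = sm[, 3], x_se = xse, y_se = yse,
    speed_ground = c(d / dt, NA_real_), dv)
  class(out) <- c("track_steps", "data.frame")
  out
}

#' @export
predict.crw_fit <- function(object, interval_hours = 6, ...)
  predict_path(object, interval_hours)
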