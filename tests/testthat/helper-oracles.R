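# Independent oracle implementations used to cross-check the package's
# algorithms. These are deliberately written as plain brute-force code,
# sharing no internals with the implementations they test.

# iterative speed-criterion filter: recompute every leg speed from scratch
# each pass, remove one offender per pass (worst quality class, then the
# latest fix), never touching class-Z handling beyond the initial drop
oracle_speed_filter <- function(obs, vmax = 9) {
  keep <- !(obs$quality_class %in% "Z")
  rank_of <- function(lc) match(lc, c("3", "2", "1", "0", "A", "B", "Z"))
  repeat {
    idx <- which(keep)
    if (length(idx) < 3) break
    p <- cbind(obs$lon[idx], obs$lat[idx])
    tt <- as.numeric(obs$timestamp[idx])
    sp <- geosphere::distGeo(p[-nrow(p), , drop = FALSE],
                             p[-1, , drop = FALSE]) /
      pmax(diff(tt), 1e-9)
    bad <- integer(0)
    for (i in 2:(length(idx) - 1))
      if (sp[i - 1] > vmax && sp[i] > vmax) bad <- c(bad, idx[i])
    if (!length(bad)) break
    r <- rank_of(obs$quality_class[bad])
    bad <- bad[r == max(r)]
    keep[max(bad)] <- FALSE
  }
  keep
}

# exhaustive minimum within-segment SSQ over all segmentations with K
# segments of length >= Lmin
oracle_exhaustive_contrast <- function(y, K, Lmin = 1) {
  n <- length(y)
  ssq <- function(v) sum((v - mean(v))^2)
  if (K == 1) return(ssq(y))
  best <- Inf
  cuts <- utils::combn(seq_len(n - 1), K - 1)
  for (c_i in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c_i], n)
    if (any(diff(b) < Lmin)) next
    tot <- 0
    for (s in seq_len(K)) tot <- tot + ssq(y[(b[s] + 1):b[s + 1]])
    if (tot < best) best <- tot
  }
  best
}

# plain-R Kalman filter + RTS smoother for the exact-discretised
# integrated OU velocity model, dense matrices throughout
oracle_kalman_r <- function(tt, z, R3, beta, s2, psi, a0, P0) {
  n <- length(tt)
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 3] <- 1
  mats <- function(dt) {
    phi <- exp(-beta * dt)
    ixv <- (1 - phi) / beta
    T <- diag(4); T[1, 2] <- ixv; T[2, 2] <- phi
    T[3, 4] <- ixv; T[4, 4] <- phi
    qvv <- s2 * (1 - phi^2) / (2 * beta)
    qxv <- s2 * (1 - phi)^2 / (2 * beta^2)
    qxx <- s2 * (dt - 2 * ixv + (1 - phi^2) / (2 * beta)) / beta^2
    Q <- matrix(0, 4, 4)
    Q[1:2, 1:2] <- matrix(c(qxx, qxv, qxv, qvv), 2)
    Q[3:4, 3:4] <- matrix(c(qxx, qxv, qxv, qvv), 2)
    list(T = T, Q = Q)
  }
  a <- a0; P <- diag(P0)
  ap <- af <- matrix(0, 4, n)
  Pp <- Pf <- array(0, c(4, 4, n))
  ll <- 0
  for (i in seq_len(n)) {
    if (i > 1) {
      m <- mats(tt[i] - tt[i - 1])
      a <- m$T %*% a
      P <- m$T %*% P %*% t(m$T) + m$Q
    }
    ap[, i] <- a; Pp[, , i] <- P
    if (is.finite(z[i, 1])) {
      R <- psi * matrix(c(R3[i, 1], R3[i, 3], R3[i, 3], R3[i, 2]), 2)
      v <- z[i, ] - as.numeric(H %*% a)
      F <- H %*% P %*% t(H) + R
      ll <- ll + mvn2_logdens(v, F)
      K <- P %*% t(H) %*% solve(F)
      a <- a + K %*% v
      P <- P - K %*% H %*% P
    }
    af[, i] <- a; Pf[, , i] <- P
  }
  as <- af; Ps <- Pf
  for (k in (n - 1):1) {
    m <- mats(tt[k + 1] - tt[k])
    J <- Pf[, , k] %*% t(m$T) %*% solve(Pp[, , k + 1])
    as[, k] <- af[, k] + J %*% (as[, k + 1] - ap[, k + 1])
    Ps[, , k] <- Pf[, , k] + J %*% (Ps[, , k + 1] - Pp[, , k + 1]) %*% t(J)
  }
  list(loglik = ll, smooth_mean = t(as), smooth_cov = Ps)
}

mvn2_logdens <- function(v, S) {
  -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * as.numeric(t(v) %*% solve(S) %*% v)
}

# pruned depth-first enumeration of all simple paths on the water-cell
# graph; returns the minimum total geodesic length
oracle_enumerate_shortest <- function(grid, min_depth, start, end,
                                      connectivity = 16) {
  adm <- !grid$land & !is.na(grid$depth) & grid$depth > min_depth
  nr <- length(grid$lats); nc <- length(grid$lons)
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  if (connectivity == 16)
    offs <- rbind(offs, c(1, 2), c(2, 1), c(-1, 2), c(-2, 1),
                  c(1, -2), c(2, -1), c(-1, -2), c(-2, -1))
  wdist <- function(a, b)
    geosphere::distGeo(c(grid$lons[a[2]], grid$lats[a[1]]),
                       c(grid$lons[b[2]], grid$lats[b[1]]))
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(cell, len) {
    if (len >= best) return()
    if (all(cell == end)) { best <<- len; return() }
    visited[cell[1], cell[2]] <<- TRUE
    for (k in seq_len(nrow(offs))) {
      nb <- cell + offs[k, ]
      if (nb[1] < 1 || nb[1] > nr || nb[2] < 1 || nb[2] > nc) next
      if (!adm[nb[1], nb[2]] || visited[nb[1], nb[2]]) next
      dfs(nb, len + wdist(cell, nb))
    }
    visited[cell[1], cell[2]] <<- FALSE
  }
  dfs(start, 0)
  best
}

# exact simulation of the integrated OU velocity process at given times
sim_ctcrw_exact <- function(tt, beta, sigma2) {
  n <- length(tt)
  x <- matrix(0, n, 2)
  v <- matrix(rnorm(2, 0, sqrt(sigma2 / (2 * beta))), 1, 2)
  for (i in 2:n) {
    dt <- tt[i] - tt[i - 1]
    phi <- exp(-beta * dt)
    qvv <- sigma2 * (1 - phi^2) / (2 * beta)
    qxv <- sigma2 * (1 - phi)^2 / (2 * beta^2)
    qxx <- sigma2 * (dt - 2 * (1 - phi) / beta +
                       (1 - phi^2) / (2 * beta)) / beta^2
    S <- matrix(c(qxx, qxv, qxv, qvv), 2)
    L <- t(chol(S + diag(1e-12, 2)))
    for (d in 1:2) {
      e <- L %*% rnorm(2)
      x[i, d] <- x[i - 1, d] + v[d] * (1 - phi) / beta + e[1]
      v[d] <- v[d] * phi + e[2]
    }
  }
  x
}

# Monte-Carlo E[|v|^3] for a bivariate normal velocity
oracle_mc_cubic <- function(mu, Sigma, n = 2e5) {
  L <- t(chol(Sigma + diag(1e-12, 2)))
  z <- matrix(rnorm(2 * n), 2)
  w <- L %*% z + mu
  mean(colSums(w^2)^1.5)
}
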