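#' Penalized-contrast change-point segmentation (Lavielle)
#'
#' Exact dynamic-programming segmentation of a numeric series under the
#' mean-change model: for each number of segments `K <= Kmax` the
#' breakpoints minimise the within-segment sum of squared deviations from
#' the segment means, subject to a minimum segment length `Lmin`. The
#' number of segments is then selected by the normalized-contrast
#' second-difference rule: with
#' `Jt(K) = (J(Kmax) - J(K)) / (J(Kmax) - J(1)) * (Kmax - 1) + 1`,
#' `D(K) = Jt(K-1) - 2 Jt(K) + Jt(K+1)`, the chosen `K` is the largest one
#' with `D(K) > S` (default threshold `S = 0.75`), or 1 when no `K`
#' qualifies or the series is (numerically) constant.
#'
#' An alternative selection rule (`select = "drop"`) chooses the largest
#' `K` whose incremental contrast decrease `J(K-1) - J(K)` is at least
#' `min_drop * J(1)`. The second-difference rule assumes a single elbow;
#' when the mean alternates (residence/transit/residence...), isolating an
#' interior segment requires a *pair* of breakpoints, the one-step drops
#' alternate small/large, and the second difference oscillates around
#' zero, so the threshold rule systematically under-segments; the drop
#' rule is robust to that pairing.
#'
#' @param series Numeric vector without missing values.
#' @param Kmax Maximum number of segments considered.
#' @param Lmin Minimum segment length (observations), default 8.
#' @param S Selection threshold for the second-difference rule, default
#'   0.75.
#' @param select `"threshold"` (normalized-contrast second difference,
#'   default) or `"drop"` (relative incremental decrease).
#' @param min_drop Minimum relative contrast decrease for
#'   `select = "drop"`, default 0.02; floored at `2 log(n) / n` to
#'   discount chance-level decreases on unstructured series.
#' @return Object of class `lavielle_seg` with elements `K` (chosen),
#'   `breakpoints` (last index of each segment but the final one, for the
#'   chosen `K`), `segment_means`, `contrast` (vector `J(1..Kmax)`),
#'   `all_breakpoints` (list over `K`), `Kmax`, `Lmin`, `S`.
#' @export
lavielle_segment <- function(series, Kmax = 10, Lmin = 8, S = 0.75,
                             select = c("threshold", "drop"),
                             min_drop = 0.02) {
  select <- match.arg(select)
  y <- as.numeric(series)
  n <- length(y)
  if (anyNA(y)) stop("series must not contain missing values")
  if (n < 2 * Lmin) stop("series shorter than 2*Lmin")
  if (Lmin * Kmax > n) stop("Lmin * Kmax exceeds series length")
  c1 <- c(0, cumsum(y)); c2 <- c(0, cumsum(y^2))
  segcost <- function(i, j)   # ssq of y[i..j], i,j vectors
    (c2[j + 1] - c2[i]) - (c1[j + 1] - c1[i])^2 / (j - i + 1)
  V <- matrix(Inf, Kmax, n)     # V[k, j]: best contrast for y[1..j], k segs
  B <- matrix(NA_integer_, Kmax, n)
  j1 <- Lmin:n
  V[1, j1] <- segcost(rep(1L, length(j1)), j1)
  if (Kmax > 1) {
    for (k in 2:Kmax) {
      jmin <- k * Lmin
      if (jmin > n) break
      for (j in jmin:n) {
        t <- ((k - 1) * Lmin):(j - Lmin)     # end of previous segment
        cand <- V[k - 1, t] + segcost(t + 1L, rep(j, length(t)))
        b <- which.min(cand)                 # first (earliest) optimum
        V[k, j] <- cand[b]
        B[k, j] <- t[b]
      }
    }
  }
  J <- V[, n]
  all_bp <- lapply(seq_len(Kmax), function(k) {
    if (!is.finite(J[k])) return(NULL)
    bp <- integer(0); j <- n
    if (k >= 2) for (kk in k:2) { j <- B[kk, j]; bp <- c(j, bp) }
    bp
  })
  feas <- which(is.finite(J))
  Kf <- max(feas)
  K <- 1L
  degenerate <- (J[1] - J[Kf]) <= max(1e-12, 1e-10 * J[1])
  if (!degenerate && select == "threshold" && Kf >= 3) {
    Jt <- (J[Kf] - J[seq_len(Kf)]) / (J[Kf] - J[1]) * (Kf - 1) + 1
    Dk <- rep(-Inf, Kf)
    for (k in 2:(Kf - 1)) Dk[k] <- Jt[k - 1] - 2 * Jt[k] + Jt[k + 1]
    ok <- which(Dk > S)
    if (length(ok)) K <- max(ok)
  } else if (!degenerate && select == "drop" && Kf >= 2) {
    # guard against chance-level drops on unstructured series: a spurious
    # split of pure noise reduces the contrast by O(log n / n) of the
    # total, so the threshold never falls below twice that
    thr <- max(min_drop, 2 * log(n) / n)
    drops <- -diff(J[seq_len(Kf)]) / J[1]
    ok <- which(drops >= thr)
    if (length(ok)) K <- max(ok) + 1L
  }
  bp <- all_bp[[K]]
  bounds <- c(0, bp, n)
  means <- vapply(seq_len(K), function(s)
    mean(y[(bounds[s] + 1):bounds[s + 1]]), numeric(1))
  structure(list(K = K, breakpoints = bp, segment_means = means,
                 contrast = J, all_breakpoints = all_bp,
                 n = n, Kmax = Kmax, Lmin = Lmin, S = S, series = y),
            class = "lavielle_seg")
}

#' @export
print.lavielle_seg <- function(x, ...) {
  cat(sprintf("Lavielle segmentation: n = %d, chose K = %d (Kmax %d, Lmin %d)\n",
              x$n, x$K, x$Kmax, x$Lmin))
  if (length(x$breakpoints))
    cat("  breakpoints after indices:",
        paste(x$breakpoints, collapse = ", "), "\n")
  cat("  segment means:", paste(signif(x$segment_means, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.lavielle_seg <- function(x, ...) {
  plot(x$series, type = "l", xlab = "index", ylab = "series", ...)
  abline(v = x$breakpoints + 0.5, lty = 2, col = "red")
  bounds <- c(0, x$breakpoints, x$n)
  for (s in seq_len(x$K))
    segments(bounds[s] + 1, x$segment_means[s], bounds[s + 1],
             x$segment_means[s], col = "blue", lwd = 2)
  invisible(x)
}

#' Detect migration phases from movement persistence
#'
#' Segments the per-step persistence series and labels each segment
#' `transit` when its mean persistence exceeds the track-median
#' persistence, `residence` otherwise.
#'
#' Persistence estimated from a state-space smoothed path anticipates
#' departures (and prolongs arrivals) by up to a few days: near a regime
#' switch the smoother already curves towards the upcoming transit while
#' speeds are still low, so the persistence ramp starts inside the
#' residence period. With `refine_with_speed = TRUE` (default) each
#' breakpoint is therefore re-dated by the best single mean-change split
#' of the step-speed series within `refine_window` steps of the
#' persistence breakpoint — speed switches sharply at true departures and
#' arrivals. Refinement keeps the original breakpoint when the local
#' speed split is degenerate, and never reorders breakpoints.
#'
#' Phase detection defaults to the `"drop"` selection rule of
#' [lavielle_segment()] because alternating residence/transit structures
#' defeat the second-difference rule (see there).
#'
#' @param track A `track_steps` data frame with a `gamma` column (and
#'   `speed_ground` if refinement is on). Finding fewer than 2 segments
#'   raises a warning (not an error).
#' @param Kmax,Lmin,S,select,min_drop Passed to [lavielle_segment()].
#' @param refine_with_speed Re-date breakpoints on the speed series
#'   (default TRUE).
#' @param refine_window Half-width (steps) of the refinement window,
#'   default 24 (6 days at 6 h; covers smoothing-induced anticipation).
#' @return List with `segmentation` (the `lavielle_seg`), `phases` (a
#'   data frame with one row per segment: indices, start/end timestamps,
#'   mean persistence and label), and `breakpoints` (refined).
#' @export
detect_migration_phases <- function(track, Kmax = 10, Lmin = 8, S = 0.75,
                                    select = "drop", min_drop = 0.02,
                                    refine_with_speed = TRUE,
                                    refine_window = 24) {
  if (is.null(track$gamma) || anyNA(track$gamma))
    stop("track must carry a complete gamma column")
  seg <- lavielle_segment(track$gamma, Kmax = Kmax, Lmin = Lmin, S = S,
                          select = select, min_drop = min_drop)
  if (seg$K < 2)
    warning("fewer than 2 persistence segments found on a migratory track")
  bp <- seg$breakpoints
  if (refine_with_speed && length(bp) && !is.null(track$speed_ground)) {
    sp <- track$speed_ground
    sp[is.na(sp)] <- median(sp, na.rm = TRUE)
    lower <- c(1, head(bp, -1) + 1)
    upper <- c(bp[-1] - 1, seg$n - 1)
    for (i in seq_along(bp)) {
      w1 <- max(bp[i] - refine_window, lower[i], 2)
      w2 <- min(bp[i] + refine_window, upper[i], seg$n - 1)
      if (w2 - w1 < 3) next
      y <- sp[w1:w2]
      nw <- length(y)
      css <- function(v) sum(v^2) - sum(v)^2 / length(v)
      tot <- css(y)
      if (tot <= 1e-12) next
      cost <- vapply(seq_len(nw - 1), function(b)
        css(y[seq_len(b)]) + css(y[(b + 1):nw]), numeric(1))
      if ((tot - min(cost)) / tot < 0.1) next    # no local speed change
      bp[i] <- w1 - 1 + which.min(cost)
    }
    bp <- sort(bp)
    seg$breakpoints <- bp
    bounds0 <- c(0, bp, seg$n)
    seg$segment_means <- vapply(seq_len(seg$K), function(s)
      mean(seg$series[(bounds0[s] + 1):bounds0[s + 1]]), numeric(1))
  }
  bounds <- c(0, seg$breakpoints, seg$n)
  med <- median(track$gamma)
  phases <- do.call(rbind, lapply(seq_len(seg$K), function(s) {
    i1 <- bounds[s] + 1; i2 <- bounds[s + 1]
    data.frame(segment = s, start_index = i1, end_index = i2,
               start = track$timestamp[i1], end = track$timestamp[i2],
               mean_gamma = seg$segment_means[s],
               label = if (seg$segment_means[s] > med) "transit"
                       else "residence")
  }))
  list(segmentation = seg, phases = phases, breakpoints = seg$breakpoints)
}

#' Detect the calving change-point on a southbound speed series
#'
#' Two-segment (single change-point) penalized-contrast segmentation of
#' the swim-speed series of the southbound migration leg, reflecting a
#' sustained drop in speed once the female travels with a neonate calf.
#' Uses current-corrected speed through water when present, otherwise
#' speed over ground (flagged in the output). A change is declared only
#' when the single best split reduces the contrast by more than
#' `min_improvement` relative to the unsegmented fit.
#'
#' @param track A `track_steps` data frame restricted (by the caller) to
#'   the southbound leg, with `speed_water` and/or `speed_ground`.
#' @param Lmin Minimum segment length (steps), default 8.
#' @param min_improvement Minimum relative contrast reduction, default 0.05.
#' @return List: `change_detected`, `breakpoint_index`, `breakpoint_time`
#'   (last step of the pre-calving segment), `median_pre`, `median_post`
#'   (m/s), `speed_source` (`"water"` or `"ground"`).
#' @export
detect_calving <- function(track, Lmin = 8, min_improvement = 0.05) {
  src <- if (!is.null(track$speed_water) && !anyNA(track$speed_water))
    "water" else "ground"
  sp <- if (src == "water") track$speed_water else track$speed_ground
  keep <- !is.na(sp)
  sp <- sp[keep]
  ts <- track$timestamp[keep]
  no_change <- list(change_detected = FALSE, breakpoint_index = NA_integer_,
                    breakpoint_time = as.POSIXct(NA, tz = "UTC"),
                    median_pre = NA_real_, median_post = NA_real_,
                    speed_source = src)
  if (length(sp) < 2 * Lmin) return(no_change)
  seg <- lavielle_segment(sp, Kmax = 2, Lmin = Lmin)
  J1 <- seg$contrast[1]; J2 <- seg$contrast[2]
  if (!is.finite(J2) || J1 <= 1e-12 || (J1 - J2) / J1 < min_improvement)
    return(no_change)
  bp <- seg$all_breakpoints[[2]][1]
  list(change_detected = TRUE, breakpoint_index = bp,
       breakpoint_time = ts[bp],
       median_pre = median(sp[seq_len(bp)]),
       median_post = median(sp[(bp + 1):length(sp)]),
       speed_source = src)
}
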