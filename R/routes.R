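#' Ellipsoidal geodesic distance
#'
#' WGS84 geodesic distance between points; vectorised.
#'
#' @param p1,p2 Two-column matrices (or length-2 vectors) of lon/lat in
#'   degrees.
#' @return Distance(s) in meters.
#' @export
geodesic_distance <- function(p1, p2) {
  geosphere::distGeo(rbind(p1)[, 1:2, drop = FALSE],
                     rbind(p2)[, 1:2, drop = FALSE])
}

# admissible water cells and their igraph representation
.water_graph <- function(grid, min_depth, connectivity = 16) {
  adm <- !grid$land & !is.na(grid$depth) & grid$depth > min_depth
  nr <- length(grid$lats); nc <- length(grid$lons)
  id <- matrix(NA_integer_, nr, nc)
  id[adm] <- seq_len(sum(adm))
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  if (connectivity == 16)
    offs <- rbind(offs, c(1, 2), c(2, 1), c(-1, 2), c(-2, 1))
  else if (connectivity != 8)
    stop("connectivity must be 8 or 16")
  from <- to <- integer(0); w <- numeric(0)
  ij <- which(adm, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    i2 <- ij[, 1] + offs[k, 1]; j2 <- ij[, 2] + offs[k, 2]
    ok <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
    ok[ok] <- adm[cbind(i2[ok], j2[ok])]
    if (!any(ok)) next
    a <- ij[ok, , drop = FALSE]; b <- cbind(i2[ok], j2[ok])
    from <- c(from, id[a]); to <- c(to, id[b])
    w <- c(w, geosphere::distGeo(cbind(grid$lons[a[, 2]], grid$lats[a[, 1]]),
                                 cbind(grid$lons[b[, 2]], grid$lats[b[, 1]])))
  }
  g <- igraph::make_graph(edges = as.vector(rbind(from, to)),
                          n = sum(adm), directed = FALSE)
  igraph::E(g)$weight <- w
  list(graph = g, id = id, adm = adm)
}

.snap_cell <- function(grid, adm, lon, lat, max_cells = 5) {
  i0 <- which.min(abs(grid$lats - lat)); j0 <- which.min(abs(grid$lons - lon))
  best <- NULL
  for (r in 0:max_cells) {
    ii <- max(1, i0 - r):min(length(grid$lats), i0 + r)
    jj <- max(1, j0 - r):min(length(grid$lons), j0 + r)
    cand <- expand.grid(i = ii, j = jj)
    cand <- cand[pmax(abs(cand$i - i0), abs(cand$j - j0)) == r, , drop = FALSE]
    cand <- cand[adm[cbind(cand$i, cand$j)], , drop = FALSE]
    if (nrow(cand)) {
      d <- geosphere::distGeo(cbind(lon, lat),
                              cbind(grid$lons[cand$j], grid$lats[cand$i]))
      k <- which.min(d)
      best <- list(i = cand$i[k], j = cand$j[k], snap_m = d[k])
      break
    }
  }
  if (is.null(best))
    stop(sprintf("no admissible water cell within %d cells of (%.3f, %.3f)",
                 max_cells, lon, lat))
  best
}

#' Least-cost path through water
#'
#' Exact shortest path (Dijkstra) on the graph of admissible water cells
#' (depth strictly greater than `min_depth`), with 16-connected
#' neighbourhoods by default (8-connected available) and WGS84 geodesic
#' edge lengths between cell centers. Start and end positions are snapped
#' to the nearest admissible cell within `snap_cells` cells; the snap
#' distances are reported.
#'
#' @param start,end `c(lon, lat)` endpoints (degrees).
#' @param grid A [depth_grid].
#' @param min_depth Minimum water depth (m), default 10.
#' @param connectivity 16 (default) or 8.
#' @param snap_cells Snapping tolerance in cells, default 5.
#' @return Object of class `route_path`: `vertices` (lon/lat matrix of
#'   cell centers traversed), `length_km`, `cells` (index matrix),
#'   `snap_start_m`, `snap_end_m`.
#' @export
least_cost_path <- function(start, end, grid, min_depth = 10,
                            connectivity = 16, snap_cells = 5) {
  wg <- .water_graph(grid, min_depth, connectivity)
  a <- .snap_cell(grid, wg$adm, start[1], start[2], snap_cells)
  b <- .snap_cell(grid, wg$adm, end[1], end[2], snap_cells)
  va <- wg$id[a$i, a$j]; vb <- wg$id[b$i, b$j]
  if (va == vb) {
    verts <- cbind(lon = grid$lons[a$j], lat = grid$lats[a$i])
    return(structure(list(vertices = verts, length_km = 0,
                          cells = cbind(i = a$i, j = b$j),
                          snap_start_m = a$snap_m, snap_end_m = b$snap_m),
                     class = "route_path"))
  }
  sp <- igraph::shortest_paths(wg$graph, from = va, to = vb,
                               weights = igraph::E(wg$graph)$weight,
                               output = "vpath", algorithm = "dijkstra")
  vp <- as.integer(sp$vpath[[1]])
  if (!length(vp)) stop("unreachable: endpoints not connected through water")
  cells_all <- which(wg$adm, arr.ind = TRUE)   # row k is vertex id k
  cells <- cells_all[vp, , drop = FALSE]
  colnames(cells) <- c("i", "j")
  verts <- cbind(lon = grid$lons[cells[, "j"]], lat = grid$lats[cells[, "i"]])
  legs <- geosphere::distGeo(verts[-nrow(verts), , drop = FALSE],
                             verts[-1, , drop = FALSE])
  structure(list(vertices = verts, length_km = sum(legs) / 1000,
                 cells = cells, snap_start_m = a$snap_m,
                 snap_end_m = b$snap_m),
            class = "route_path")
}

#' @export
print.route_path <- function(x, ...) {
  cat(sprintf("Least-cost water path: %d vertices, %.1f km (snap %d m / %d m)\n",
              nrow(x$vertices), x$length_km, round(x$snap_start_m),
              round(x$snap_end_m)))
  invisible(x)
}

#' Compare observed track length to least-cost routes
#'
#' @param observed A `track_steps` data frame (uses cumulative geodesic
#'   length between consecutive rows).
#' @param direct A [route_path] for the direct feeding-breeding route.
#' @param via_stopovers Optional [route_path] via observed stopovers.
#' @return List: `observed_km`, `direct_km`, `via_km`,
#'   `via_increase_pct` (via over direct), `excess_over_direct_pct`,
#'   `excess_over_via_pct` (observed over each route).
#' @export
route_comparison <- function(observed, direct, via_stopovers = NULL) {
  stopifnot(nrow(observed) >= 2)
  p <- cbind(observed$lon, observed$lat)
  obs_km <- sum(geosphere::distGeo(p[-nrow(p), , drop = FALSE],
                                   p[-1, , drop = FALSE])) / 1000
  via_km <- if (is.null(via_stopovers)) NA_real_ else via_stopovers$length_km
  list(observed_km = obs_km, direct_km = direct$length_km, via_km = via_km,
       via_increase_pct = if (is.na(via_km)) NA_real_ else
         100 * (via_km / direct$length_km - 1),
       excess_over_direct_pct = 100 * (obs_km / direct$length_km - 1),
       excess_over_via_pct = if (is.na(via_km)) NA_real_ else
         100 * (obs_km / via_km - 1))
}
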