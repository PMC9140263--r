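flat_grid <- function(n = 8, lat0 = 50, lon0 = 0, res = 0.1,
                      depth = 3000) {
  depth_grid(lats = lat0 + (0:(n - 1)) * res,
             lons = lon0 + (0:(n - 1)) * res,
             depth = matrix(depth, n, n))
}

test_that("geodesic distance has the expected values and symmetry", {
  expect_equal(geodesic_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(geodesic_distance(c(0, 0), c(1, 0)) / 1000, 111.32,
               tolerance = 1e-4)
  set.seed(2)
  for (i in 1:10) {
    a <- c(runif(1, -170, 170), runif(1, -80, 80))
    b <- c(runif(1, -170, 170), runif(1, -80, 80))
    expect_equal(geodesic_distance(a, b), geodesic_distance(b, a))
  }
})

test_that("open-water least-cost path is nearly straight", {
  g <- flat_grid(10)
  a <- c(0.05, 50.05); b <- c(0.85, 50.85)
  p <- least_cost_path(a, b, g)
  straight <- geodesic_distance(p$vertices[1, ],
                                p$vertices[nrow(p$vertices), ]) / 1000
  expect_lt(p$length_km, straight * 1.03)
  expect_gte(p$length_km, straight - 1e-9)
  # start = end: zero-length path
  p0 <- least_cost_path(a, a, g)
  expect_equal(p0$length_km, 0)
})

test_that("path goes through the only gap in a wall and matches the
           enumeration oracle", {
  g <- flat_grid(6)
  g$depth[, 3] <- 0                        # north-south wall at lon index 3
  g$depth[4, 3] <- 3000                    # one gap
  g <- depth_grid(g$lats, g$lons, g$depth)
  a <- c(g$lons[1], g$lats[1]); b <- c(g$lons[6], g$lats[6])
  p <- least_cost_path(a, b, g)
  expect_true(any(p$cells[, "j"] == 3 & p$cells[, "i"] == 4))
  want <- oracle_enumerate_shortest(g, 10, c(1, 1), c(6, 6))
  expect_equal(p$length_km * 1000, want, tolerance = 1e-9)
})

test_that("Dijkstra equals path enumeration on random 6x6 grids", {
  set.seed(33)
  for (rep in 1:6) {
    g <- flat_grid(6)
    mask <- matrix(runif(36) < 0.25, 6, 6)
    mask[1, 1] <- FALSE; mask[6, 6] <- FALSE
    d <- g$depth; d[mask] <- 0
    g <- depth_grid(g$lats, g$lons, d)
    a <- c(g$lons[1], g$lats[1]); b <- c(g$lons[6], g$lats[6])
    want <- oracle_enumerate_shortest(g, 10, c(1, 1), c(6, 6))
    if (!is.finite(want)) {
      expect_error(least_cost_path(a, b, g, snap_cells = 0), "unreachable")
    } else {
      p <- least_cost_path(a, b, g, snap_cells = 0)
      expect_equal(p$length_km * 1000, want, tolerance = 1e-9)
    }
  }
})

test_that("raising the depth threshold never shortens the path", {
  set.seed(44)
  g <- flat_grid(8)
  d <- g$depth
  d[sample(64, 20)] <- runif(20, 5, 100)   # scatter shallow cells
  d[1, 1] <- 3000; d[8, 8] <- 3000
  g <- depth_grid(g$lats, g$lons, d)
  a <- c(g$lons[1], g$lats[1]); b <- c(g$lons[8], g$lats[8])
  lens <- c()
  for (md in c(10, 50, 90)) {
    p <- tryCatch(least_cost_path(a, b, g, min_depth = md, snap_cells = 0),
                  error = function(e) NULL)
    lens <- c(lens, if (is.null(p)) Inf else p$length_km)
  }
  expect_true(all(diff(lens) >= -1e-9))
})

test_that("triangle inequality holds on the water graph", {
  g <- flat_grid(6)
  set.seed(5)
  cells <- cbind(sample(6, 9, TRUE), sample(6, 9, TRUE))
  for (k in seq_len(3)) {
    a <- c(g$lons[cells[3 * k - 2, 2]], g$lats[cells[3 * k - 2, 1]])
    b <- c(g$lons[cells[3 * k - 1, 2]], g$lats[cells[3 * k - 1, 1]])
    cc <- c(g$lons[cells[3 * k, 2]], g$lats[cells[3 * k, 1]])
    dab <- least_cost_path(a, b, g)$length_km
    dac <- least_cost_path(a, cc, g)$length_km
    dcb <- least_cost_path(cc, b, g)$length_km
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("8-neighbour connectivity is available and never shorter", {
  g <- flat_grid(7)
  a <- c(g$lons[1], g$lats[2]); b <- c(g$lons[7], g$lats[6])
  p16 <- least_cost_path(a, b, g, connectivity = 16)
  p8 <- least_cost_path(a, b, g, connectivity = 8)
  expect_gte(p8$length_km, p16$length_km - 1e-9)
})

test_that("route comparison reports excess percentages", {
  g <- flat_grid(10)
  a <- c(0.05, 50.05); b <- c(0.85, 50.85)
  direct <- least_cost_path(a, b, g)
  cmp0 <- route_comparison(
    structure(data.frame(lon = direct$vertices[, 1],
                         lat = direct$vertices[, 2]),
              class = c("track_steps", "data.frame")),
    direct, direct)
  expect_equal(cmp0$via_increase_pct, 0)
  expect_equal(cmp0$excess_over_via_pct, 0, tolerance = 1e-9)

  # a via-route exactly 1.1x the direct route -> +10.0%
  via <- direct
  via$length_km <- direct$length_km * 1.1
  cmp1 <- route_comparison(
    structure(data.frame(lon = c(0.05, 0.85), lat = c(50.05, 50.85)),
              class = c("track_steps", "data.frame")), direct, via)
  expect_equal(cmp1$via_increase_pct, 10, tolerance = 1e-9)
})
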