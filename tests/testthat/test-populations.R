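# Buffer-dissolve delineation, zonal statistics, labelling.

prj <- albers_projection(lon0 = -83, lat0 = 31, lat1 = 29, lat2 = 33)

# records at given projected offsets (km) from a common origin
records_at <- function(dx, dy) {
  ll <- offset_ll(prj, -83, 31, dx, dy)
  make_records(ll[, 1], ll[, 2])
}

test_that("two points merge iff their buffers overlap", {
  near <- records_at(c(0, 4.9), c(0, 0))
  far <- records_at(c(0, 5.1), c(0, 0))
  expect_equal(nrow(delineate_populations(near, 2.5, prj)), 1)
  expect_equal(nrow(delineate_populations(far, 2.5, prj)), 2)
})

test_that("an isolated buffer has the analytic disc area and centroid", {
  pops <- delineate_populations(records_at(0, 0), 2.5, prj)
  expect_equal(pops$area_km2, pi * 2.5^2, tolerance = 0.01)
  xy <- prj$project(-83, 31)
  expect_equal(pops$centroid_x, xy[1], tolerance = 0.05)
  expect_equal(pops$centroid_y, xy[2], tolerance = 0.05)
})

test_that("component counts match a graph oracle on random points", {
  skip_if_not_installed("igraph")
  set.seed(20)
  n <- 80
  dx <- runif(n, 0, 60)
  dy <- runif(n, 0, 60)
  recs <- records_at(dx, dy)
  for (r in c(1, 2.5, 5)) {
    pops <- delineate_populations(recs, r, prj)
    d <- as.matrix(dist(cbind(dx, dy)))
    g <- igraph::graph_from_adjacency_matrix(d < 2 * r, mode = "undirected",
                                             diag = FALSE)
    expect_equal(nrow(pops), igraph::components(g)$no)
    # every record lands in exactly one population
    expect_equal(length(attr(pops, "membership")), n)
    expect_false(anyNA(attr(pops, "membership")))
  }
})

test_that("population count is monotone in buffer size and area subadditive", {
  set.seed(21)
  recs <- records_at(runif(40, 0, 40), runif(40, 0, 40))
  counts <- vapply(c(0.5, 1, 2.5, 5),
                   function(r) nrow(delineate_populations(recs, r, prj)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  for (r in c(1, 2.5)) {
    pops <- delineate_populations(recs, r, prj)
    expect_lte(sum(pops$area_km2), 40 * pi * r^2 * 1.01)
    expect_true(all(pops$area_km2 >= pi * r^2 * 0.99))
  }
})

test_that("empty input gives an empty set with a warning", {
  expect_warning(pops <- delineate_populations(records_at(0, 0)[0, ], 2.5, prj),
                 "no records")
  expect_equal(nrow(pops), 0)
})

test_that("ecoregion assignment covers containment, nearest and ties", {
  pops <- delineate_populations(records_at(c(0, 30), c(0, 0)), 2.5, prj)
  ring_a <- square_ring(prj, -83, 31, 10)             # contains pop 1
  far_b <- offset_ll(prj, -83, 31, 30, 15)
  ring_b <- square_ring(prj, far_b[1], far_b[2], 10)  # nearest to pop 2
  eco <- assign_ecoregion(pops, poly_set(c("A", "B"), list(ring_a, ring_b)))
  expect_equal(eco$ecoregion, c("A", "B"))
  expect_equal(eco$ecoregion_flag, c(FALSE, TRUE))    # pop 2 flagged nearest
  # overlapping polygons: first in layer order wins, flagged
  eco2 <- assign_ecoregion(pops, poly_set(c("X", "Y"), list(ring_a, ring_a)))
  expect_equal(eco2$ecoregion[1], "X")
  expect_true(eco2$ecoregion_flag[1])
  expect_error(assign_ecoregion(pops, poly_set(character(0), list())),
               "empty")
})

test_that("protected-area assignment maps designations with priority", {
  pops <- delineate_populations(records_at(c(0, 30), c(0, 0)), 2.5, prj)
  nf <- square_ring(prj, -83, 31, 8)
  wma <- square_ring(prj, -83, 31, 6)                 # overlaps nf
  polys <- poly_set(c("Apalachicola NF", "Local WMA"), list(nf, wma))
  cmap <- c("Apalachicola NF" = "national forest",
            "Local WMA" = "wildlife management area")
  got <- assign_protected(pops, polys, cmap,
                          priority = c("national forest",
                                       "wildlife management area"))
  expect_equal(got$protected, c("national forest", "none"))
  expect_true(got$protected_flag[1])                  # overlapping designations
  expect_warning(
    got2 <- assign_protected(pops, poly_set("Mystery Tract", list(nf)),
                             cmap),
    "unmapped")
  expect_equal(got2$protected, c("other", "none"))
})

test_that("zonal means handle constant rasters and split cells", {
  pops <- delineate_populations(records_at(0, 0), 2.5, prj)
  origin <- prj$project(-83, 31)
  const <- grid_raster(matrix(0.7, 60, 60), origin[1] - 15, origin[2] - 15, 0.5)
  expect_equal(zonal_mean(pops, const)$value, 0.7)
  # centre on a column boundary of a raster whose west half is 0.2 and
  # east half is 0.4: symmetric cell sets average to 0.3
  m <- matrix(rep(c(0.2, 0.4), each = 30), 60, 60, byrow = TRUE)
  split <- grid_raster(m, origin[1] - 15, origin[2] - 15, 0.5)
  expect_equal(zonal_mean(pops, split)$value, 0.3, tolerance = 1e-12)
})

test_that("zonal means equal exhaustive per-cell enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(1:4, 1)
    dx <- runif(k, 0, 12)
    dy <- runif(k, 0, 12)
    recs <- records_at(dx, dy)
    r <- runif(1, 1.5, 3)
    pops <- delineate_populations(recs, r, prj)
    origin <- prj$project(-83, 31)
    cs <- runif(1, 0.3, 0.9)
    nx <- ceiling(20 / cs)
    rast <- grid_raster(matrix(runif(nx * nx), nx, nx),
                        origin[1] - 4, origin[2] - 4, cs)
    got <- zonal_mean(pops, rast)
    # oracle: enumerate every cell centre, point-in-disc-union test
    xs <- rast$xll + (seq_len(ncol(rast$values)) - 0.5) * cs
    ys <- rast$yll + (nrow(rast$values) - seq_len(nrow(rast$values)) + 0.5) * cs
    members <- attr(pops, "members")
    for (i in seq_len(nrow(pops))) {
      vals <- c()
      for (row in seq_along(ys)) for (col in seq_along(xs)) {
        d2 <- (members[[i]][, 1] - xs[col])^2 + (members[[i]][, 2] - ys[row])^2
        if (any(d2 <= r^2)) vals <- c(vals, rast$values[row, col])
      }
      if (length(vals)) {
        expect_equal(got$value[i], mean(vals), tolerance = 1e-12)
        expect_equal(got$n_cells[i], length(vals))
      } else {
        expect_true(got$flag_no_cells[i])
      }
    }
  }
})

test_that("tiny polygons fall back to the nearest cell, flagged", {
  pops <- delineate_populations(records_at(0, 0), 2.5, prj)
  origin <- prj$project(-83, 31)
  # 20-km cells: no cell centre inside a 2.5-km disc off-centre
  rast <- grid_raster(matrix(1:4, 2, 2), origin[1] + 4, origin[2] + 4, 20)
  got <- zonal_mean(pops, rast)
  expect_true(got$flag_no_cells)
  expect_true(got$value %in% 1:4)
})

test_that("covariate correlations recover exact and degenerate structure", {
  pops <- delineate_populations(records_at(runif(6, 0, 60), runif(6, 0, 60)),
                                1, prj)
  pops$h <- c(0.1, 0.3, 0.5, 0.6, 0.8, 0.9)
  pops$v <- 1 - pops$h
  pops$w <- c(0.2, 0.9, 0.1, 0.7, 0.4, 0.5)
  cors <- covariate_correlations(pops)
  expect_equal(cors$r[cors$var1 == "h" & cors$var2 == "v"], -1)
  # direct Pearson formula oracle on the toy table
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(cors$r[cors$var1 == "h" & cors$var2 == "w"],
               pearson(pops$h, pops$w), tolerance = 1e-12)
  pops$w <- 0.5
  cors2 <- covariate_correlations(pops)
  expect_true(all(cors2$degenerate[cors2$var1 == "w" | cors2$var2 == "w"]))
  expect_error(covariate_correlations(pops[1:2, ]), "at least 3")
})

test_that("covariates lie in the unit interval after scaling", {
  set.seed(5)
  land <- simulate_landscape(seed = 5, extent_km = c(60, 60))
  recs <- simulate_records(sim_truth(n_pops = 8), land, seed = 6)
  pops <- delineate_populations(
    clean_target_records(recs$target, land$range,
                         projection = land$projection),
    2.5, land$projection)
  pops <- population_covariates(
    pops, land$suitability,
    winter_precip_raster(land$precip_monthly, land$precip_years),
    land$impervious)
  expect_true(all(pops$h >= 0 & pops$h <= 1))
  expect_true(all(pops$w >= 0 & pops$w <= 1))
  expect_true(all(pops$v >= 0 & pops$v <= 1))
})
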