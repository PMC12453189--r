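# Record ingestion and the cleaning rules for target and effort streams.

prj <- albers_projection(lon0 = -83, lat0 = 31, lat1 = 29, lat2 = 33)

test_that("read_records parses well-formed files and reports bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,event_date,lon,lat",
               "target,2001-02-03,-83.1,31.2",
               "target,2002-03-04,-83.2,31.3",
               "target,2003-04-05,-83.3,31.4"), f)
  recs <- read_records(f)
  expect_equal(nrow(recs), 3)
  expect_s3_class(recs$event_date, "Date")
  expect_equal(nrow(attr(recs, "problems")), 0)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,event_date,lon,lat",
               "target,2001-02-03,-83.1,95",
               "target,2001-02-04,-83.1,31.2"), f2)
  recs2 <- read_records(f2)
  expect_equal(nrow(recs2), 1)
  probs <- attr(recs2, "problems")
  expect_equal(probs$row, 1)
  expect_match(probs$reason, "latitude")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,event_date,lon,lat", f3)
  expect_equal(nrow(read_records(f3)), 0)
})

test_that("read_records applies column maps and errors on missing columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sci_name,obs_date,x,y",
               "target,2001-02-03,-83.1,31.2"), f)
  recs <- read_records(f, column_map = c(species = "sci_name",
                                         event_date = "obs_date",
                                         lon = "x", lat = "y"))
  expect_equal(recs$species, "target")
  expect_error(read_records(f, column_map = c(species = "nope")),
               "not present")
  expect_error(read_records(f), "absent after mapping")
})

test_that("row validation catches dates and uncertainties", {
  df <- tibble::tibble(
    species = "t", event_date = c("2001-01-01", "not-a-date", "2999-01-01"),
    lon = -83, lat = 31, coord_uncertainty_m = c(10, 10, -5))
  recs <- as_occ_records(df)
  expect_equal(nrow(recs), 1)
  expect_setequal(attr(recs, "problems")$reason,
                  c("unparseable date", "date in the future"))
})

test_that("range filter keeps points within the boundary tolerance", {
  ring <- square_ring(prj, -83, 31, 20)    # 40 x 40 km square
  inside <- make_records(-83, 31)
  out9 <- make_records(offset_ll(prj, -83, 31, 29, 0)[, 1],
                       offset_ll(prj, -83, 31, 29, 0)[, 2])
  out11 <- make_records(offset_ll(prj, -83, 31, 31, 0)[, 1],
                        offset_ll(prj, -83, 31, 31, 0)[, 2])
  expect_equal(nrow(filter_range(inside, ring, 10, prj)), 1)
  expect_equal(nrow(filter_range(out9, ring, 10, prj)), 1)
  expect_equal(nrow(filter_range(out11, ring, 10, prj)), 0)
  expect_error(filter_range(inside, cbind(1, 2), 10, prj), "degenerate")
})

test_that("uncertainty filter treats missing estimates asymmetrically", {
  r <- make_records(rep(-83, 3), rep(31, 3), unc = c(6000, NA, NA))
  kept_target <- filter_uncertainty(r, 5000, drop_missing = FALSE)
  expect_equal(nrow(kept_target), 2)        # 6 km dropped, missing retained
  kept_effort <- filter_uncertainty(r, 2500, drop_missing = TRUE)
  expect_equal(nrow(kept_effort), 0)        # missing dropped for effort
  r2 <- make_records(-83, 31, unc = 2400)
  expect_equal(nrow(filter_uncertainty(r2, 2500, drop_missing = TRUE)), 1)
})

test_that("same-day dedup collapses 10-m clusters by single linkage", {
  base <- c(-83, 31)
  step <- function(m) m / 111320              # degrees of latitude per metre
  two <- make_records(rep(base[1], 2), base[2] + c(0, step(5)))
  expect_equal(nrow(dedup_target(two)), 1)
  two_far <- make_records(rep(base[1], 2), base[2] + c(0, step(15)))
  expect_equal(nrow(dedup_target(two_far)), 2)
  # different days never collapse
  two_days <- make_records(rep(base[1], 2), base[2] + c(0, step(5)),
                           date = c("2010-02-01", "2010-02-02"))
  expect_equal(nrow(dedup_target(two_days)), 2)
})

test_that("dedup matches a union-find oracle on a mixed-gap chain", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:20) {
    n <- 5
    gaps <- runif(n - 1, 2, 20)               # metres, mixed around the cutoff
    lat <- 31 + cumsum(c(0, gaps)) / 111320
    recs <- make_records(rep(-83, n), lat)
    got <- nrow(dedup_target(recs, dist_m = 10))
    d <- geosphere::distm(cbind(recs$lon, recs$lat))
    g <- igraph::graph_from_adjacency_matrix(d <= 10, mode = "undirected",
                                             diag = FALSE)
    expect_equal(got, igraph::components(g)$no)
  }
})

test_that("dedup output is order invariant and honors source priority", {
  lat <- 31 + c(0, 3, 6, 40, 44) / 111320
  recs <- make_records(rep(-83, 5), lat,
                       source = c("gbif", "museum", "inat", "gbif", "museum"))
  a <- dedup_target(recs, source_priority = c("museum", "gbif", "inat"))
  b <- dedup_target(recs[5:1, ], source_priority = c("museum", "gbif", "inat"))
  expect_setequal(a$record_id, b$record_id)
  expect_true(all(a$source == "museum"))      # best source kept per cluster
})

test_that("effort dedup keys on date, rounded coordinates and observer", {
  r <- make_records(rep(-83, 2), rep(31, 2), species = c("sp_a", "sp_b"))
  expect_equal(nrow(dedup_effort(r)), 1)      # two species, one search event
  r2 <- make_records(rep(-83, 2), rep(31, 2), observer = c("a", "b"))
  expect_equal(nrow(dedup_effort(r2)), 2)
  r3 <- make_records(rep(-83, 2), rep(31, 2),
                     date = c("2010-02-01", "2010-02-02"))
  expect_equal(nrow(dedup_effort(r3)), 2)
  # missing observer falls back to (source, coordinates)
  r4 <- make_records(rep(-83, 2), rep(31, 2), observer = NA_character_)
  expect_equal(nrow(dedup_effort(r4)), 1)
})

test_that("season window is inclusive and wraps the year boundary", {
  r <- make_records(rep(-83, 4), rep(31, 4),
                    date = c("2010-03-15", "2010-07-01",
                             "2010-11-01", "2010-04-30"))
  kept <- filter_season(r)
  expect_setequal(format(kept$event_date, "%m-%d"),
                  c("03-15", "11-01", "04-30"))
})

test_that("regional species restrictions use state field or polygons", {
  map <- list(sp_all = "all", sp_sc = c("SC"))
  r <- make_records(rep(-83, 3), rep(31, 3),
                    species = c("sp_sc", "sp_sc", "sp_all"),
                    state = c("SC", "GA", NA))
  kept <- filter_nontarget_species(r, map)
  expect_setequal(kept$species, c("sp_sc", "sp_all"))
  expect_true(all(kept$state %in% c("SC", NA)))
  # species not in the map are never effort events
  r2 <- make_records(-83, 31, species = "unlisted")
  expect_equal(nrow(filter_nontarget_species(r2, map)), 0)
  # missing state resolved by polygon
  states <- poly_set("SC", list(square_ring(prj, -83, 31, 30)))
  r3 <- make_records(-83, 31, species = "sp_sc", state = NA_character_)
  expect_equal(nrow(filter_nontarget_species(r3, map, states, prj)), 1)
  # unresolvable region-restricted record is dropped and counted
  r4 <- filter_nontarget_species(r3, map)
  expect_equal(nrow(r4), 0)
  expect_equal(attr(r4, "dropped_unresolved"), 1L)
})

test_that("cleaning operations are idempotent", {
  set.seed(7)
  n <- 60
  recs <- make_records(-83 + runif(n, -0.5, 0.5), 31 + runif(n, -0.5, 0.5),
                       date = sample(c("2010-02-01", "2010-08-01"), n, TRUE),
                       unc = sample(c(NA, 100, 3000, 7000), n, TRUE),
                       observer = sample(c("a", "b", NA), n, TRUE))
  ring <- square_ring(prj, -83, 31, 40)
  ops <- list(
    function(r) filter_range(r, ring, 10, prj),
    function(r) filter_uncertainty(r, 5000, FALSE),
    function(r) filter_uncertainty(r, 2500, TRUE),
    function(r) dedup_target(r),
    function(r) dedup_effort(r),
    function(r) filter_season(r)
  )
  for (op in ops) {
    once <- op(recs)
    twice <- op(once)
    expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
  }
})

test_that("cleaning reports reconcile with input and output sizes", {
  set.seed(11)
  n <- 80
  recs <- make_records(-83 + runif(n, -0.6, 0.6), 31 + runif(n, -0.6, 0.6),
                       unc = sample(c(NA, 100, 7000), n, TRUE))
  ring <- square_ring(prj, -83, 31, 30)
  cleaned <- clean_target_records(recs, ring, projection = prj)
  rep <- cleaning_report(cleaned)
  expect_equal(sum(rep$n_dropped, na.rm = TRUE), n - nrow(cleaned))
  expect_equal(rep$n_input[1], n)
})
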