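## Synthetic data with known truth.  The generator emulates the structure
## of a compiled multi-source occurrence dataset: populations scattered
## over a landscape, latent extirpation driven by known logit-linear
## covariate effects, search effort reconstructed from non-target records
## concentrated in the Nov-Apr season and increasing over calendar time,
## plus the dirt real databases carry (duplicates, missing uncertainty,
## out-of-range decoys).

#' Generating truth for synthetic datasets
#'
#' Default conditions: 407 populations over 1950-2024, true parameters of
#' the magnitude estimated for the study system (persistence intercepts
#' near logit(0.81), strong positive habitat-suitability and
#' winter-precipitation effects, negative imperviousness effect, detection
#' intercept near logit(0.014) with a small positive yearly trend and a
#' positive effort slope), ecoregion mix 0.47/0.40/0.13, and Poisson
#' observer-day effort whose log-mean rises by 0.08/year so that ~87% of
#' effort events fall on or after 2000, averaging 0.143 events per
#' population-year.
#'
#' @param n_pops number of populations
#' @param year_range modeled calendar years
#' @param t_ref detection reference year
#' @param params true [cjs_params()]
#' @param eco_probs ecoregion membership probabilities (named)
#' @param effort_trend yearly slope of log effort intensity
#' @param effort_mean mean observer-days per population-year
#' @param buffer_km population buffer radius
#' @return a `sim_truth` list, serializable with [write_truth()]
#' @export
sim_truth <- function(n_pops = 407,
                      year_range = c(1950, 2024),
                      t_ref = 1987,
                      params = cjs_params(
                        alpha = qlogis(c(ecoregion_1 = 0.808,
                                         ecoregion_2 = 0.815,
                                         ecoregion_3 = 0.834)),
                        beta_hs = 2.856, beta_rain = 4.007,
                        beta_imp = -1.553,
                        gamma0 = qlogis(0.014),
                        beta_trend = 0.019, beta_effort = 0.279),
                      eco_probs = c(ecoregion_1 = 0.47, ecoregion_2 = 0.40,
                                    ecoregion_3 = 0.13),
                      effort_trend = 0.08,
                      effort_mean = 0.143,
                      buffer_km = 2.5) {
  stopifnot(length(eco_probs) == length(params$alpha))
  structure(list(n_pops = n_pops, year_range = year_range, t_ref = t_ref,
                 params = params, eco_probs = eco_probs,
                 effort_trend = effort_trend, effort_mean = effort_mean,
                 buffer_km = buffer_km),
            class = "sim_truth")
}

## Poisson effort intensity per year: log-linear trend calibrated to the
## requested overall mean.
effort_intensity <- function(truth) {
  years <- seq(truth$year_range[1], truth$year_range[2])
  raw <- exp(truth$effort_trend * (years - years[1]))
  raw * truth$effort_mean * length(years) / sum(raw)
}

#' Simulate detection/effort matrices directly from the model
#'
#' Matrix-level generator used for parameter-recovery and calibration
#' experiments: covariates are drawn from fixed laws (`h ~ Beta(2, 2)`,
#' `w ~ Unif(0, 1)`, `v ~ Beta(1.2, 8)`), latent states from the annual
#' persistence process (every population treated as known at the start
#' year, matching the likelihood's conditioning exactly), effort from the
#' Poisson observer-day process, and detections from the detection model
#' with the realized z-scored effort.
#'
#' @param truth a [sim_truth()]
#' @param seed RNG seed
#' @return list with `det` (a `detection_matrix`), `eff` (an
#'   `effort_matrix`), `covariates` tibble, latent last-extant-year `tau`
#'   (T+1 index convention: `tau = T + 1` means survived) and `truth`
#' @export
simulate_histories <- function(truth = sim_truth(), seed = 1) {
  set.seed(seed)
  N <- truth$n_pops
  years <- seq(truth$year_range[1], truth$year_range[2])
  T <- length(years)
  eco <- sample(names(truth$eco_probs), N, replace = TRUE,
                prob = truth$eco_probs)
  covariates <- tibble::tibble(
    pop_id = sprintf("pop_%04d", seq_len(N)),
    ecoregion = eco,
    h = rbeta(N, 2, 2),
    w = runif(N),
    v = rbeta(N, 1.2, 8)
  )
  phi <- annual_persistence(truth$params, covariates)
  lam <- effort_intensity(truth)
  e_raw <- matrix(rpois(N * T, rep(lam, each = N)), N, T,
                  dimnames = list(covariates$pop_id, years))
  mu <- mean(e_raw)
  sdv <- stats::sd(e_raw)
  if (sdv == 0) sdv <- 1
  e <- (e_raw - mu) / sdv
  p <- detection_prob(truth$params,
                      matrix(years, N, T, byrow = TRUE), e, truth$t_ref)
  sim <- simulate_cjs_matrix(phi, p)
  y <- sim$y
  dimnames(y) <- dimnames(e_raw)
  L <- apply(y, 1, function(r) if (any(r > 0)) max(which(r > 0)) else 1L)
  last_det <- ifelse(apply(y, 1, function(r) any(r > 0)),
                     years[pmax(L, 1L)], NA_integer_)
  tau <- apply(sim$z, 1, function(z) if (all(z > 0)) T + 1L else min(which(z == 0)))
  det <- structure(list(y = y, years = years,
                        first_detection_year = apply(y, 1, function(r)
                          if (any(r > 0)) years[which(r > 0)[1]] else NA_integer_),
                        last_detection_year = last_det,
                        last_record_year = last_det,
                        known_before_start = rep(TRUE, N),
                        L = as.integer(L)),
                   class = "detection_matrix")
  eff <- structure(list(e_raw = e_raw, e = e,
                        scaling = list(name = "zscore", center = mu, scale = sdv),
                        years = years, n_events_outside = 0L),
                   class = "effort_matrix")
  list(det = det, eff = eff, covariates = covariates, tau = tau,
       z = sim$z, truth = truth, seed = seed)
}

#' Simulate a synthetic landscape
#'
#' Builds the spatial inputs of the pipeline: a smooth habitat-suitability
#' field in `[0, 1]`, monthly precipitation grids with a south-north
#' gradient, a patchy imperviousness field, banded ecoregion polygons,
#' banded state polygons, rectangular protected areas and a range polygon,
#' all in a projection centred on the study extent.
#'
#' @param seed RNG seed (same seed, same landscape, bit for bit)
#' @param extent_km `c(width, height)` of the study extent
#' @param n_ecoregions number of ecoregion bands
#' @param cellsize_km suitability/imperviousness cell size
#' @param precip_cellsize_km precipitation cell size (coarser, like real
#'   climate grids)
#' @param precip_years winters (Jan/Feb year labels) with monthly grids
#' @param n_protected number of protected-area rectangles
#' @param lon0,lat0 geographic centre of the study extent
#' @return a `sim_landscape` list: rasters (`suitability`, `impervious`,
#'   `precip_monthly`), polygon layers (`range`, `ecoregions`, `states`,
#'   `protected`), `protected_categories` map, `projection`, `extent`
#' @export
simulate_landscape <- function(seed = 1, extent_km = c(120, 120),
                               n_ecoregions = 3, cellsize_km = 1,
                               precip_cellsize_km = 5,
                               precip_years = 1994:2023,
                               n_protected = 6,
                               lon0 = -83, lat0 = 31) {
  set.seed(seed)
  prj <- albers_projection(lon0 = lon0, lat0 = lat0,
                           lat1 = lat0 - 2, lat2 = lat0 + 2)
  anchor <- prj$project(lon0, lat0)
  xll <- anchor[1] - extent_km[1] / 2
  yll <- anchor[2] - extent_km[2] / 2
  W <- extent_km[1]; H <- extent_km[2]

  smooth_field <- function(cs, n_bumps, base = 0) {
    nx <- ceiling(W / cs); ny <- ceiling(H / cs)
    xs <- xll + (seq_len(nx) - 0.5) * cs
    ys <- yll + (ny - seq_len(ny) + 0.5) * cs
    m <- matrix(base, ny, nx)
    for (b in seq_len(n_bumps)) {
      cx <- runif(1, xll, xll + W); cy <- runif(1, yll, yll + H)
      s <- runif(1, W / 12, W / 4); amp <- runif(1, -1, 1)
      m <- m + amp * exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) / (2 * s^2))
    }
    grid_raster(m, xll, yll, cs)
  }

  suit <- smooth_field(cellsize_km, 12)
  suit$values <- (suit$values - min(suit$values)) /
    (max(suit$values) - min(suit$values))

  imp <- smooth_field(cellsize_km, 0)
  imp$values[] <- 0
  xs <- raster_x_centers(imp); ys <- raster_y_centers(imp)
  for (b in seq_len(4)) {                     # compact urban blobs
    cx <- runif(1, xll + 0.1 * W, xll + 0.9 * W)
    cy <- runif(1, yll + 0.1 * H, yll + 0.9 * H)
    s <- runif(1, W / 40, W / 20)
    imp$values <- pmin(imp$values +
      runif(1, 0.5, 0.9) * exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) / (2 * s^2)), 1)
  }

  precip <- list()
  npx <- ceiling(W / precip_cellsize_km); npy <- ceiling(H / precip_cellsize_km)
  pys <- yll + (npy - seq_len(npy) + 0.5) * precip_cellsize_km
  gradient <- matrix(rep(120 + 0.6 * (pys - yll), npx), npy, npx)
  month_effect <- c("12" = 10, "01" = 0, "02" = -5)
  for (y in precip_years) {
    for (mo in c("12", "01", "02")) {
      yy <- if (mo == "12") y - 1L else y
      noise <- matrix(rnorm(npy * npx, 0, 8), npy, npx)
      precip[[sprintf("%d-%s", yy, mo)]] <-
        grid_raster(pmax(gradient + month_effect[[mo]] + noise, 1),
                    xll, yll, precip_cellsize_km)
    }
  }

  inset <- 2
  range_ring_xy <- cbind(
    c(xll + inset, xll + W - inset, xll + W - inset, xll + inset),
    c(yll + inset, yll + inset, yll + H - inset, yll + H - inset))
  to_ll <- function(m) prj$unproject(m[, 1], m[, 2])
  range_poly <- poly_set("range", list(to_ll(range_ring_xy)))

  band <- function(i, n, horiz = FALSE) {
    # bands extend past the extent so boundary records always fall inside
    if (horiz) {
      y0 <- yll + (i - 1) * H / n; y1 <- yll + i * H / n
      if (i == 1) y0 <- y0 - 50
      if (i == n) y1 <- y1 + 50
      cbind(c(xll - 50, xll + W + 50, xll + W + 50, xll - 50),
            c(y0, y0, y1, y1))
    } else {
      x0 <- xll + (i - 1) * W / n; x1 <- xll + i * W / n
      if (i == 1) x0 <- x0 - 50
      if (i == n) x1 <- x1 + 50
      cbind(c(x0, x1, x1, x0),
            c(yll - 50, yll - 50, yll + H + 50, yll + H + 50))
    }
  }
  ecoregions <- poly_set(paste0("ecoregion_", seq_len(n_ecoregions)),
                         lapply(seq_len(n_ecoregions), function(i)
                           to_ll(band(i, n_ecoregions))))
  state_codes <- c("AA", "BB", "CC")
  states <- poly_set(state_codes,
                     lapply(seq_along(state_codes), function(i)
                       to_ll(band(i, length(state_codes), horiz = TRUE))))

  raw_desigs <- c("State Forest", "State Park", "National Forest",
                  "National Wildlife Refuge", "Wildlife Management Area",
                  "Military Installation", "Private Conservation Land",
                  "Research Reserve")
  protected_categories <- c(
    "State Forest" = "state forest", "State Park" = "state park",
    "National Forest" = "national forest",
    "National Wildlife Refuge" = "national wildlife refuge",
    "Wildlife Management Area" = "wildlife management area",
    "Military Installation" = "military", "Private Conservation Land" = "ngo",
    "Research Reserve" = "other")
  prot_rings <- list(); prot_labels <- character(0)
  for (b in seq_len(n_protected)) {
    w <- runif(1, 0.08, 0.2) * W; h <- runif(1, 0.08, 0.2) * H
    x0 <- runif(1, xll + inset, xll + W - inset - w)
    y0 <- runif(1, yll + inset, yll + H - inset - h)
    prot_rings[[b]] <- to_ll(cbind(c(x0, x0 + w, x0 + w, x0),
                                   c(y0, y0, y0 + h, y0 + h)))
    prot_labels[b] <- raw_desigs[(b - 1L) %% length(raw_desigs) + 1L]
  }
  protected <- poly_set(prot_labels, prot_rings)

  structure(list(suitability = suit, impervious = imp,
                 precip_monthly = precip, precip_years = precip_years,
                 range = range_poly, ecoregions = ecoregions,
                 states = states, protected = protected,
                 protected_categories = protected_categories,
                 projection = prj,
                 extent = c(xll = xll, yll = yll, width = W, height = H),
                 seed = seed),
            class = "sim_landscape")
}

## Raster value at a projected point (cell containing it).
raster_value_at <- function(r, x, y) {
  j <- pmin(pmax(ceiling((x - r$xll) / r$cellsize), 1L), ncol(r$values))
  i <- pmin(pmax(nrow(r$values) - ceiling((y - r$yll) / r$cellsize) + 1L, 1L),
            nrow(r$values))
  r$values[cbind(i, j)]
}

#' Simulate occurrence-record tables over a landscape
#'
#' Record-level generator exercising the full ingestion path.  Population
#' centres are placed inside the range polygon with enough separation that
#' buffer-dissolve recovers them exactly; every population is anchored by
#' an early (pre-start-year) record.  Latent extirpation follows the
#' persistence model with covariates read from the landscape at the
#' centre; search events are Poisson observer-days whose intensity rises
#' over calendar time; detections follow the detection model given the
#' realized scaled effort of the non-target stream.  The tables include the
#' defects cleaning must handle: near-duplicate records, missing
#' coordinate uncertainty (36% of target records, as in multi-source
#' compilations), oversized uncertainties, out-of-range decoys and
#' out-of-season non-target records.
#'
#' @param truth a [sim_truth()] (covariate laws are replaced by landscape
#'   values)
#' @param landscape a [simulate_landscape()] result
#' @param seed RNG seed
#' @param effort_species names of non-target indexing species
#' @param frac_missing_unc fraction of target records without an
#'   uncertainty estimate
#' @param frac_decoy fraction of extra out-of-range target decoys
#' @param frac_dup fraction of target records duplicated within 10 m
#' @param jitter_km coordinate jitter radius around the population centre
#' @return list with `target` and `effort` `occ_records` tibbles and a
#'   `truth` list holding generating parameters, centres, covariates,
#'   latent `tau` and the seed
#' @export
simulate_records <- function(truth, landscape, seed = 1,
                             effort_species = c("Pseudacris crucifer",
                                                "Pseudacris nigrita",
                                                "Lithobates sphenocephalus"),
                             frac_missing_unc = 0.36,
                             frac_decoy = 0.03,
                             frac_dup = 0.05,
                             jitter_km = 0.3) {
  set.seed(seed)
  prj <- landscape$projection
  ext <- landscape$extent
  N <- truth$n_pops
  years <- seq(truth$year_range[1], truth$year_range[2])
  T <- length(years)

  ## --- population centres: dart throwing with hard separation ----------
  min_sep <- 2 * truth$buffer_km + 2 * jitter_km + 0.2
  centers <- matrix(NA_real_, N, 2)
  placed <- 0L
  attempts <- 0L
  rring <- prj$project(landscape$range$ring[[1]][, 1],
                       landscape$range$ring[[1]][, 2])
  while (placed < N && attempts < 200000L) {
    attempts <- attempts + 1L
    cand <- c(runif(1, ext["xll"] + 1, ext["xll"] + ext["width"] - 1),
              runif(1, ext["yll"] + 1, ext["yll"] + ext["height"] - 1))
    if (!point_in_ring(cand[1], cand[2], rring)) next
    if (placed > 0) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  if (placed < N) stop("could not place ", N, " separated populations; ",
                       "enlarge the extent", call. = FALSE)

  ## --- truth covariates and latent states ------------------------------
  wraster <- scale_01(winter_precip_raster(landscape$precip_monthly,
                                           landscape$precip_years))
  covariates <- tibble::tibble(
    pop_id = sprintf("pop_%04d", seq_len(N)),
    h = raster_value_at(landscape$suitability, centers[, 1], centers[, 2]),
    w = raster_value_at(wraster, centers[, 1], centers[, 2]),
    v = raster_value_at(landscape$impervious, centers[, 1], centers[, 2])
  )
  eco_rings <- lapply(landscape$ecoregions$ring,
                      function(r) prj$project(r[, 1], r[, 2]))
  eco <- rep(landscape$ecoregions$label[1], N)
  for (k in seq_along(eco_rings)) {
    inside <- point_in_ring(centers[, 1], centers[, 2], eco_rings[[k]])
    eco[inside] <- landscape$ecoregions$label[k]
  }
  covariates$ecoregion <- eco
  ## map truth alphas onto the landscape's ecoregion labels
  alpha <- truth$params$alpha
  names(alpha) <- landscape$ecoregions$label[seq_along(alpha)]
  params <- truth$params
  params$alpha <- alpha
  phi <- annual_persistence(params, covariates)

  lam <- effort_intensity(truth)
  e_sim <- matrix(rpois(N * T, rep(lam, each = N)), N, T)
  mu <- mean(e_sim); sdv <- max(stats::sd(e_sim), 1e-9)
  p <- detection_prob(params, matrix(years, N, T, byrow = TRUE),
                      (e_sim - mu) / sdv, truth$t_ref)
  ## latent states; detection happens at event level below (each search
  ## event of an extant population detects the target with probability p)
  sim <- simulate_cjs_matrix(phi, p * 0)
  z <- sim$z
  n_detect <- matrix(rbinom(N * T, as.vector(e_sim) * as.vector(z),
                            as.vector(p)), N, T)
  tau <- apply(z, 1, function(zi) if (all(zi > 0)) T + 1L else min(which(zi == 0)))

  ## --- record emission --------------------------------------------------
  season_date <- function(year) {
    # a date in the Nov-Apr activity season whose calendar year is `year`
    doy <- sample(c(1:119, 306:364), 1)
    as.Date(doy - 1, origin = sprintf("%d-01-01", year))
  }
  jitter_pt <- function(center) {
    ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * jitter_km
    center + rad * c(cos(ang), sin(ang))
  }
  observers <- sprintf("obs_%03d", 1:40)
  sources <- c("gbif", "inat", "museum", "survey")
  t_rows <- list(); e_rows <- list()
  add_target <- function(x, y, date, unc, source) {
    ll <- prj$unproject(x, y)
    t_rows[[length(t_rows) + 1L]] <<- tibble::tibble(
      species = "Pseudacris ornata", event_date = as.character(date),
      lon = ll[1], lat = ll[2], coord_uncertainty_m = unc,
      observer = sample(c(observers, NA), 1), source = source,
      state = NA_character_)
  }
  state_rings <- lapply(landscape$states$ring,
                        function(r) prj$project(r[, 1], r[, 2]))
  state_of <- function(x, y) {
    for (k in seq_along(state_rings)) {
      if (point_in_ring(x, y, state_rings[[k]])) return(landscape$states$label[k])
    }
    NA_character_
  }
  for (i in seq_len(N)) {
    # anchor record predating the modeled period (historical/museum
    # records often carry no uncertainty estimate either)
    pt <- jitter_pt(centers[i, ])
    add_target(pt[1], pt[2], season_date(sample(1900:1949, 1)),
               if (runif(1) < frac_missing_unc) NA_real_ else 100, "museum")
    for (t in seq_len(T)) {
      n_ev <- e_sim[i, t]
      if (n_ev == 0) next
      # each search event either detects the target (emitting a target
      # record) or emits a non-target record
      for (k in seq_len(n_ev)) {
        pt <- jitter_pt(centers[i, ])
        date <- season_date(years[t])
        if (k <= n_detect[i, t]) {
          unc <- if (runif(1) < frac_missing_unc) NA_real_ else
            min(exp(rnorm(1, log(400), 1)), 20000)
          add_target(pt[1], pt[2], date, unc, sample(sources, 1))
        } else {
          ll <- prj$unproject(pt[1], pt[2])
          e_rows[[length(e_rows) + 1L]] <- tibble::tibble(
            species = sample(effort_species, 1),
            event_date = as.character(date),
            lon = ll[1], lat = ll[2],
            coord_uncertainty_m = if (runif(1) < 0.05) NA_real_ else
              runif(1, 10, 2400),
            observer = if (runif(1) < 0.1) NA_character_ else
              sample(observers, 1),
            source = sample(sources[1:2], 1),
            state = state_of(pt[1], pt[2]))
        }
      }
    }
  }
  target <- dplyr::bind_rows(t_rows)
  ## near-duplicates (same day, < 10 m apart, different database)
  n_dup <- ceiling(frac_dup * nrow(target))
  if (n_dup > 0) {
    pick <- sample(nrow(target), n_dup)
    dups <- target[pick, ]
    dups$lon <- dups$lon + runif(n_dup, -3e-5, 3e-5)
    dups$source <- "herpmapper"
    target <- dplyr::bind_rows(target, dups)
  }
  ## out-of-range decoys (> 10 km beyond the range polygon)
  n_dec <- ceiling(frac_decoy * nrow(target))
  if (n_dec > 0) {
    dx <- ext["xll"] - runif(n_dec, 15, 40)
    dy <- runif(n_dec, ext["yll"], ext["yll"] + ext["height"])
    ll <- prj$unproject(dx, dy)
    decoys <- tibble::tibble(
      species = "Pseudacris ornata",
      event_date = as.character(season_date(2000)),
      lon = ll[, 1], lat = ll[, 2], coord_uncertainty_m = 100,
      observer = NA_character_, source = "gbif", state = NA_character_)
    target <- dplyr::bind_rows(target, decoys)
  }
  effort <- dplyr::bind_rows(e_rows)
  ## a few out-of-season non-target records (must be filtered)
  if (nrow(effort) > 0) {
    n_oos <- max(1L, nrow(effort) %/% 50L)
    oos <- effort[sample(nrow(effort), n_oos), ]
    oos$event_date <- as.character(as.Date(sprintf("%d-07-15", 2010)))
    effort <- dplyr::bind_rows(effort, oos)
  }
  list(
    target = as_occ_records(target),
    effort = as_occ_records(effort),
    truth = list(params = params, centers = centers,
                 covariates = covariates, tau = tau, z = sim$z,
                 e_sim = e_sim, buffer_km = truth$buffer_km,
                 year_range = truth$year_range, t_ref = truth$t_ref,
                 seed = seed)
  )
}

#' Serialize / restore a simulation truth
#'
#' @param truth truth list from [simulate_records()]
#' @param path JSON file
#' @return `read_truth` returns the truth list
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$params <- unclass(out$params)
  out$centers <- unname(apply(out$centers, 1, c, simplify = FALSE))
  out$covariates <- as.list(out$covariates)
  out$z <- NULL                                 # reconstructible from tau
  out$e_sim <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$params <- cjs_params(alpha = unlist(x$params$alpha),
                         beta_hs = x$params$beta_hs,
                         beta_rain = x$params$beta_rain,
                         beta_imp = x$params$beta_imp,
                         gamma0 = x$params$gamma0,
                         beta_trend = x$params$beta_trend,
                         beta_effort = x$params$beta_effort)
  x$centers <- if (is.list(x$centers)) do.call(rbind, x$centers) else
    as.matrix(x$centers)
  x$covariates <- tibble::as_tibble(x$covariates)
  x
}

#' Write a packaged synthetic dataset to disk
#'
#' Two documented fixtures: `"tiny"` (12 populations on a 70 km extent;
#' fast end-to-end runs) and `"paper-scale"` (407 populations on a 340 km
#' extent; full-size experiments).  Both are fully deterministic in the
#' seed and regenerate byte-identically.  The bundle contains everything
#' [run_pipeline()] reads: record CSVs, ASCII-grid rasters, GeoJSON
#' polygon layers, the serialized truth and a ready config.
#'
#' @param name `"tiny"` or `"paper-scale"`
#' @param dir output directory (created)
#' @param seed RNG seed (defaults fixed per fixture)
#' @param precip_years winters for the monthly precipitation stack
#' @return the config list (invisibly written as `config.yaml`)
#' @export
fixture_bundle <- function(name = c("tiny", "paper-scale"), dir,
                           seed = NULL, precip_years = NULL) {
  name <- match.arg(name)
  cfg0 <- switch(name,
    "tiny" = list(seed = 101L, extent = c(70, 70), n_pops = 12L,
                  cellsize = 1, precip_cellsize = 5,
                  precip_years = 2019:2023),
    "paper-scale" = list(seed = 202L, extent = c(340, 340), n_pops = 407L,
                         cellsize = 2, precip_cellsize = 5,
                         precip_years = 1994:2023))
  seed <- seed %||% cfg0$seed
  precip_years <- precip_years %||% cfg0$precip_years
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  land <- simulate_landscape(seed = derive_seed(seed, 1),
                             extent_km = cfg0$extent,
                             cellsize_km = cfg0$cellsize,
                             precip_cellsize_km = cfg0$precip_cellsize,
                             precip_years = precip_years)
  truth <- sim_truth(n_pops = cfg0$n_pops)
  recs <- simulate_records(truth, land, seed = derive_seed(seed, 2))

  readr::write_csv(tibble::as_tibble(recs$target),
                   file.path(dir, "target_records.csv"))
  readr::write_csv(tibble::as_tibble(recs$effort),
                   file.path(dir, "effort_records.csv"))
  write_ascii_grid(land$suitability, file.path(dir, "suitability.asc"))
  write_ascii_grid(land$impervious, file.path(dir, "impervious.asc"))
  pdir <- file.path(dir, "precip")
  dir.create(pdir, showWarnings = FALSE)
  for (nm in names(land$precip_monthly)) {
    write_ascii_grid(land$precip_monthly[[nm]],
                     file.path(pdir, paste0("precip_", nm, ".asc")),
                     digits = 5)
  }
  write_geojson_polygons(land$range, file.path(dir, "range.geojson"))
  write_geojson_polygons(land$ecoregions, file.path(dir, "ecoregions.geojson"))
  write_geojson_polygons(land$states, file.path(dir, "states.geojson"))
  write_geojson_polygons(land$protected, file.path(dir, "protected.geojson"))
  write_truth(recs$truth, file.path(dir, "truth.json"))

  config <- list(
    name = name, seed = seed, dir = dir,
    buffer_km = truth$buffer_km,
    year_range = truth$year_range,
    t_ref = truth$t_ref,
    target_species = "Pseudacris ornata",
    effort_species = list("Pseudacris crucifer" = "all",
                          "Pseudacris nigrita" = "all",
                          "Lithobates sphenocephalus" = "all"),
    projection = list(lon0 = land$projection$lon0,
                      lat0 = land$projection$lat0,
                      lat1 = land$projection$lat1,
                      lat2 = land$projection$lat2),
    precip_years = range(precip_years),
    protected_categories = as.list(land$protected_categories),
    paths = list(
      target_records = "target_records.csv",
      effort_records = "effort_records.csv",
      suitability = "suitability.asc",
      impervious = "impervious.asc",
      precip_dir = "precip",
      range = "range.geojson",
      ecoregions = "ecoregions.geojson",
      states = "states.geojson",
      protected = "protected.geojson",
      truth = "truth.json"
    ),
    model = list(chains = 3, iterations = 6000, burn_in = 3000, thin = 3,
                 prior_sd = 10)
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(config)
}
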