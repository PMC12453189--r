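# Independent oracles and small fixture builders used across the suite.

# Brute-force CJS likelihood: enumerate every binary latent sequence of
# length T, keep the monotone ones starting extant, and sum the product of
# Bernoulli transition and observation terms.  Deliberately naive -- no
# shared code with the package's marginalized computation.
brute_force_lik <- function(y, p, phi) {
  T <- length(y)
  grids <- rep(list(c(0L, 1L)), T)
  states <- as.matrix(expand.grid(grids))
  total <- 0
  for (s in seq_len(nrow(states))) {
    z <- states[s, ]
    if (z[1] != 1L) next
    if (any(diff(z) > 0)) next               # monotone non-increasing only
    pr <- 1
    for (t in 2:T) {
      pr <- pr * if (z[t - 1] == 1L) (if (z[t] == 1L) phi else 1 - phi) else
        (if (z[t] == 0L) 1 else 0)
    }
    for (t in seq_len(T)) {
      pdet <- z[t] * p[t]
      pr <- pr * if (y[t] == 1L) pdet else 1 - pdet
    }
    total <- total + pr
  }
  unname(total)
}

brute_force_persist <- function(y, p, phi) {
  T <- length(y)
  grids <- rep(list(c(0L, 1L)), T)
  states <- as.matrix(expand.grid(grids))
  num <- 0; den <- 0
  for (s in seq_len(nrow(states))) {
    z <- states[s, ]
    if (z[1] != 1L || any(diff(z) > 0)) next
    pr <- 1
    for (t in 2:T) {
      pr <- pr * if (z[t - 1] == 1L) (if (z[t] == 1L) phi else 1 - phi) else
        (if (z[t] == 0L) 1 else 0)
    }
    for (t in seq_len(T)) {
      pdet <- z[t] * p[t]
      pr <- pr * if (y[t] == 1L) pdet else 1 - pdet
    }
    den <- den + pr
    if (z[T] == 1L) num <- num + pr
  }
  unname(num / den)
}

# Random single-population instance compatible with the model's
# constraints (y zero after L).
random_instance <- function(T) {
  phi <- runif(1, 0.05, 0.95)
  p <- runif(T, 0.02, 0.9)
  L <- sample(T, 1)
  y <- integer(T)
  if (runif(1) < 0.8) {
    y[L] <- 1L
    extra <- which(runif(T) < 0.4 & seq_len(T) < L)
    y[extra] <- 1L
  } else {
    L <- 1L                                   # never-detected population
  }
  list(y = y, p = p, phi = phi, L = L)
}

# Record tibble builder (valid WGS84 rows around a local origin).
make_records <- function(lon, lat, date = "2010-02-01", species = "target",
                         unc = 100, observer = "obs_1", source = "gbif",
                         state = NA_character_) {
  n <- max(length(lon), length(lat), length(date))
  as_occ_records(tibble::tibble(
    species = rep_len(species, n),
    event_date = rep_len(date, n),
    lon = rep_len(lon, n),
    lat = rep_len(lat, n),
    coord_uncertainty_m = rep_len(unc, n),
    observer = rep_len(observer, n),
    source = rep_len(source, n),
    state = rep_len(state, n)
  ))
}

# A square polygon (lon/lat ring) of the given half-width in km centred on
# (lon0, lat0) under the given projection.
square_ring <- function(prj, lon0, lat0, half_km) {
  c0 <- prj$project(lon0, lat0)
  ring_xy <- cbind(c0[1] + c(-1, 1, 1, -1) * half_km,
                   c0[2] + c(-1, -1, 1, 1) * half_km)
  prj$unproject(ring_xy[, 1], ring_xy[, 2])
}

# Offset a lon/lat point by (dx, dy) km under the projection.
offset_ll <- function(prj, lon, lat, dx_km, dy_km) {
  xy <- prj$project(lon, lat)
  prj$unproject(xy[, 1] + dx_km, xy[, 2] + dy_km)
}
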