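## Population delineation by buffer-dissolve.  A population is the union of
## discs of radius `buffer_km` around its member records; two records share
## a population exactly when they are connected through pairs closer than
## 2 * buffer_km.  The disc-union polygon is kept implicit: a point lies
## inside a population iff it is within buffer_km of some member record.
## Area and centroid come from cell-centre counting on a fine grid
## (h = buffer_km / 64), which resolves an isolated disc's area to ~0.1%.

#' Delineate populations by buffer-dissolve
#'
#' Buffers every record by `buffer_km` and dissolves overlapping buffers:
#' records closer than `2 * buffer_km` end up in the same population.
#'
#' @param records cleaned `occ_records` of the target species
#' @param buffer_km buffer radius in km (default 2.5)
#' @param projection an [albers_projection()] used for all metric geometry
#' @return a `population_set` tibble with columns `pop_id`, `n_records`,
#'   `centroid_x`, `centroid_y`, `centroid_lon`, `centroid_lat`, `area_km2`;
#'   attributes `membership` (record row -> population row), `members`
#'   (list of projected member-coordinate matrices), `buffer_km`,
#'   `projection`.  Populations are ordered west-to-east by centroid so ids
#'   are invariant to record order.
#' @export
delineate_populations <- function(records, buffer_km = 2.5,
                                  projection = albers_projection()) {
  stopifnot(buffer_km > 0)
  n <- nrow(records)
  if (n == 0) {
    warning("no records: returning an empty population set")
    out <- tibble::tibble(pop_id = character(0), n_records = integer(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          centroid_lon = numeric(0), centroid_lat = numeric(0),
                          area_km2 = numeric(0))
    class(out) <- c("population_set", class(out))
    attr(out, "membership") <- integer(0)
    attr(out, "members") <- list()
    attr(out, "buffer_km") <- buffer_km
    attr(out, "projection") <- projection
    return(out)
  }
  xy <- projection$project(records$lon, records$lat)
  comp <- uf_components(n, threshold_edges(xy, 2 * buffer_km))
  ncomp <- max(comp)
  stats <- lapply(seq_len(ncomp), function(k) {
    pts <- xy[comp == k, , drop = FALSE]
    disc_union_stats(pts, buffer_km)
  })
  cx <- vapply(stats, `[[`, numeric(1), "cx")
  cy <- vapply(stats, `[[`, numeric(1), "cy")
  area <- vapply(stats, `[[`, numeric(1), "area")
  ord <- order(cx, cy)
  relabel <- match(seq_len(ncomp), ord)
  ll <- projection$unproject(cx[ord], cy[ord])
  out <- tibble::tibble(
    pop_id = sprintf("pop_%04d", seq_len(ncomp)),
    n_records = as.integer(tabulate(relabel[comp], nbins = ncomp)),
    centroid_x = cx[ord], centroid_y = cy[ord],
    centroid_lon = ll[, 1], centroid_lat = ll[, 2],
    area_km2 = area[ord]
  )
  class(out) <- c("population_set", class(out))
  attr(out, "membership") <- relabel[comp]
  attr(out, "members") <- lapply(ord, function(k) xy[comp == k, , drop = FALSE])
  attr(out, "buffer_km") <- buffer_km
  attr(out, "projection") <- projection
  out
}

## Area and centroid of a union of equal discs by cell-centre counting.
disc_union_stats <- function(pts, r, h = r / 64) {
  xs <- seq(min(pts[, 1]) - r + h / 2, max(pts[, 1]) + r, by = h)
  ys <- seq(min(pts[, 2]) - r + h / 2, max(pts[, 2]) + r, by = h)
  mark <- matrix(FALSE, length(xs), length(ys))
  r2 <- r^2
  for (i in seq_len(nrow(pts))) {
    jx <- which(abs(xs - pts[i, 1]) <= r)
    jy <- which(abs(ys - pts[i, 2]) <= r)
    if (!length(jx) || !length(jy)) next
    mark[jx, jy] <- mark[jx, jy] |
      (outer((xs[jx] - pts[i, 1])^2, (ys[jy] - pts[i, 2])^2, `+`) <= r2)
  }
  idx <- which(mark, arr.ind = TRUE)
  list(area = nrow(idx) * h^2, cx = mean(xs[idx[, 1]]), cy = mean(ys[idx[, 2]]))
}

#' Assign projected points to populations
#'
#' A point belongs to population `i` when it lies within the dissolved
#' buffer, i.e. within `buffer_km` of one of `i`'s member records.  Buffers
#' of distinct populations cannot overlap (members of different populations
#' are at least `2 * buffer_km` apart), so assignment is unique.
#'
#' @param xy two-column matrix of projected coordinates (km)
#' @param populations a `population_set`
#' @return integer vector of population row indices (NA = outside all)
#' @export
assign_to_populations <- function(xy, populations) {
  members <- attr(populations, "members")
  r <- attr(populations, "buffer_km")
  out <- rep(NA_integer_, nrow(xy))
  r2 <- r^2
  for (k in seq_along(members)) {
    m <- members[[k]]
    box <- c(range(m[, 1]), range(m[, 2]))
    cand <- which(is.na(out) &
                    xy[, 1] >= box[1] - r & xy[, 1] <= box[2] + r &
                    xy[, 2] >= box[3] - r & xy[, 2] <= box[4] + r)
    if (!length(cand)) next
    for (i in cand) {
      d2 <- (m[, 1] - xy[i, 1])^2 + (m[, 2] - xy[i, 2])^2
      if (any(d2 <= r2)) out[i] <- k
    }
  }
  out
}

#' Label populations with the ecoregion containing their centroid
#'
#' Centroids outside every ecoregion polygon are attached to the nearest
#' one and flagged; centroids claimed by more than one (overlapping or
#' shared-boundary) polygon take the first in layer order, flagged.
#'
#' @param populations a `population_set`
#' @param ecoregion_polygons a [poly_set()] of level-III ecoregions
#' @return `populations` with columns `ecoregion` and `ecoregion_flag`
#' @export
assign_ecoregion <- function(populations, ecoregion_polygons) {
  if (nrow(ecoregion_polygons) == 0) {
    stop("ecoregion layer is empty", call. = FALSE)
  }
  proj <- attr(populations, "projection")
  lab <- rep(NA_character_, nrow(populations))
  flag <- rep(FALSE, nrow(populations))
  rings <- lapply(ecoregion_polygons$ring,
                  function(r) proj$project(r[, 1], r[, 2]))
  x <- populations$centroid_x
  y <- populations$centroid_y
  for (k in seq_along(rings)) {
    inside <- point_in_ring(x, y, rings[[k]])
    dup <- inside & !is.na(lab)
    flag[dup] <- TRUE
    lab[inside & is.na(lab)] <- ecoregion_polygons$label[k]
  }
  out <- which(is.na(lab))
  if (length(out)) {
    d <- sapply(rings, function(r) dist_to_ring(x[out], y[out], r))
    d <- matrix(d, nrow = length(out))
    nearest <- max.col(-d, ties.method = "first")
    lab[out] <- ecoregion_polygons$label[nearest]
    flag[out] <- TRUE
  }
  populations$ecoregion <- lab
  populations$ecoregion_flag <- flag
  populations
}

#' Assign protected-area categories to populations
#'
#' A population's category is the mapped designation of a protected-area
#' polygon containing its centroid, `"none"` when no polygon contains it.
#' Unmapped designations become `"other"` with a warning; centroids inside
#' several designations take the highest-priority category and are flagged.
#'
#' @param populations a `population_set`
#' @param protected_polygons a [poly_set()] whose labels are raw
#'   designations
#' @param category_map named character vector raw designation -> analysis
#'   category
#' @param priority character vector of categories, highest priority first;
#'   defaults to first appearance order in `category_map`
#' @return `populations` with columns `protected` and `protected_flag`
#' @export
assign_protected <- function(populations, protected_polygons, category_map,
                             priority = unique(unname(category_map))) {
  proj <- attr(populations, "projection")
  x <- populations$centroid_x
  y <- populations$centroid_y
  cats <- vector("list", nrow(populations))
  for (k in seq_len(nrow(protected_polygons))) {
    ring <- proj$project(protected_polygons$ring[[k]][, 1],
                         protected_polygons$ring[[k]][, 2])
    inside <- point_in_ring(x, y, ring)
    if (!any(inside)) next
    raw <- protected_polygons$label[k]
    cat_k <- unname(category_map[raw])
    if (is.null(cat_k) || is.na(cat_k)) {
      warning("unmapped protected-area designation '", raw,
              "': using 'other'")
      cat_k <- "other"
    }
    for (i in which(inside)) cats[[i]] <- c(cats[[i]], cat_k)
  }
  pick <- function(cs) {
    if (is.null(cs)) return(c("none", FALSE))
    if (length(unique(cs)) == 1) return(c(cs[1], FALSE))
    pr <- match(cs, priority)
    pr[is.na(pr)] <- length(priority) + 1L
    c(cs[order(pr)][1], TRUE)
  }
  res <- t(vapply(cats, pick, character(2)))
  populations$protected <- res[, 1]
  populations$protected_flag <- as.logical(res[, 2])
  populations
}

#' Zonal mean of a raster over population polygons
#'
#' Averages the raster cells whose centres fall inside each population's
#' dissolved buffer, ignoring missing cells.  Populations too small to
#' contain any cell centre take the value of the nearest cell and are
#' flagged.
#'
#' @param populations a `population_set`
#' @param raster a [grid_raster()] in the same projection
#' @return tibble with `pop_id`, `value`, `n_cells`, `flag_no_cells`
#' @export
zonal_mean <- function(populations, raster) {
  members <- attr(populations, "members")
  r <- attr(populations, "buffer_km")
  xs <- raster_x_centers(raster)
  ys <- raster_y_centers(raster)
  vals <- raster$values
  r2 <- r^2
  value <- numeric(length(members))
  ncell <- integer(length(members))
  flag <- logical(length(members))
  for (k in seq_along(members)) {
    m <- members[[k]]
    mark <- matrix(FALSE, length(ys), length(xs))
    for (i in seq_len(nrow(m))) {
      jx <- which(abs(xs - m[i, 1]) <= r)
      jy <- which(abs(ys - m[i, 2]) <= r)
      if (!length(jx) || !length(jy)) next
      mark[jy, jx] <- mark[jy, jx] |
        (outer((ys[jy] - m[i, 2])^2, (xs[jx] - m[i, 1])^2, `+`) <= r2)
    }
    v <- vals[mark]
    v <- v[!is.na(v)]
    if (length(v)) {
      value[k] <- mean(v)
      ncell[k] <- length(v)
    } else {
      # no interior cell centre: nearest cell, flagged
      cx <- mean(m[, 1]); cy <- mean(m[, 2])
      jx <- which.min(abs(xs - cx)); jy <- which.min(abs(ys - cy))
      value[k] <- vals[jy, jx]
      ncell[k] <- 0L
      flag[k] <- TRUE
    }
  }
  tibble::tibble(pop_id = populations$pop_id, value = value,
                 n_cells = ncell, flag_no_cells = flag)
}

#' Attach the three persistence covariates to a population set
#'
#' Computes zonal means of habitat suitability (`h`), scaled winter
#' precipitation (`w`) and imperviousness (`v`) over each population
#' polygon.  Precipitation is rescaled to `[0, 1]` across the raster
#' *before* zonal averaging.
#'
#' @param populations a `population_set`
#' @param suitability,winter_precip,imperviousness [grid_raster()]s;
#'   suitability and imperviousness already live in `[0, 1]`
#' @return `populations` with columns `h`, `w`, `v`
#' @export
population_covariates <- function(populations, suitability, winter_precip,
                                  imperviousness) {
  populations$h <- zonal_mean(populations, suitability)$value
  populations$w <- zonal_mean(populations, scale_01(winter_precip))$value
  populations$v <- zonal_mean(populations, imperviousness)$value
  populations
}

#' Pairwise Pearson correlations among population covariates
#'
#' @param populations a `population_set` with covariate columns
#' @param vars covariate columns to correlate (default `h`, `w`, `v`)
#' @return long tibble (`var1`, `var2`, `r`, `degenerate`); `r` is NA and
#'   flagged degenerate when either covariate has zero variance
#' @export
covariate_correlations <- function(populations, vars = c("h", "w", "v")) {
  if (nrow(populations) < 3) {
    stop("need at least 3 populations for correlations", call. = FALSE)
  }
  m <- as.matrix(populations[, vars])
  zero_var <- apply(m, 2, function(col) stats::sd(col) == 0)
  cm <- suppressWarnings(stats::cor(m))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[pairs[, 1]],
    var2 = vars[pairs[, 2]],
    r = cm[pairs],
    degenerate = zero_var[pairs[, 1]] | zero_var[pairs[, 2]]
  )
}

#' @export
print.population_set <- function(x, ...) {
  cat(sprintf("<population_set> %d populations, buffer %.2f km\n",
              nrow(x), attr(x, "buffer_km")))
  NextMethod()
}

#' Export a population set to GeoJSON and CSV
#'
#' Writes the attribute table as CSV and the member coordinates as a
#' GeoJSON FeatureCollection of MultiPoint features carrying the buffer
#' radius (the dissolved polygon is the union of discs of that radius
#' around the points).
#'
#' @param populations a `population_set`
#' @param csv_path,geojson_path output paths (either may be NULL)
#' @return invisibly, the population tibble written
#' @export
export_populations <- function(populations, csv_path = NULL,
                               geojson_path = NULL) {
  tab <- tibble::as_tibble(populations)
  if (!is.null(csv_path)) readr::write_csv(tab, csv_path)
  if (!is.null(geojson_path)) {
    proj <- attr(populations, "projection")
    members <- attr(populations, "members")
    feats <- lapply(seq_len(nrow(populations)), function(i) {
      ll <- proj$unproject(members[[i]][, 1], members[[i]][, 2])
      coords <- lapply(seq_len(nrow(ll)), function(k) c(ll[k, 1], ll[k, 2]))
      list(type = "Feature",
           properties = list(pop_id = populations$pop_id[i],
                             buffer_km = attr(populations, "buffer_km")),
           geometry = list(type = "MultiPoint", coordinates = coords))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson_path, auto_unbox = TRUE, digits = 10)
  }
  invisible(tab)
}
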