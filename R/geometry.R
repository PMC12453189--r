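## Minimal planar geometry used throughout the package.  All metric work
## (buffers, areas, centroids, zonal statistics) happens in a spherical
## Albers equal-area projection with kilometre units; occurrence records and
## vector layers arrive in WGS84 longitude/latitude.

EARTH_RADIUS_KM <- 6371.0088

#' Albers equal-area conic projection
#'
#' Spherical Albers equal-area projection used for all metric geometry
#' (buffer-dissolve, areas in km^2, centroids, zonal statistics).  The
#' default parameters are the standard continental-US configuration; the
#' synthetic landscape generator re-centres the projection on its own study
#' extent.
#'
#' @param lon0,lat0 origin (degrees)
#' @param lat1,lat2 standard parallels (degrees)
#' @return an object of class `albers_projection` with `project(lon, lat)`
#'   and `unproject(x, y)` functions mapping degrees to kilometres and back
#' @examples
#' prj <- albers_projection()
#' xy <- prj$project(-84, 30)
#' ll <- prj$unproject(xy[, 1], xy[, 2])
#' @export
albers_projection <- function(lon0 = -96, lat0 = 23, lat1 = 29.5, lat2 = 45.5) {
  d2r <- pi / 180
  R <- EARTH_RADIUS_KM
  n <- (sin(lat1 * d2r) + sin(lat2 * d2r)) / 2
  C <- cos(lat1 * d2r)^2 + 2 * n * sin(lat1 * d2r)
  rho0 <- R / n * sqrt(C - 2 * n * sin(lat0 * d2r))
  project <- function(lon, lat) {
    rho <- R / n * sqrt(C - 2 * n * sin(lat * d2r))
    theta <- n * (lon - lon0) * d2r
    cbind(x = rho * sin(theta), y = rho0 - rho * cos(theta))
  }
  unproject <- function(x, y) {
    rho <- sqrt(x^2 + (rho0 - y)^2)
    theta <- atan2(x, rho0 - y)
    lat <- asin((C - (rho * n / R)^2) / (2 * n)) / d2r
    lon <- lon0 + theta / (n * d2r)
    cbind(lon = lon, lat = lat)
  }
  structure(list(project = project, unproject = unproject,
                 lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2),
            class = "albers_projection")
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param x,y point coordinates (vectors)
#' @param ring two-column matrix of ring vertices (closed or open)
#' @return logical vector; points exactly on an edge may land on either side
#' @export
point_in_ring <- function(x, y, ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) > 1 &&
      isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  n <- nrow(ring)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Distance from points to a polygon ring boundary (planar).
dist_to_ring <- function(x, y, ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) > 1 &&
      isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  n <- nrow(ring)
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- ring[i, 1]; ay <- ring[i, 2]
    bx <- ring[j, 1]; by <- ring[j, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    dd <- (x - (ax + t * vx))^2 + (y - (ay + t * vy))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

#' Construct a set of labelled polygons
#'
#' Lightweight container for vector layers (species range, ecoregions,
#' protected areas, states): one single-ring polygon per row, in WGS84
#' longitude/latitude.
#'
#' @param labels character vector of polygon labels
#' @param rings list of two-column matrices (lon, lat vertices)
#' @param properties optional tibble of extra per-polygon attributes
#' @return a `poly_set` tibble with columns `label` and list-column `ring`
#' @export
poly_set <- function(labels, rings, properties = NULL) {
  stopifnot(length(labels) == length(rings))
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    colnames(r) <- c("lon", "lat")
    r
  })
  out <- tibble::tibble(label = as.character(labels), ring = rings)
  if (!is.null(properties)) out <- dplyr::bind_cols(out, properties)
  class(out) <- c("poly_set", class(out))
  out
}

#' Read polygons from a GeoJSON file
#'
#' Reads a FeatureCollection of Polygon features (outer rings only) into a
#' [poly_set()].  The feature property named by `label_property` becomes the
#' polygon label.
#'
#' @param path GeoJSON file
#' @param label_property property holding the label (default `"name"`)
#' @return a `poly_set`
#' @export
read_geojson_polygons <- function(path, label_property = "name") {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats) || !length(feats)) {
    stop("no features in GeoJSON file: ", path, call. = FALSE)
  }
  labels <- character(0)
  rings <- list()
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) next
    ring <- do.call(rbind, lapply(geom$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    labels <- c(labels, as.character(f$properties[[label_property]] %||% (length(labels) + 1)))
    rings <- c(rings, list(ring))
  }
  poly_set(labels, rings)
}

#' Write polygons to a GeoJSON file
#'
#' @param polys a [poly_set()]
#' @param path output file
#' @param label_property property name for the label
#' @return `path`, invisibly
#' @export
write_geojson_polygons <- function(polys, path, label_property = "name") {
  feats <- lapply(seq_len(nrow(polys)), function(i) {
    ring <- polys$ring[[i]]
    if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
      ring <- rbind(ring, ring[1, ])
    }
    coords <- lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
    props <- list()
    props[[label_property]] <- polys$label[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
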