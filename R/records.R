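## Occurrence-record ingestion and cleaning.  Records are tibbles with
## columns record_id, species, event_date, lon, lat, coord_uncertainty_m,
## observer, source, state; invalid rows are reported, never silently
## dropped.

occ_record_cols <- c("record_id", "species", "event_date", "lon", "lat",
                     "coord_uncertainty_m", "observer", "source", "state")

#' Validate a data frame of occurrence records
#'
#' Checks coordinate bounds, date parseability (dates must not postdate
#' `max_date`) and non-negative coordinate uncertainty.  Valid rows are
#' returned as an `occ_records` tibble; invalid rows are attached as a
#' `problems` attribute with row numbers and reasons.
#'
#' @param df data frame with (at least) `species`, `event_date`, `lon`, `lat`
#' @param max_date latest admissible observation date (default today)
#' @return an `occ_records` tibble; `attr(, "problems")` holds rejected rows
#' @export
as_occ_records <- function(df, max_date = Sys.Date()) {
  df <- tibble::as_tibble(df)
  need <- c("species", "event_date", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (opt in setdiff(occ_record_cols, names(df))) {
    df[[opt]] <- if (opt == "coord_uncertainty_m") NA_real_ else NA_character_
  }
  if (all(is.na(df$record_id)) && nrow(df) > 0) {
    df$record_id <- sprintf("rec_%06d", seq_len(nrow(df)))
  }
  dates <- suppressWarnings(as.Date(df$event_date))
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  unc <- suppressWarnings(as.numeric(df$coord_uncertainty_m))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(dates) & !is.na(df$event_date), "unparseable date")
  reason <- flag(is.na(df$event_date), "missing date")
  reason <- flag(!is.na(dates) & dates > max_date, "date in the future")
  reason <- flag(is.na(lat) | lat < -90 | lat > 90, "latitude outside [-90, 90]")
  reason <- flag(is.na(lon) | lon < -180 | lon > 180, "longitude outside [-180, 180]")
  reason <- flag(!is.na(unc) & unc < 0, "negative coordinate uncertainty")

  bad <- !is.na(reason)
  problems <- tibble::tibble(row = which(bad), reason = reason[bad])
  out <- df[!bad, occ_record_cols]
  out$event_date <- dates[!bad]
  out$lon <- lon[!bad]
  out$lat <- lat[!bad]
  out$coord_uncertainty_m <- unc[!bad]
  class(out) <- c("occ_records", class(out))
  attr(out, "problems") <- problems
  out
}

#' Read occurrence records from a CSV file
#'
#' @param path CSV file with one row per observation
#' @param column_map named character vector mapping canonical field names
#'   (`species`, `event_date`, `lon`, `lat`, `coord_uncertainty_m`,
#'   `observer`, `source`, `state`, `record_id`) to column names in the
#'   file; fields absent from the map use their canonical name when present
#' @param max_date latest admissible observation date
#' @return an `occ_records` tibble (see [as_occ_records()]); malformed rows
#'   are reported in the `problems` attribute
#' @export
read_records <- function(path, column_map = NULL, max_date = Sys.Date()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' (for field '", canon,
             "') not present in ", path, call. = FALSE)
      }
      raw[[canon]] <- raw[[src]]
    }
  }
  need <- c("species", "event_date", "lon", "lat")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("required column(s) absent after mapping: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as_occ_records(raw, max_date = max_date)
}

#' Drop records far outside the species range polygon
#'
#' Retains records inside the range polygon or within `tolerance_km` of its
#' boundary; records further out are treated as georeferencing errors.
#'
#' @param records `occ_records`
#' @param range_polygon a single-ring [poly_set()] row or lon/lat matrix
#' @param tolerance_km boundary tolerance in km (default 10)
#' @param projection an [albers_projection()] for metric distances
#' @return filtered records
#' @export
filter_range <- function(records, range_polygon, tolerance_km = 10,
                         projection = albers_projection()) {
  stopifnot(tolerance_km >= 0)
  ring <- if (inherits(range_polygon, "poly_set")) range_polygon$ring[[1]]
          else as.matrix(range_polygon)
  if (is.null(ring) || nrow(ring) < 3) {
    stop("range polygon is empty or degenerate", call. = FALSE)
  }
  if (nrow(records) == 0) return(records)
  ringp <- projection$project(ring[, 1], ring[, 2])
  pts <- projection$project(records$lon, records$lat)
  inside <- point_in_ring(pts[, 1], pts[, 2], ringp)
  keep <- inside
  if (any(!inside)) {
    d <- dist_to_ring(pts[!inside, 1], pts[!inside, 2], ringp)
    keep[!inside] <- d <= tolerance_km
  }
  records[keep, ]
}

#' Drop records with large location uncertainty
#'
#' Target records use a 5-km ceiling and keep records with no uncertainty
#' estimate; effort (non-target) records use a 2.5-km ceiling and drop
#' missing-uncertainty records.
#'
#' @param records `occ_records`
#' @param max_m maximum allowed uncertainty in metres
#' @param drop_missing drop records with no uncertainty estimate?
#' @return filtered records
#' @export
filter_uncertainty <- function(records, max_m = 5000, drop_missing = FALSE) {
  stopifnot(max_m > 0)
  unc <- records$coord_uncertainty_m
  keep <- ifelse(is.na(unc), !drop_missing, unc <= max_m)
  records[keep, ]
}

#' Remove same-day near-duplicate records
#'
#' Within each observation day, records are clustered by single linkage at
#' `dist_m` (geodesic metres) and one representative is kept per cluster:
#' the member from the highest-priority source when `source_priority` is
#' given, otherwise the earliest row in input order.  Catches the same
#' observation reported to several databases with rounded coordinates.
#'
#' @param records `occ_records`
#' @param dist_m linkage distance in metres (default 10)
#' @param source_priority optional character vector of source names, best
#'   first, used as the within-cluster tie-break
#' @return deduplicated records
#' @export
dedup_target <- function(records, dist_m = 10, source_priority = NULL) {
  stopifnot(dist_m >= 0)
  if (nrow(records) < 2) return(records)
  keep <- logical(nrow(records))
  for (day in split(seq_len(nrow(records)), as.character(records$event_date))) {
    if (length(day) == 1) {
      keep[day] <- TRUE
      next
    }
    pts <- cbind(records$lon[day], records$lat[day])
    dmat <- geosphere::distm(pts)
    edges <- which(dmat <= dist_m & upper.tri(dmat), arr.ind = TRUE)
    comp <- uf_components(length(day), edges)
    for (cl in split(seq_along(day), comp)) {
      pick <- if (!is.null(source_priority)) {
        pr <- match(records$source[day[cl]], source_priority)
        pr[is.na(pr)] <- length(source_priority) + 1L
        cl[order(pr, cl)][1]
      } else {
        cl[1]
      }
      keep[day[pick]] <- TRUE
    }
  }
  records[keep, ]
}

#' Remove duplicate search-effort records
#'
#' Keeps exactly one record per (date, coordinates rounded to 5 decimal
#' places, observer) key, regardless of species: repeated reports from one
#' observer at one place on one day represent a single search event.  When
#' the observer is missing, the key substitutes (source, rounded
#' coordinates) so community-database records without observer ids still
#' collapse to one event per day.
#'
#' @param records `occ_records`
#' @return deduplicated records (first row per key kept)
#' @export
dedup_effort <- function(records) {
  if (nrow(records) == 0) return(records)
  who <- ifelse(is.na(records$observer) | records$observer == "",
                paste0("src:", records$source %||% "", "@",
                       coord_key(records$lon, records$lat)),
                records$observer)
  key <- paste(records$event_date, coord_key(records$lon, records$lat), who,
               sep = "|")
  records[!duplicated(key), ]
}

#' Keep records inside a month-day season window
#'
#' The default window, Nov 1 through Apr 30 inclusive, is the peak activity
#' season during which an observer reporting an indexing species could also
#' have detected the target; it wraps the calendar-year boundary.
#'
#' @param records `occ_records`
#' @param start_month_day,end_month_day `(month, day)` integer pairs
#' @return filtered records
#' @export
filter_season <- function(records, start_month_day = c(11, 1),
                          end_month_day = c(4, 30)) {
  if (nrow(records) == 0) return(records)
  records[month_day_in_window(records$event_date, start_month_day, end_month_day), ]
}

#' Apply regional restrictions to effort species
#'
#' Some effort-indexing species are informative only in part of the study
#' area (their calling seasons overlap the target's only regionally).  Each
#' species in `species_region_map` is either unrestricted (`"all"`) or
#' limited to a set of states; records of unlisted species are dropped.
#' State membership uses the record's `state` field when present, else a
#' point-in-polygon test against `state_polygons`.
#'
#' @param records `occ_records`
#' @param species_region_map named list: species -> `"all"` or character
#'   vector of allowed 2-letter state codes
#' @param state_polygons optional [poly_set()] of state boundaries (labels =
#'   state codes) used when the `state` field is missing
#' @param projection an [albers_projection()]
#' @return filtered records; unresolvable region-restricted records are
#'   dropped and counted in the `dropped_unresolved` attribute
#' @export
filter_nontarget_species <- function(records, species_region_map,
                                     state_polygons = NULL,
                                     projection = albers_projection()) {
  if (nrow(records) == 0) return(records)
  keep <- logical(nrow(records))
  unresolved <- 0L
  state <- records$state
  if (!is.null(state_polygons) && any(is.na(state))) {
    idx <- which(is.na(state))
    pts <- projection$project(records$lon[idx], records$lat[idx])
    for (k in seq_len(nrow(state_polygons))) {
      ring <- projection$project(state_polygons$ring[[k]][, 1],
                                 state_polygons$ring[[k]][, 2])
      inside <- point_in_ring(pts[, 1], pts[, 2], ring)
      state[idx[inside & is.na(state[idx])]] <- state_polygons$label[k]
    }
  }
  for (i in seq_len(nrow(records))) {
    allowed <- species_region_map[[records$species[i]]]
    if (is.null(allowed)) next
    if (identical(allowed, "all")) {
      keep[i] <- TRUE
    } else if (!is.na(state[i])) {
      keep[i] <- state[i] %in% allowed
    } else {
      unresolved <- unresolved + 1L
    }
  }
  out <- records[keep, ]
  attr(out, "dropped_unresolved") <- unresolved
  out
}

#' Clean a stream of target-species records
#'
#' Applies the target cleaning rules in order -- range filter (10-km
#' tolerance), location-uncertainty ceiling (5 km, missing estimates kept),
#' same-day 10-m deduplication -- and attaches a reconciled cleaning report.
#'
#' @param records `occ_records` of the target species
#' @param range_polygon species range polygon ([poly_set()] or matrix)
#' @param range_tolerance_km,max_uncertainty_m,dedup_dist_m rule parameters
#' @param source_priority see [dedup_target()]
#' @param projection an [albers_projection()]
#' @return cleaned records; `attr(, "cleaning_report")` is a tibble with one
#'   row per rule whose drop counts reconcile exactly with input/output sizes
#' @export
clean_target_records <- function(records, range_polygon,
                                 range_tolerance_km = 10,
                                 max_uncertainty_m = 5000,
                                 dedup_dist_m = 10,
                                 source_priority = NULL,
                                 projection = albers_projection()) {
  n0 <- nrow(records)
  r1 <- filter_range(records, range_polygon, range_tolerance_km, projection)
  r2 <- filter_uncertainty(r1, max_uncertainty_m, drop_missing = FALSE)
  r3 <- dedup_target(r2, dedup_dist_m, source_priority)
  report <- tibble::tibble(
    rule = c("out_of_range", "uncertainty", "duplicate"),
    n_dropped = c(n0 - nrow(r1), nrow(r1) - nrow(r2), nrow(r2) - nrow(r3))
  )
  attr(r3, "cleaning_report") <- report
  attr(r3, "n_input") <- n0
  r3
}

#' Clean a stream of effort (non-target) records
#'
#' Applies the effort cleaning rules: season window (Nov 1 - Apr 30),
#' regional species restrictions, location-uncertainty ceiling (2.5 km,
#' missing estimates dropped), and one-event-per-observer-day
#' deduplication.  Target-species detections should be appended afterwards
#' (they are search events too) via [build_effort_matrix()].
#'
#' @inheritParams clean_target_records
#' @param species_region_map,state_polygons see [filter_nontarget_species()]
#' @param season_start,season_end `(month, day)` pairs
#' @param max_uncertainty_m uncertainty ceiling in metres (default 2500)
#' @return cleaned records with a `cleaning_report` attribute
#' @export
clean_effort_records <- function(records, species_region_map,
                                 state_polygons = NULL,
                                 season_start = c(11, 1),
                                 season_end = c(4, 30),
                                 max_uncertainty_m = 2500,
                                 projection = albers_projection()) {
  n0 <- nrow(records)
  r1 <- filter_season(records, season_start, season_end)
  r2 <- filter_nontarget_species(r1, species_region_map, state_polygons,
                                 projection)
  r3 <- filter_uncertainty(r2, max_uncertainty_m, drop_missing = TRUE)
  r4 <- dedup_effort(r3)
  report <- tibble::tibble(
    rule = c("season", "species_region", "uncertainty", "duplicate_effort"),
    n_dropped = c(n0 - nrow(r1), nrow(r1) - nrow(r2),
                  nrow(r2) - nrow(r3), nrow(r3) - nrow(r4))
  )
  attr(r4, "cleaning_report") <- report
  attr(r4, "n_input") <- n0
  r4
}

#' Summarize a cleaning run
#'
#' @param records output of [clean_target_records()] or
#'   [clean_effort_records()]
#' @return tibble of per-rule drop counts plus input/retained totals;
#'   `n_dropped` always sums to `n_input - n_retained`
#' @export
cleaning_report <- function(records) {
  rep <- attr(records, "cleaning_report")
  if (is.null(rep)) stop("records carry no cleaning report", call. = FALSE)
  dplyr::bind_rows(
    rep,
    tibble::tibble(rule = "retained", n_dropped = NA_integer_)
  ) |>
    dplyr::mutate(
      n_input = attr(records, "n_input"),
      n_retained = nrow(records)
    )
}
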