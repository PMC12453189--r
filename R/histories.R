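## Population x year detection and effort histories.  The detection matrix
## y[i, t] records whether the target species was observed in population i
## during year t; the effort matrix counts observer-days (one observer
## reporting any indexing species -- or the target itself -- inside a
## population polygon on one date).

#' Build the population-by-year detection matrix
#'
#' `y[i, t] = 1` iff at least one target record falls in population `i`
#' during calendar year `t`.  Records dated before the start year do not
#' enter `y`; they set the `known_before_start` flag (such populations are
#' assumed present-but-undetected at the start of the modeled period).
#'
#' @param records cleaned target `occ_records`
#' @param populations a `population_set` delineated from these records
#' @param year_range `c(start, end)` calendar years (default 1950-2024)
#' @param season_year_offset if `TRUE`, November and December observations
#'   are attributed to the following (breeding-season) year
#' @return a `detection_matrix`: list with binary matrix `y` (pop x year),
#'   `first_detection_year`, `last_detection_year` (calendar, NA when never
#'   detected in range), `last_record_year` (any date), `known_before_start`,
#'   `L` (index of last detection, 1 for populations with all-zero rows) and
#'   `years`
#' @export
build_detection_matrix <- function(records, populations,
                                   year_range = c(1950, 2024),
                                   season_year_offset = FALSE) {
  years <- seq(year_range[1], year_range[2])
  proj <- attr(populations, "projection")
  xy <- proj$project(records$lon, records$lat)
  pop <- assign_to_populations(xy, populations)
  if (any(is.na(pop))) {
    stop(sum(is.na(pop)), " record(s) fall outside every population; ",
         "delineate populations from the same cleaned records", call. = FALSE)
  }
  yr <- as.integer(format(records$event_date, "%Y"))
  if (season_year_offset) {
    mo <- as.integer(format(records$event_date, "%m"))
    yr <- yr + (mo >= 11L)
  }
  n <- nrow(populations)
  y <- matrix(0L, n, length(years),
              dimnames = list(populations$pop_id, years))
  in_range <- yr >= year_range[1] & yr <= year_range[2]
  if (any(in_range)) {
    y[cbind(pop[in_range], match(yr[in_range], years))] <- 1L
  }
  first_det <- unname(apply(y, 1, function(r)
    if (any(r > 0)) years[which(r > 0)[1]] else NA_integer_))
  last_det <- unname(apply(y, 1, function(r)
    if (any(r > 0)) years[max(which(r > 0))] else NA_integer_))
  last_rec <- vapply(seq_len(n), function(i) {
    yy <- yr[pop == i]
    if (length(yy)) max(yy) else NA_integer_
  }, integer(1))
  known_before <- vapply(seq_len(n), function(i) {
    any(yr[pop == i] < year_range[1])
  }, logical(1))
  L <- ifelse(is.na(last_det), 1L, match(last_det, years))
  structure(list(y = y, years = years,
                 first_detection_year = first_det,
                 last_detection_year = last_det,
                 last_record_year = last_rec,
                 known_before_start = known_before,
                 L = as.integer(L)),
            class = "detection_matrix")
}

#' Build the population-by-year search-effort matrix
#'
#' Counts observer-days per population-year: the number of distinct
#' (date, observer) pairs among deduplicated search events (non-target
#' detections plus target detections, which are search events too) that
#' fall inside the population polygon.  A scaled copy is attached because
#' the detection model uses effort as a unitless covariate.
#'
#' @param events deduplicated `occ_records` of all search events (output of
#'   [dedup_effort()] on the combined non-target + target stream)
#' @param populations a `population_set`
#' @param year_range `c(start, end)` calendar years
#' @param scaling `"zscore"` (default; `(e - mean) / sd` over all cells),
#'   `"minmax"`, or `"none"`
#' @param season_year_offset as in [build_detection_matrix()]
#' @return an `effort_matrix`: list with integer `e_raw`, numeric `e`
#'   (scaled), `scaling` constants, `years`, and `n_events_outside` (events
#'   falling in no population, excluded)
#' @export
build_effort_matrix <- function(events, populations,
                                year_range = c(1950, 2024),
                                scaling = c("zscore", "minmax", "none"),
                                season_year_offset = FALSE) {
  scaling <- match.arg(scaling)
  years <- seq(year_range[1], year_range[2])
  proj <- attr(populations, "projection")
  n <- nrow(populations)
  e_raw <- matrix(0L, n, length(years),
                  dimnames = list(populations$pop_id, years))
  outside <- 0L
  if (nrow(events) > 0) {
    xy <- proj$project(events$lon, events$lat)
    pop <- assign_to_populations(xy, populations)
    outside <- sum(is.na(pop))
    yr <- as.integer(format(events$event_date, "%Y"))
    if (season_year_offset) {
      mo <- as.integer(format(events$event_date, "%m"))
      yr <- yr + (mo >= 11L)
    }
    who <- ifelse(is.na(events$observer) | events$observer == "",
                  paste0("src:", events$source, "@",
                         coord_key(events$lon, events$lat)),
                  events$observer)
    keep <- !is.na(pop) & yr >= year_range[1] & yr <= year_range[2]
    if (any(keep)) {
      key <- paste(pop[keep], yr[keep], events$event_date[keep], who[keep],
                   sep = "|")
      uniq <- !duplicated(key)
      tab <- table(factor(pop[keep][uniq], levels = seq_len(n)),
                   factor(yr[keep][uniq], levels = years))
      e_raw[] <- as.integer(tab)
    }
  }
  sc <- switch(scaling,
    zscore = {
      mu <- mean(e_raw)
      sdv <- stats::sd(e_raw)
      if (sdv == 0) sdv <- 1
      list(name = "zscore", center = mu, scale = sdv)
    },
    minmax = {
      rng <- range(e_raw)
      list(name = "minmax", center = rng[1],
           scale = max(rng[2] - rng[1], 1))
    },
    none = list(name = "none", center = 0, scale = 1)
  )
  e <- (e_raw - sc$center) / sc$scale
  structure(list(e_raw = e_raw, e = e, scaling = sc, years = years,
                 n_events_outside = outside),
            class = "effort_matrix")
}

#' Co-occurrence of candidate effort species with the target
#'
#' For call-survey data grouped into survey events (rounded coordinates +
#' date), computes for each candidate species the fraction of
#' target-present events at which that species was also recorded.  Used to
#' choose which non-target species index search effort; the choice itself
#' is configuration, not automated.
#'
#' @param records `occ_records` from call surveys
#' @param target_species name of the target species in `records$species`
#' @param coord_digits coordinate rounding that defines a survey site
#' @return tibble (`species`, `n_cooccur`, `n_target_events`, `fraction`)
#'   sorted by decreasing fraction
#' @export
cooccurrence_table <- function(records, target_species, coord_digits = 3) {
  event <- paste(coord_key(records$lon, records$lat, coord_digits),
                 records$event_date, sep = "|")
  by_event <- split(records$species, event)
  target_events <- Filter(function(sp) target_species %in% sp, by_event)
  n_t <- length(target_events)
  if (n_t == 0) {
    stop("no survey events with the target species present", call. = FALSE)
  }
  others <- setdiff(unique(records$species), target_species)
  counts <- vapply(others, function(sp) {
    sum(vapply(target_events, function(e) sp %in% e, logical(1)))
  }, integer(1))
  out <- tibble::tibble(species = others, n_cooccur = unname(counts),
                        n_target_events = n_t,
                        fraction = unname(counts) / n_t)
  out[order(-out$fraction, out$species), ]
}

#' Export detection/effort matrices as CSV with a JSON sidecar
#'
#' @param det a `detection_matrix`
#' @param eff an `effort_matrix`
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
export_histories <- function(det, eff, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- function(m) {
    tibble::as_tibble(as.data.frame(m), rownames = "pop_id")
  }
  p1 <- file.path(dir, "detections.csv")
  p2 <- file.path(dir, "effort_raw.csv")
  p3 <- file.path(dir, "effort_scaled.csv")
  p4 <- file.path(dir, "histories_meta.json")
  readr::write_csv(wide(det$y), p1)
  readr::write_csv(wide(eff$e_raw), p2)
  readr::write_csv(wide(eff$e), p3)
  jsonlite::write_json(
    list(years = det$years, scaling = eff$scaling,
         n_events_outside = eff$n_events_outside,
         last_detection_year = as.list(setNames(det$last_detection_year,
                                                rownames(det$y)))),
    p4, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4))
}
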