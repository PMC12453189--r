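## Post-model summaries: grouped persistence tables, persistence-category
## histograms, protected-area comparisons, correlation with last
## observation, buffer-size sensitivity, and the end-to-end pipeline
## driver.

#' Grouped persistence summaries
#'
#' Per-group sample size, mean and SD of the posterior persistence means,
#' and the proportion of populations below/above the conventional
#' thresholds.  Threshold comparisons are strict (`< 0.25`, `< 0.5`,
#' `> 0.75`, `> 0.9`), so a population sitting exactly on a threshold
#' counts in neither tail.
#'
#' @param persistence tibble with `persist_mean` and the grouping column
#' @param grouping name of the grouping column (e.g. `"state"`,
#'   `"ecoregion"`, `"protected"`, `"protected_binary"`)
#' @return tibble with one row per group (empty groups reported with
#'   `n = 0`) plus an overall `"(all)"` row
#' @export
summarize_groups <- function(persistence, grouping) {
  if (!grouping %in% names(persistence)) {
    stop("grouping column '", grouping, "' not present", call. = FALSE)
  }
  g <- persistence[[grouping]]
  one <- function(v) {
    tibble::tibble(
      n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_,
      prop_below_0.25 = if (length(v)) mean(v < 0.25) else NA_real_,
      prop_below_0.5 = if (length(v)) mean(v < 0.5) else NA_real_,
      prop_above_0.75 = if (length(v)) mean(v > 0.75) else NA_real_,
      prop_above_0.9 = if (length(v)) mean(v > 0.9) else NA_real_
    )
  }
  groups <- sort(unique(as.character(g)))
  out <- dplyr::bind_rows(lapply(groups, function(grp) {
    dplyr::bind_cols(tibble::tibble(group = grp),
                     one(persistence$persist_mean[g == grp]))
  }))
  dplyr::bind_rows(out,
                   dplyr::bind_cols(tibble::tibble(group = "(all)"),
                                    one(persistence$persist_mean)))
}

#' Histogram counts of persistence categories
#'
#' @param values persistence probabilities in `[0, 1]`
#' @param bin_edges strictly increasing edges covering `[0, 1]`; bins are
#'   `[e_k, e_{k+1})`, with the final bin closed on the right
#' @return named integer vector of counts (sums to `length(values)`)
#' @export
categorize <- function(values, bin_edges = c(0, 0.25, 0.5, 0.75, 0.9, 1)) {
  stopifnot(all(diff(bin_edges) > 0), bin_edges[1] <= 0,
            bin_edges[length(bin_edges)] >= 1)
  if (any(values < 0 | values > 1)) {
    stop("persistence values must lie in [0, 1]", call. = FALSE)
  }
  bins <- cut(values, bin_edges, right = FALSE, include.lowest = FALSE)
  # right = FALSE makes bins [a, b); fold values equal to the top edge
  # into the last bin
  counts <- table(bins)
  counts[length(counts)] <- counts[length(counts)] +
    sum(values == bin_edges[length(bin_edges)])
  n <- as.integer(counts)
  names(n) <- sprintf("[%g,%g%s", bin_edges[-length(bin_edges)],
                      bin_edges[-1],
                      c(rep(")", length(bin_edges) - 2), "]"))
  n
}

#' Welch's unequal-variance t-test
#'
#' Direct implementation of the Welch statistic with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value; used to
#' compare mean persistence between protected and unprotected populations.
#'
#' @param group_a,group_b numeric vectors (each `n >= 2`)
#' @return tibble (`t`, `df`, `p`, `mean_a`, `mean_b`)
#' @export
welch_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  va <- var(group_a); vb <- var(group_b)
  if (va == 0 && vb == 0) {
    stop("both groups have zero variance; t undefined", call. = FALSE)
  }
  se2 <- va / na + vb / nb
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df),
                 mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Correlation of persistence with the year of last observation
#'
#' Pearson correlation between posterior persistence means and the
#' calendar year of the most recent target observation in each
#' population (any date, including pre-start records).
#'
#' @param persistence persistence tibble from [run_mcmc()] (columns
#'   `persist_mean`, `last_record_year`)
#' @return list with `r` and `n`; `r` is NA (flagged) when last-observation
#'   years are constant
#' @export
persistence_vs_last_obs <- function(persistence) {
  yrs <- persistence$last_record_year
  keep <- !is.na(yrs)
  if (sd(yrs[keep]) == 0) {
    warning("last-observation years are constant; correlation undefined")
    return(list(r = NA_real_, n = sum(keep), degenerate = TRUE))
  }
  list(r = cor(persistence$persist_mean[keep], yrs[keep]),
       n = sum(keep), degenerate = FALSE)
}

#' Buffer-size sensitivity analysis
#'
#' Reruns delineation, histories and the model for each buffer radius and
#' collects population counts, parameter summaries and per-population
#' persistence tables, so conclusions can be checked for robustness to the
#' buffer choice.
#'
#' @param config pipeline config (list or path to YAML); see
#'   [run_pipeline()]
#' @param buffer_list numeric vector of buffer radii in km
#' @return list with `summary` tibble (one row per buffer x parameter) and
#'   `persistence` (named list of per-buffer persistence tibbles)
#' @export
sensitivity_run <- function(config, buffer_list = c(1, 2.5, 5)) {
  stopifnot(all(buffer_list > 0))
  summaries <- vector("list", length(buffer_list))
  tables <- vector("list", length(buffer_list))
  for (i in seq_along(buffer_list)) {
    b <- buffer_list[i]
    res <- run_pipeline(config, buffer_km = b, write_outputs = FALSE)
    summaries[[i]] <- dplyr::bind_cols(
      tibble::tibble(buffer_km = b, n_populations = nrow(res$populations)),
      summarize_posterior(res$fit))
    tables[[i]] <- res$fit$persistence
  }
  names(tables) <- make.unique(sprintf("buffer_%g", buffer_list))
  list(summary = dplyr::bind_rows(summaries), persistence = tables)
}

#' Run the full pipeline on a synthetic-bundle config
#'
#' Executes clean -> delineate -> covariates -> histories -> model ->
#' report on a dataset laid out as written by [fixture_bundle()], and
#' (optionally) writes every artifact, the resolved config and the seed to
#' an output directory.  Identical config and seed give byte-identical
#' outputs.
#'
#' @param config list or path to a YAML file (see [fixture_bundle()] for
#'   the schema)
#' @param outdir output directory (default `file.path(config$dir, "run")`)
#' @param buffer_km optional override of the buffer radius
#' @param write_outputs write artifacts to `outdir`?
#' @return invisible list: `records`, `populations`, `det`, `eff`, `fit`,
#'   `summaries`, `config`
#' @export
run_pipeline <- function(config, outdir = NULL, buffer_km = NULL,
                         write_outputs = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("dir", "seed", "buffer_km", "year_range", "paths")
  miss <- setdiff(required, names(config))
  if (length(miss)) {
    stop("config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pth <- function(key) {
    p <- config$paths[[key]]
    if (is.null(p)) stop("config$paths$", key, " missing", call. = FALSE)
    fp <- file.path(config$dir, p)
    if (!file.exists(fp)) stop("input not found: ", fp, call. = FALSE)
    fp
  }
  buffer_km <- buffer_km %||% config$buffer_km
  year_range <- as.numeric(config$year_range)
  prj <- do.call(albers_projection, config$projection)

  ## stage: ingest + clean
  target_raw <- read_records(pth("target_records"))
  effort_raw <- read_records(pth("effort_records"))
  range_poly <- read_geojson_polygons(pth("range"))
  states <- read_geojson_polygons(pth("states"))
  target <- clean_target_records(target_raw, range_poly, projection = prj)
  effort_map <- lapply(config$effort_species, function(x) unlist(x))
  effort <- clean_effort_records(effort_raw, effort_map,
                                 state_polygons = states, projection = prj)

  ## stage: delineate + covariates
  pops <- delineate_populations(target, buffer_km = buffer_km,
                                projection = prj)
  ecoregions <- read_geojson_polygons(pth("ecoregions"))
  pops <- assign_ecoregion(pops, ecoregions)
  protected <- read_geojson_polygons(pth("protected"))
  pops <- assign_protected(pops, protected,
                           unlist(config$protected_categories))
  state_lab <- assign_ecoregion(pops, states)$ecoregion  # same centroid rule
  pops$state <- state_lab
  suit <- read_ascii_grid(pth("suitability"))
  imp <- read_ascii_grid(pth("impervious"))
  pfiles <- list.files(pth("precip_dir"), pattern = "^precip_.*\\.asc$",
                       full.names = TRUE)
  monthly <- lapply(pfiles, read_ascii_grid)
  names(monthly) <- sub("^precip_(.*)\\.asc$", "\\1", basename(pfiles))
  pyears <- seq(config$precip_years[[1]], config$precip_years[[2]])
  winter <- winter_precip_raster(monthly, pyears)
  pops <- population_covariates(pops, suit, winter, imp)

  ## stage: histories
  det <- build_detection_matrix(target, pops, year_range)
  events <- dedup_effort(dplyr::bind_rows(tibble::as_tibble(effort),
                                          tibble::as_tibble(target)))
  eff <- build_effort_matrix(events, pops, year_range)

  ## stage: model
  m <- config$model %||% list()
  spec <- model_spec(chains = m$chains %||% 3,
                     iterations = m$iterations %||% 6000,
                     burn_in = m$burn_in %||% 3000,
                     thin = m$thin %||% 3,
                     prior_sd = m$prior_sd %||% 10,
                     t_ref = config$t_ref %||% round(mean(year_range)),
                     seed = config$seed)
  covs <- tibble::as_tibble(pops)[, c("pop_id", "ecoregion", "h", "w", "v")]
  fit <- run_mcmc(det, eff, covs, spec)

  ## stage: report
  persistence <- dplyr::left_join(
    fit$persistence,
    tibble::as_tibble(pops)[, c("pop_id", "ecoregion", "state", "protected")],
    by = "pop_id")
  persistence$protected_binary <- ifelse(persistence$protected == "none",
                                         "unprotected", "protected")
  summaries <- list(
    by_state = summarize_groups(persistence, "state"),
    by_ecoregion = summarize_groups(persistence, "ecoregion"),
    by_protected = summarize_groups(persistence, "protected"),
    by_protected_binary = summarize_groups(persistence, "protected_binary"),
    categories = categorize(persistence$persist_mean),
    rhat = gelman_rubin(fit),
    correlations = covariate_correlations(pops),
    last_obs = persistence_vs_last_obs(fit$persistence)
  )
  pa <- persistence$persist_mean[persistence$protected_binary == "protected"]
  pb <- persistence$persist_mean[persistence$protected_binary == "unprotected"]
  if (length(pa) >= 2 && length(pb) >= 2) {
    summaries$protected_test <- welch_t(pa, pb)
  }

  if (write_outputs) {
    outdir <- outdir %||% file.path(config$dir, "run")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cleaning_report(target),
                     file.path(outdir, "cleaning_target.csv"))
    readr::write_csv(cleaning_report(effort),
                     file.path(outdir, "cleaning_effort.csv"))
    export_populations(pops, csv_path = file.path(outdir, "populations.csv"),
                       geojson_path = file.path(outdir, "populations.geojson"))
    export_histories(det, eff, outdir)
    readr::write_csv(tibble::as_tibble(as.data.frame(fit$draws)),
                     file.path(outdir, "posterior_draws.csv"))
    readr::write_csv(persistence, file.path(outdir, "persistence.csv"))
    readr::write_csv(summarize_posterior(fit),
                     file.path(outdir, "parameters.csv"))
    readr::write_csv(summaries$rhat, file.path(outdir, "rhat.csv"))
    for (nm in c("by_state", "by_ecoregion", "by_protected",
                 "by_protected_binary")) {
      readr::write_csv(summaries[[nm]],
                       file.path(outdir, paste0("summary_", nm, ".csv")))
    }
    jsonlite::write_json(
      list(seed = config$seed, buffer_km = buffer_km,
           year_range = year_range,
           n_populations = nrow(pops),
           categories = as.list(summaries$categories),
           last_obs_r = summaries$last_obs$r,
           config = config),
      file.path(outdir, "run_meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(records = list(target = target, effort = effort),
                 populations = pops, det = det, eff = eff, fit = fit,
                 persistence = persistence, summaries = summaries,
                 config = config))
}
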