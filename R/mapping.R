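#' Areal apportionment of a parent population to a unit
#'
#' A mapping unit inherits the share of its parent census area's
#' population proportional to the share of the parent's area it covers:
#' for a 2 km2 parent with 500 residents split into two 1 km2 units, each
#' unit is assigned 250 people. Values stay fractional; rounding, if any,
#' happens only at final reporting.
#'
#' @param parent_population persons in the parent area.
#' @param parent_area parent area (km2), positive.
#' @param unit_area unit area (km2), positive and at most the parent area.
#' @return apportioned persons (real-valued). All arguments vectorise.
#' @export
apportion_population <- function(parent_population, parent_area, unit_area) {
  if (any(parent_area <= 0))
    stop_input("apportion_population: parent_area must be positive")
  if (any(unit_area <= 0))
    stop_input("apportion_population: unit_area must be positive")
  if (any(unit_area > parent_area * (1 + 1e-9)))
    stop_input("apportion_population: unit_area exceeds parent_area")
  parent_population * unit_area / parent_area
}

#' Per-unit apportioned populations for a unit table
#' @param units data.frame with `parent_population`, `parent_area_km2`,
#'   `area_km2`.
#' @return numeric vector of unit populations, aligned with `units`.
#' @export
unit_populations <- function(units) {
  apportion_population(units$parent_population, units$parent_area_km2,
                       units$area_km2)
}

#' Classify every unit at every threshold
#'
#' Applies each threshold's fitted model to the full unit table, yielding
#' one complete vulnerability map per threshold (classes "high", "low" or
#' "INELIGIBLE" for units whose categorical covariates carry levels unseen
#' in training). The high fraction is expected to shrink as the threshold
#' grows; because per-threshold models are independent the predictions
#' need not nest exactly, so a violation of the average monotone trend
#' raises a warning, not an error.
#'
#' @param models named list of fitted [brf_fit()] models, names =
#'   thresholds.
#' @param units data.frame of units carrying the models' covariates.
#' @return long data.frame with `unit_id`, `threshold`, `class`.
#' @export
build_threshold_maps <- function(models, units) {
  thresholds <- as.numeric(names(models))
  if (anyNA(thresholds))
    stop_input("build_threshold_maps: model list names must be thresholds")
  maps <- do.call(rbind, lapply(seq_along(models), function(i) {
    data.frame(unit_id = units$unit_id, threshold = thresholds[i],
               class = predict(models[[i]], units),
               stringsAsFactors = FALSE)
  }))
  frac_high <- vapply(split(maps$class, maps$threshold),
                      function(cl) mean(cl == "high"), numeric(1))
  frac_high <- frac_high[order(as.numeric(names(frac_high)))]
  if (is.unsorted(rev(frac_high)) && any(diff(frac_high) > 0.02))
    warning("high-vulnerability fraction is not non-increasing in threshold")
  maps
}

#' Regional summaries of vulnerability and population at risk
#'
#' For every region and threshold: the area-weighted fraction of eligible
#' units classified high, and the apportioned population living in high,
#' low and ineligible units. Populations stay fractional so they conserve
#' exactly under aggregation.
#'
#' @param maps long map data.frame from [build_threshold_maps()].
#' @param units data.frame with `unit_id`, `region_id`, `area_km2`,
#'   `parent_area_km2`, `parent_population`.
#' @return data.frame with one row per region x threshold: `region_id`,
#'   `threshold`, `fraction_units_high`, `population_high`,
#'   `population_low`, `population_ineligible`.
#' @export
summarize_regions <- function(maps, units) {
  if (!all(maps$unit_id %in% units$unit_id))
    stop_input("summarize_regions: map refers to unknown units")
  if (anyNA(units$region_id) || any(!nzchar(units$region_id)))
    stop_input("summarize_regions: every unit needs a region")
  idx <- match(maps$unit_id, units$unit_id)
  df <- data.frame(region_id = units$region_id[idx],
                   threshold = maps$threshold,
                   class = maps$class,
                   area = units$area_km2[idx],
                   population = unit_populations(units)[idx],
                   stringsAsFactors = FALSE)
  parts <- split(df, list(df$region_id, df$threshold), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    eligible <- p$class != "INELIGIBLE"
    frac <- if (any(eligible)) {
      sum(p$area[eligible & p$class == "high"]) / sum(p$area[eligible])
    } else NA_real_
    data.frame(region_id = p$region_id[1], threshold = p$threshold[1],
               fraction_units_high = frac,
               population_high = sum(p$population[p$class == "high"]),
               population_low = sum(p$population[p$class == "low"]),
               population_ineligible = sum(p$population[p$class == "INELIGIBLE"]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$threshold, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold change in the population classified high between two thresholds
#'
#' @param summaries data.frame from [summarize_regions()].
#' @param t_from,t_to thresholds present in `summaries`; the returned
#'   ratio is total `population_high` at `t_to` over that at `t_from`.
#' @return a single ratio.
#' @export
population_fold_change <- function(summaries, t_from, t_to) {
  pop_at <- function(t) {
    rows <- summaries$threshold == t
    if (!any(rows))
      stop_input("population_fold_change: threshold ", t, " not present")
    sum(summaries$population_high[rows])
  }
  denom <- pop_at(t_from)
  if (denom == 0)
    stop_input("population_fold_change: no population classified high at ",
               t_from)
  pop_at(t_to) / denom
}
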