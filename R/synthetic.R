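#' Configuration for the synthetic study generator
#'
#' Builds the parameter list that drives [synthesize_study()] and the
#' individual `generate_*()` stages. The defaults describe a desk-scale
#' province: 800 parent census areas split into roughly 2,000 mapping units
#' over six bedrock geology classes, about a quarter of units carrying
#' indoor radon measurements, an 83-health-area smoking surface, and a
#' 16-year mortality record (1998 onwards) whose lung cancer fraction
#' responds to the latent radon stratum, area smoking class, sex and
#' calendar year through a logistic model with odds-ratio effects.
#'
#' @param n_parent_areas number of parent census areas.
#' @param mean_units_per_parent mean mapping units per parent (>= 1); unit
#'   counts are `1 + Poisson(mean - 1)`.
#' @param n_covariates_categorical number of categorical covariates
#'   generated in addition to the geology class itself.
#' @param n_covariates_continuous number of continuous covariates; the last
#'   one is always pure noise so classifiers can be probed for robustness.
#' @param geology_gm named vector of geometric mean indoor radon
#'   concentrations (Bq/m3) per geology class.
#' @param geology_gsd named vector of geometric standard deviations
#'   (dimensionless, > 1) per geology class; names must match `geology_gm`.
#' @param measured_fraction overall fraction of units receiving any
#'   measurements; sampling is weighted towards high-GM geology, emulating
#'   surveys that oversample areas with known high ambient radiation.
#' @param measurements_per_unit_mean Poisson mean for the number of
#'   measurements in a measured unit (truncated to >= 1); 0 disables
#'   measurement generation.
#' @param population_per_parent_mean Poisson mean of a parent area's
#'   population (census dissemination areas hold roughly 400-700 people).
#' @param n_years,first_year study window for mortality records.
#' @param n_health_areas number of health administration areas carrying a
#'   smoking prevalence estimate.
#' @param n_regions number of economic regions; geology composition shifts
#'   towards radon-prone classes with increasing region index, so the last
#'   region is the known radon-prone one.
#' @param smoking_prevalence_range range of uniform smoking prevalences.
#' @param lung_base_rate baseline probability that a natural death is lung
#'   cancer (reference stratum: true-low radon, lower smoking, female).
#' @param lung_effect_radon,lung_effect_smoking,sex_effect odds ratios on
#'   the lung cancer fraction for true-high radon stratum, higher-smoking
#'   area, and male sex.
#' @param year_trend_ratio odds ratio applied across the full study window
#'   (1 = no temporal trend).
#' @param truth_threshold latent 95th percentile concentration (Bq/m3) at
#'   or above which a unit belongs to the true-high radon stratum.
#' @param deaths_per_unit_year mean natural deaths per unit per year for a
#'   unit of average population.
#' @param external_fraction fraction of records given external causes of
#'   death (ICD-10 first letter T-Y) to exercise the cause filters.
#' @param under20_fraction fraction of records aged under 20, likewise for
#'   filter testing.
#' @param seed integer seed; each generator stage derives its own
#'   substream from it, so a fixed seed reproduces the study bit for bit.
#' @return a list of class `radon_generator_config`.
#' @export
generator_config <- function(n_parent_areas = 800,
                             mean_units_per_parent = 2.5,
                             n_covariates_categorical = 7,
                             n_covariates_continuous = 5,
                             geology_gm = c(alluvial = 15, sedimentary = 25,
                                            volcanic = 40, metamorphic = 65,
                                            intrusive = 105, karst = 170),
                             geology_gsd = c(alluvial = 2.2, sedimentary = 2.5,
                                             volcanic = 2.8, metamorphic = 2.8,
                                             intrusive = 3.0, karst = 3.2),
                             measured_fraction = 0.25,
                             measurements_per_unit_mean = 4,
                             population_per_parent_mean = 550,
                             n_years = 16,
                             first_year = 1998,
                             n_health_areas = 83,
                             n_regions = 8,
                             smoking_prevalence_range = c(0.08, 0.25),
                             lung_base_rate = 0.075,
                             lung_effect_radon = 1.5,
                             lung_effect_smoking = 1.3,
                             sex_effect = 1.2,
                             year_trend_ratio = 1,
                             truth_threshold = 200,
                             deaths_per_unit_year = 6.5,
                             external_fraction = 0.05,
                             under20_fraction = 0.02,
                             seed = NULL) {
  config <- list(
    n_parent_areas = n_parent_areas,
    mean_units_per_parent = mean_units_per_parent,
    n_covariates_categorical = n_covariates_categorical,
    n_covariates_continuous = n_covariates_continuous,
    geology_gm = geology_gm, geology_gsd = geology_gsd,
    measured_fraction = measured_fraction,
    measurements_per_unit_mean = measurements_per_unit_mean,
    population_per_parent_mean = population_per_parent_mean,
    n_years = n_years, first_year = first_year,
    n_health_areas = n_health_areas, n_regions = n_regions,
    smoking_prevalence_range = smoking_prevalence_range,
    lung_base_rate = lung_base_rate,
    lung_effect_radon = lung_effect_radon,
    lung_effect_smoking = lung_effect_smoking,
    sex_effect = sex_effect,
    year_trend_ratio = year_trend_ratio,
    truth_threshold = truth_threshold,
    deaths_per_unit_year = deaths_per_unit_year,
    external_fraction = external_fraction,
    under20_fraction = under20_fraction,
    seed = seed)
  validate_generator_config(config)
  class(config) <- "radon_generator_config"
  config
}

validate_generator_config <- function(config) {
  counts <- c("n_parent_areas", "n_covariates_continuous", "n_years",
              "n_health_areas", "n_regions")
  for (f in counts) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1 ||
        config[[f]] < 1 || config[[f]] != round(config[[f]]))
      stop_input("generator config: '", f, "' must be a count >= 1")
  }
  if (config$n_covariates_categorical < 0)
    stop_input("generator config: 'n_covariates_categorical' must be >= 0")
  if (config$mean_units_per_parent < 1)
    stop_input("generator config: 'mean_units_per_parent' must be >= 1")
  if (is.null(names(config$geology_gm)) ||
      !identical(sort(names(config$geology_gm)), sort(names(config$geology_gsd))))
    stop_input("generator config: geology_gm and geology_gsd must share class names")
  if (any(config$geology_gm <= 0))
    stop_input("generator config: geometric means must be positive")
  if (any(config$geology_gsd <= 1))
    stop_input("generator config: geometric standard deviations must exceed 1")
  fracs <- c(config$measured_fraction, config$lung_base_rate,
             config$external_fraction, config$under20_fraction,
             config$smoking_prevalence_range)
  if (any(fracs < 0 | fracs > 1))
    stop_input("generator config: fractions must lie in [0, 1]")
  if (config$measurements_per_unit_mean < 0)
    stop_input("generator config: 'measurements_per_unit_mean' must be >= 0")
  if (config$lung_effect_radon < 1 || config$lung_effect_smoking < 1)
    stop_input("generator config: lung effect ratios must be >= 1")
  if (config$sex_effect <= 0 || config$year_trend_ratio <= 0)
    stop_input("generator config: ratio effects must be positive")
  invisible(config)
}

# Zero-truncated Poisson draw via inverse CDF, vectorised and seed-stable.
rpois_truncated <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  u <- runif(n, dpois(0, lambda), 1)
  qpois(u, lambda)
}

#' Generate synthetic mapping units
#'
#' Splits each parent census area into one or more mapping units (the
#' intersection of census geography with bedrock geology), sampling a
#' geology class per unit, categorical covariates correlated with geology,
#' continuous covariates that are linear-plus-noise in log latent radon
#' (with one pure-noise column), and latent per-unit radon distribution
#' parameters. Parents are laid out on a square grid so that region index
#' corresponds to a spatial stripe; geology composition shifts towards
#' radon-prone classes with region index.
#'
#' @param config a [generator_config()].
#' @return a data.frame with one row per unit: identifiers
#'   (`unit_id`, `parent_id`, `region_id`, `health_area_id`), geometry
#'   (`area_km2`, `parent_area_km2`, `centroid_x`, `centroid_y`),
#'   `parent_population`, the `geology` class, covariates `cat_*` /
#'   `cont_*`, and latent truth columns `true_gm`, `true_gsd`.
#' @export
generate_units <- function(config) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(substream_seed(config$seed, 1L))

  n_par <- config$n_parent_areas
  geo_classes <- names(config$geology_gm)
  n_geo <- length(geo_classes)

  # parents on a square grid; index stripes define regions and health areas
  ncol_grid <- ceiling(sqrt(n_par))
  parent <- data.frame(
    parent_id = sprintf("P%04d", seq_len(n_par)),
    gx = (seq_len(n_par) - 1) %% ncol_grid,
    gy = (seq_len(n_par) - 1) %/% ncol_grid,
    area_km2 = rlnorm(n_par, log(10), 0.5),
    population = rpois(n_par, config$population_per_parent_mean),
    stringsAsFactors = FALSE)
  per_region <- ceiling(n_par / config$n_regions)
  per_ha <- ceiling(n_par / config$n_health_areas)
  parent$region_idx <- pmin((seq_len(n_par) - 1) %/% per_region + 1,
                            config$n_regions)
  parent$health_area_id <- sprintf(
    "HA%03d", pmin((seq_len(n_par) - 1) %/% per_ha + 1, config$n_health_areas))

  n_units_per <- 1L + rpois(n_par, config$mean_units_per_parent - 1)
  pidx <- rep(seq_len(n_par), n_units_per)
  n_units <- length(pidx)

  # Dirichlet split of each parent area into its units
  g <- rgamma(n_units, shape = 1.5, rate = 1)
  share <- g / ave(g, pidx, FUN = sum)
  area <- parent$area_km2[pidx] * share

  # region-dependent geology mixture: later regions weighted to high-GM classes
  ord <- order(config$geology_gm)
  p_low <- setNames(rev(seq_len(n_geo)), geo_classes[ord])  # favour low GM
  p_low <- p_low / sum(p_low)
  p_high <- setNames(seq_len(n_geo)^1.5, geo_classes[ord])  # favour high GM
  p_high <- p_high / sum(p_high)
  w <- if (config$n_regions > 1) {
    (parent$region_idx[pidx] - 1) / (config$n_regions - 1)
  } else rep(0.5, n_units)
  u <- runif(n_units)
  geo <- character(n_units)
  for (i in seq_len(n_units)) {
    probs <- (1 - w[i]) * p_low + w[i] * p_high
    geo[i] <- geo_classes[ord][findInterval(u[i], cumsum(probs),
                                            left.open = TRUE) + 1L]
  }

  true_gm <- config$geology_gm[geo] * exp(rnorm(n_units, 0, 0.15))
  true_gsd <- config$geology_gsd[geo]

  units <- data.frame(
    unit_id = sprintf("U%05d", seq_len(n_units)),
    parent_id = parent$parent_id[pidx],
    region_id = sprintf("R%02d", parent$region_idx[pidx]),
    health_area_id = parent$health_area_id[pidx],
    area_km2 = area,
    parent_area_km2 = parent$area_km2[pidx],
    parent_population = parent$population[pidx],
    centroid_x = parent$gx[pidx] + runif(n_units, -0.4, 0.4),
    centroid_y = parent$gy[pidx] + runif(n_units, -0.4, 0.4),
    geology = geo,
    stringsAsFactors = FALSE)

  # categorical covariates: follow the geology class with prob 0.6
  geo_idx <- match(geo, geo_classes)
  for (k in seq_len(config$n_covariates_categorical)) {
    follow <- runif(n_units) < 0.6
    lev <- ifelse(follow, geo_idx, sample.int(n_geo, n_units, replace = TRUE))
    units[[sprintf("cat_%02d", k)]] <- paste0("lv", lev)
  }
  # continuous covariates: linear in log true GM plus noise; last is pure noise
  for (k in seq_len(config$n_covariates_continuous)) {
    beta <- if (k == config$n_covariates_continuous) 0 else 1
    units[[sprintf("cont_%02d", k)]] <-
      beta * log(true_gm) + rnorm(n_units, 0, 0.5)
  }
  units$true_gm <- unname(true_gm)
  units$true_gsd <- unname(true_gsd)
  units
}

#' Names of the classifier covariate columns in a unit table
#' @param units a unit data.frame from [generate_units()].
#' @return character vector of covariate column names (geology plus the
#'   generated categorical and continuous covariates).
#' @export
covariate_names <- function(units) {
  c("geology", grep("^(cat|cont)_", names(units), value = TRUE))
}

#' Generate indoor radon measurements for a subset of units
#'
#' Samples which units are measured by Bernoulli draws weighted towards
#' high-GM geology (emulating surveys that oversample areas with known high
#' ambient radiation), draws a zero-truncated Poisson count of measurements
#' per measured unit, and draws each concentration from the unit's
#' log-normal law: geometric mean `true_gm`, geometric standard deviation
#' of its geology class.
#'
#' @param units data.frame from [generate_units()].
#' @param config a [generator_config()].
#' @return data.frame with columns `measurement_id`, `unit_id`,
#'   `concentration_bq_m3`, `survey_id`.
#' @export
generate_measurements <- function(units, config) {
  if (nrow(units) == 0) stop_input("generate_measurements: 'units' is empty")
  missing_geo <- setdiff(unique(units$geology), names(config$geology_gm))
  if (length(missing_geo))
    stop_input("generate_measurements: geology class(es) absent from ",
               "geology_gm map: ", paste(missing_geo, collapse = ", "))
  if (!is.null(config$seed)) set.seed(substream_seed(config$seed, 2L))
  if (config$measurements_per_unit_mean == 0) {
    return(data.frame(measurement_id = character(), unit_id = character(),
                      concentration_bq_m3 = numeric(),
                      survey_id = character(), stringsAsFactors = FALSE))
  }

  gm <- units$true_gm
  weight <- sqrt(gm) / mean(sqrt(gm))
  p_measured <- pmin(1, config$measured_fraction * weight)
  measured <- runif(nrow(units)) < p_measured
  midx <- which(measured)
  if (!length(midx))
    return(data.frame(measurement_id = character(), unit_id = character(),
                      concentration_bq_m3 = numeric(),
                      survey_id = character(), stringsAsFactors = FALSE))

  counts <- rpois_truncated(length(midx), config$measurements_per_unit_mean)
  ridx <- rep(midx, counts)
  conc <- rlnorm(length(ridx), meanlog = log(units$true_gm[ridx]),
                 sdlog = log(units$true_gsd[ridx]))
  data.frame(
    measurement_id = sprintf("M%06d", seq_along(ridx)),
    unit_id = units$unit_id[ridx],
    concentration_bq_m3 = conc,
    survey_id = "synthetic",
    stringsAsFactors = FALSE)
}

#' Generate health areas with smoking prevalence estimates
#' @param config a [generator_config()].
#' @return data.frame with `health_area_id` and `smoking_prevalence`.
#' @export
generate_health_areas <- function(config) {
  if (!is.null(config$seed)) set.seed(substream_seed(config$seed, 3L))
  data.frame(
    health_area_id = sprintf("HA%03d", seq_len(config$n_health_areas)),
    smoking_prevalence = runif(config$n_health_areas,
                               config$smoking_prevalence_range[1],
                               config$smoking_prevalence_range[2]),
    stringsAsFactors = FALSE)
}

#' Latent radon truth table for generated units
#'
#' The true 95th percentile of a log-normal law with geometric mean GM and
#' geometric standard deviation GSD is `GM * GSD^z95` with `z95 = qnorm(0.95)`;
#' a unit is in the true-high stratum when that percentile meets
#' `truth_threshold`.
#'
#' @param units data.frame from [generate_units()].
#' @param config a [generator_config()].
#' @return data.frame with `unit_id`, `true_gm`, `true_gsd`, `true_p95`,
#'   `true_class` ("high"/"low").
#' @export
radon_truth <- function(units, config) {
  p95 <- units$true_gm * units$true_gsd^qnorm(0.95)
  data.frame(
    unit_id = units$unit_id,
    true_gm = units$true_gm,
    true_gsd = units$true_gsd,
    true_p95 = p95,
    true_class = ifelse(p95 >= config$truth_threshold, "high", "low"),
    stringsAsFactors = FALSE)
}

#' Generate synthetic death records
#'
#' Draws a Poisson number of deaths per unit-year (rate proportional to the
#' unit's apportioned population), assigns sex, age and an ICD-10-style
#' cause code. A configurable fraction of records receives external causes
#' (first letter T-Y) and a fraction is aged under 20, so the downstream
#' filters have something to remove. Among natural adult deaths the
#' probability of lung cancer (code "C34") is logistic-linear in the unit's
#' true radon stratum, the health area's smoking class (prevalence above
#' the median), sex, and scaled calendar year, with the configured odds
#' ratios.
#'
#' @param units data.frame from [generate_units()].
#' @param health_areas data.frame from [generate_health_areas()].
#' @param truth data.frame from [radon_truth()].
#' @param config a [generator_config()].
#' @return data.frame with columns `death_id`, `year`, `sex`, `age`,
#'   `cause_code`, `unit_id`, `health_area_id`.
#' @export
generate_deaths <- function(units, health_areas, truth, config) {
  if (nrow(units) == 0) stop_input("generate_deaths: 'units' is empty")
  if (!all(units$health_area_id %in% health_areas$health_area_id))
    stop_input("generate_deaths: every unit needs a health area with a ",
               "smoking prevalence")
  if (!is.null(config$seed)) set.seed(substream_seed(config$seed, 4L))

  unit_pop <- apportion_population(units$parent_population,
                                   units$parent_area_km2, units$area_km2)
  lambda <- config$deaths_per_unit_year * unit_pop / mean(unit_pop)
  years <- seq(config$first_year, length.out = config$n_years)

  grid_counts <- rpois(nrow(units) * config$n_years,
                       rep(lambda, times = config$n_years))
  uidx <- rep(rep(seq_len(nrow(units)), times = config$n_years), grid_counts)
  year <- rep(rep(years, each = nrow(units)), grid_counts)
  n <- length(uidx)

  sex <- ifelse(runif(n) < 0.5, "male", "female")
  age <- ifelse(runif(n) < config$under20_fraction,
                sample(0:19, n, replace = TRUE),
                pmax(20, round(rnorm(n, 76, 12))))

  smoking_median <- median(health_areas$smoking_prevalence)
  smoke_high <- setNames(health_areas$smoking_prevalence > smoking_median,
                         health_areas$health_area_id)
  true_high <- setNames(truth$true_class == "high", truth$unit_id)

  year_scaled <- if (config$n_years > 1) {
    (year - config$first_year) / (config$n_years - 1)
  } else rep(0, n)
  eta <- qlogis(config$lung_base_rate) +
    log(config$lung_effect_radon) * true_high[units$unit_id[uidx]] +
    log(config$lung_effect_smoking) * smoke_high[units$health_area_id[uidx]] +
    log(config$sex_effect) * (sex == "male") +
    log(config$year_trend_ratio) * year_scaled
  is_lung <- runif(n) < plogis(eta)

  external_codes <- c("T751", "V431", "W190", "X590", "Y850")
  other_codes <- c("I219", "I640", "J449", "C61", "E149", "G309")
  code <- ifelse(is_lung, "C34",
                 other_codes[sample.int(length(other_codes), n, replace = TRUE)])
  is_ext <- runif(n) < config$external_fraction
  code[is_ext] <- external_codes[sample.int(length(external_codes),
                                            sum(is_ext), replace = TRUE)]

  data.frame(
    death_id = sprintf("D%07d", seq_len(n)),
    year = year,
    sex = sex,
    age = as.integer(age),
    cause_code = code,
    unit_id = units$unit_id[uidx],
    health_area_id = units$health_area_id[uidx],
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage under substreams of one root seed and bundles
#' the results. The object is the in-memory analogue of the CSV tables a
#' real study would supply.
#'
#' @param config a [generator_config()].
#' @return an object of class `radon_study`: a list with elements `units`,
#'   `measurements`, `health_areas`, `deaths`, `truth` and `config`.
#' @export
synthesize_study <- function(config = generator_config()) {
  units <- generate_units(config)
  measurements <- generate_measurements(units, config)
  health_areas <- generate_health_areas(config)
  truth <- radon_truth(units, config)
  deaths <- generate_deaths(units, health_areas, truth, config)
  structure(list(units = units, measurements = measurements,
                 health_areas = health_areas, deaths = deaths,
                 truth = truth, config = config),
            class = "radon_study")
}

#' @export
print.radon_study <- function(x, ...) {
  cat("Synthetic radon study\n")
  cat(sprintf("  units:        %d (in %d parent areas, %d regions)\n",
              nrow(x$units), length(unique(x$units$parent_id)),
              length(unique(x$units$region_id))))
  cat(sprintf("  measured:     %d units, %d measurements\n",
              length(unique(x$measurements$unit_id)), nrow(x$measurements)))
  cat(sprintf("  health areas: %d\n", nrow(x$health_areas)))
  cat(sprintf("  deaths:       %d over %d years\n",
              nrow(x$deaths), x$config$n_years))
  invisible(x)
}
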