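#' Train one balanced forest per threshold
#'
#' @param units unit data.frame; covariates are taken from
#'   [covariate_names()] unless `covariates` is given.
#' @param labels label table from [build_training_set()]`$labels`.
#' @param ladder a [threshold_ladder()].
#' @param config a [forest_config()]; each threshold's model derives its
#'   seed from `config$seed` and the threshold index so models are
#'   independent but reproducible.
#' @param covariates covariate column names.
#' @return named list of [brf_fit()] models, names = thresholds.
#' @export
train_ladder <- function(units, labels, ladder = threshold_ladder(),
                         config = forest_config(),
                         covariates = covariate_names(units)) {
  x <- units[match(labels$unit_id, units$unit_id), covariates, drop = FALSE]
  models <- list()
  for (i in seq_along(ladder)) {
    t <- ladder[i]
    cfg <- config
    if (!is.null(config$seed))
      cfg$seed <- substream_seed(config$seed, 1000L + i)
    models[[as.character(t)]] <- brf_fit(x, labels[[paste0("T", t)]], cfg)
  }
  models
}

#' Pipeline configuration
#'
#' @param out_dir directory for all written artifacts.
#' @param generator a [generator_config()] (its `seed` is overridden by
#'   the pipeline seed).
#' @param ladder a [threshold_ladder()].
#' @param forest a [forest_config()].
#' @param loess_span,loess_degree smoothing settings for the trend curves.
#' @param geary_permutations permutations for the spatial autocorrelation
#'   tests.
#' @param seed root seed; every stochastic stage draws from a named
#'   substream of it.
#' @return a list of class `radon_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            generator = generator_config(),
                            ladder = threshold_ladder(),
                            forest = forest_config(),
                            loess_span = 0.75, loess_degree = 2,
                            geary_permutations = 999,
                            seed = 1L) {
  structure(list(out_dir = out_dir, generator = generator, ladder = ladder,
                 forest = forest, loess_span = loess_span,
                 loess_degree = loess_degree,
                 geary_permutations = geary_permutations,
                 seed = as.integer(seed)),
            class = "radon_pipeline_config")
}

#' Run the full pipeline on a synthetic study
#'
#' Executes simulate -> label -> train (one forest per threshold) ->
#' metrics -> map -> trends, writing every artifact as CSV under
#' `config$out_dir` and a JSON manifest with file hashes and the effective
#' configuration. Reruns under the same seed produce identical hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly; its `results` element holds the
#'   in-memory study, models, metrics table, maps, regional summaries and
#'   trend series.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "radon_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character()
  emit <- function(x, name) {
    written <<- c(written, write_table_csv(x, out(name)))
  }

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  gen <- config$generator
  gen$seed <- substream_seed(config$seed, 11L)
  study <- stage("simulate", synthesize_study(gen))
  emit(study$units, "units.csv")
  emit(study$measurements, "measurements.csv")
  emit(study$health_areas, "health_areas.csv")
  emit(study$deaths, "deaths.csv")
  emit(study$truth, "truth.csv")

  training <- stage("label", build_training_set(study$units,
                                                study$measurements,
                                                config$ladder))
  emit(training$labels, "labels.csv")
  emit(training$class_distribution, "class_distribution.csv")

  fcfg <- config$forest
  fcfg$seed <- substream_seed(config$seed, 12L)
  models <- stage("train", train_ladder(study$units, training$labels,
                                        config$ladder, fcfg))

  metrics <- stage("metrics", {
    tab <- ladder_metrics(models)
    measured <- study$units[match(training$labels$unit_id,
                                  study$units$unit_id), ]
    w <- knn_weights(cbind(measured$centroid_x, measured$centroid_y), k = 8)
    gc_raw <- geary_c(training$labels$p95, w,
                      n_permutations = config$geary_permutations,
                      seed = substream_seed(config$seed, 13L))
    list(table = tab, geary_p95 = gc_raw)
  })
  emit(metrics$table, "metrics.csv")

  maps <- stage("map", build_threshold_maps(models, study$units))
  for (t in config$ladder)
    emit(maps[maps$threshold == t, c("unit_id", "class")],
         sprintf("map_T%g.csv", t))
  summaries <- summarize_regions(maps, study$units)
  emit(summaries, "regional_summary.csv")

  trends <- stage("trends", {
    filtered <- filter_deaths(study$deaths)
    smoking <- median_smoking_split(study$health_areas)
    stratified <- assign_strata(filtered, maps, smoking)
    years <- seq(gen$first_year, length.out = gen$n_years)
    series <- list()
    for (t in config$ladder) {
      for (cl in c("high", "low")) {
        s <- annual_ratio_series(stratified, threshold = t, vuln_class = cl,
                                 years = years)
        s$smoothed <- loess_smooth(s$year, s$ratio, span = config$loess_span,
                                   degree = config$loess_degree)
        series[[sprintf("T%g_%s", t, cl)]] <- s
        emit(s, sprintf("trends_T%g_%s.csv", t, cl))
      }
    }
    summary_tab <- stratum_summary_table(stratified)
    emit(summary_tab, "stratum_summary.csv")
    list(series = series, stratum_summary = summary_tab,
         stratified = stratified)
  })

  manifest <- list(
    seed = config$seed,
    config = list(ladder = as.numeric(config$ladder),
                  forest = unclass(config$forest),
                  generator = unclass(gen),
                  loess_span = config$loess_span,
                  loess_degree = config$loess_degree),
    files = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$results <- list(study = study, models = models, metrics = metrics,
                           maps = maps, regional_summary = summaries,
                           trends = trends)
  invisible(manifest)
}
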