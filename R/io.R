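# CSV readers/writers for the documented table schemas, plus model and
# GeoJSON export. Readers validate mandatory columns by name and preserve
# any extra columns verbatim; all files are comma-separated UTF-8 with "."
# decimals.

required_columns <- list(
  units = c("unit_id", "parent_id", "region_id", "health_area_id",
            "area_km2", "parent_area_km2", "parent_population"),
  measurements = c("unit_id", "concentration_bq_m3"),
  deaths = c("year", "sex", "age", "cause_code", "unit_id",
             "health_area_id"),
  health_areas = c("health_area_id", "smoking_prevalence"),
  labels = c("unit_id", "p95"),
  map = c("unit_id", "class"),
  truth = c("unit_id", "true_gm", "true_gsd", "true_p95", "true_class"))

read_table_checked <- function(path, schema) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_columns[[schema]], names(x))
  if (length(missing))
    stop_input("schema error in '", basename(path), "': missing column(s) ",
               paste(missing, collapse = ", "))
  x
}

#' Read and write the pipeline's CSV tables
#'
#' One reader/writer pair per documented schema. Readers fail with a
#' schema error naming any missing mandatory column and keep unknown
#' columns; writers emit plain comma-separated UTF-8 without row names.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return readers return a data.frame; writers return `path` invisibly.
#' @name radon_io
NULL

#' @rdname radon_io
#' @export
read_units_csv <- function(path) read_table_checked(path, "units")

#' @rdname radon_io
#' @export
read_measurements_csv <- function(path) read_table_checked(path, "measurements")

#' @rdname radon_io
#' @export
read_deaths_csv <- function(path) read_table_checked(path, "deaths")

#' @rdname radon_io
#' @export
read_health_areas_csv <- function(path) read_table_checked(path, "health_areas")

#' @rdname radon_io
#' @export
read_map_csv <- function(path) read_table_checked(path, "map")

#' @rdname radon_io
#' @export
write_table_csv <- function(x, path) {
  write.csv(format_for_csv(x), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

# fixed 10-significant-digit float formatting so output files (and their
# hashes) are stable across runs and platforms
format_for_csv <- function(x) {
  for (nm in names(x)) {
    if (is.double(x[[nm]]))
      x[[nm]] <- vapply(x[[nm]], function(v) {
        if (!is.finite(v)) return(if (is.na(v)) "NA" else as.character(v))
        format(signif(v, 10), scientific = FALSE, trim = TRUE, digits = 10)
      }, character(1))
  }
  x
}

#' Export a unit table as GeoJSON with placeholder rectangles
#'
#' Synthetic units have centroids but no real polygons; each feature gets
#' a square of the unit's area centred on its centroid (planar CRS),
#' carrying the unit's attributes (and, when `maps` rows are supplied, a
#' `class` property).
#'
#' @param units unit data.frame with `centroid_x`, `centroid_y`, `area_km2`.
#' @param path output path.
#' @param class optional per-unit class vector to attach.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(units, path, class = NULL) {
  half <- sqrt(units$area_km2) / 2
  features <- lapply(seq_len(nrow(units)), function(i) {
    x <- units$centroid_x[i]; y <- units$centroid_y[i]; h <- half[i]
    props <- list(unit_id = units$unit_id[i],
                  region_id = units$region_id[i],
                  area_km2 = units$area_km2[i])
    if (!is.null(class)) props$class <- class[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(list(
           c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
           c(x - h, y + h), c(x - h, y - h)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fitted forest to JSON (and back)
#'
#' Trees are stored as flattened node arrays (`feature`, `value`, `left`,
#' `right`, `pred`, `tree_start`) per run, together with the covariate
#' schema; the categorical split `value` is a level-set bitmask.
#'
#' @param model a fitted [brf_fit()] model.
#' @param path file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns a `radon_brf` model usable with [predict.radon_brf()].
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    schema = model$schema, is_cat = model$is_cat, y = model$y,
    mtry = model$mtry, balanced = model$balanced,
    oob_votes = model$oob_votes,
    config = unclass(model$config), runs = model$runs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- lapply(p$schema, function(s) {
    s$levels <- as.character(s$levels)
    s
  })
  runs <- lapply(seq_len(nrow_or_len(p$runs)), function(i) extract_run(p$runs, i))
  oob <- as.matrix(p$oob_votes)
  colnames(oob) <- c("low", "high")
  structure(list(runs = runs, schema = schema,
                 is_cat = as.logical(p$is_cat), oob_votes = oob,
                 y = as.character(p$y), mtry = as.integer(p$mtry),
                 balanced = isTRUE(p$balanced),
                 config = structure(p$config, class = "radon_forest_config"),
                 oob_coverage = mean(rowSums(oob) > 0)),
            class = "radon_brf")
}

nrow_or_len <- function(runs) if (is.data.frame(runs)) nrow(runs) else length(runs)

extract_run <- function(runs, i) {
  r <- if (is.data.frame(runs)) lapply(runs, `[[`, i) else runs[[i]]
  list(feature = as.integer(r$feature), value = as.numeric(r$value),
       left = as.integer(r$left), right = as.integer(r$right),
       pred = as.integer(r$pred), tree_start = as.integer(r$tree_start))
}
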