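#' Radon concentration threshold ladder
#'
#' The default ladder spans the guideline values in use internationally:
#' 50, 100, 150, 200, 300, 400, 500 and 600 Bq/m3 (e.g. the WHO reference
#' level of 100, the US action level of ~148, the Canadian guideline of
#' 200, and EU values between 200 and 400).
#'
#' @param thresholds strictly increasing positive concentrations (Bq/m3).
#' @return numeric vector of class `radon_threshold_ladder`.
#' @export
threshold_ladder <- function(thresholds = c(50, 100, 150, 200, 300, 400, 500, 600)) {
  if (!is.numeric(thresholds) || length(thresholds) < 1)
    stop_input("threshold_ladder: need at least one threshold")
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop_input("threshold_ladder: thresholds must be positive and finite")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_input("threshold_ladder: thresholds must be strictly increasing")
  structure(as.numeric(thresholds), class = "radon_threshold_ladder")
}

#' Observed 95th percentile radon concentration
#'
#' The 0.95 quantile under linear interpolation of order statistics with
#' plotting position `h = (n - 1) * p + 1` (the convention of
#' `quantile(type = 7)`). A single observation returns itself.
#'
#' @param values positive finite concentrations (Bq/m3).
#' @return the 95th percentile concentration.
#' @export
percentile_95 <- function(values) {
  if (length(values) == 0)
    stop_input("percentile_95: empty measurement list")
  if (any(!is.finite(values)) || any(values <= 0))
    stop_input("percentile_95: concentrations must be positive and finite")
  quantile(values, probs = 0.95, type = 7, names = FALSE)
}

#' Assign a vulnerability class from a 95th percentile and a threshold
#'
#' A unit is high vulnerability when its observed 95th percentile meets or
#' exceeds the threshold; a value exactly at the threshold is classified
#' high, so a home measuring exactly at a guideline remains actionable.
#'
#' @param p95 observed 95th percentile concentration(s) (Bq/m3).
#' @param threshold threshold concentration (Bq/m3), scalar.
#' @return character vector of "high"/"low".
#' @export
assign_vulnerability <- function(p95, threshold) {
  if (length(threshold) != 1 || !is.finite(threshold) || threshold <= 0)
    stop_input("assign_vulnerability: 'threshold' must be a positive scalar")
  if (any(!is.finite(p95)) || any(p95 <= 0))
    stop_input("assign_vulnerability: 'p95' must be positive and finite")
  ifelse(p95 >= threshold, "high", "low")
}

#' Build the threshold-indexed training set from measured units
#'
#' Exactly the units with at least one measurement are labelled. Each
#' labelled unit carries its observed 95th percentile and one high/low
#' class per threshold; by construction the labels nest (high at a
#' threshold implies high at every lower threshold).
#'
#' @param units data.frame with a `unit_id` column.
#' @param measurements data.frame with `unit_id` and `concentration_bq_m3`.
#' @param ladder a [threshold_ladder()].
#' @return a list with `labels` (data.frame: `unit_id`, `p95`, one `T<t>`
#'   column per threshold) and `class_distribution` (data.frame:
#'   `threshold`, `n_high`, `n_low`).
#' @export
build_training_set <- function(units, measurements,
                               ladder = threshold_ladder()) {
  ladder <- threshold_ladder(unclass(ladder))
  if (!all(c("unit_id", "concentration_bq_m3") %in% names(measurements)))
    stop_input("build_training_set: measurements need 'unit_id' and ",
               "'concentration_bq_m3' columns")
  measurements <- measurements[measurements$unit_id %in% units$unit_id, ,
                               drop = FALSE]
  if (nrow(measurements) == 0)
    stop_input("build_training_set: no unit has any measurement")

  p95 <- vapply(split(measurements$concentration_bq_m3, measurements$unit_id),
                percentile_95, numeric(1))
  labels <- data.frame(unit_id = names(p95), p95 = unname(p95),
                       stringsAsFactors = FALSE)
  for (t in ladder)
    labels[[paste0("T", t)]] <- assign_vulnerability(labels$p95, t)
  # keep the unit table's ordering for reproducible downstream joins
  labels <- labels[order(match(labels$unit_id, units$unit_id)), , drop = FALSE]
  rownames(labels) <- NULL

  dist <- data.frame(
    threshold = as.numeric(ladder),
    n_high = vapply(ladder, function(t) sum(labels[[paste0("T", t)]] == "high"),
                    integer(1)),
    n_low = vapply(ladder, function(t) sum(labels[[paste0("T", t)]] == "low"),
                   integer(1)))
  list(labels = labels, class_distribution = dist)
}
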