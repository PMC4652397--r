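#' Filter death records to adult natural deaths
#'
#' Drops records aged under 20, records whose ICD-10-style cause code
#' starts with a letter from T through Y (external causes), and records
#' with an empty/missing code (with a warning giving the count). The
#' remaining natural deaths are flagged lung cancer when the code starts
#' with "C34".
#'
#' @param deaths data.frame with `cause_code` and `age` columns.
#' @return the surviving records with a logical `lung` column added; the
#'   number of malformed records dropped is attached as attribute
#'   `n_malformed`.
#' @export
filter_deaths <- function(deaths) {
  if (!all(c("cause_code", "age") %in% names(deaths)))
    stop_input("filter_deaths: records need 'cause_code' and 'age' columns")
  code <- as.character(deaths$cause_code)
  malformed <- is.na(code) | !nzchar(code)
  if (any(malformed))
    warning(sprintf("dropping %d record(s) with malformed cause codes",
                    sum(malformed)))
  first <- toupper(substr(code, 1, 1))
  external <- first %in% c("T", "U", "V", "W", "X", "Y")
  keep <- !malformed & !external & deaths$age >= 20
  out <- deaths[keep, , drop = FALSE]
  out$lung <- startsWith(toupper(out$cause_code), "C34")
  rownames(out) <- NULL
  structure(out, n_malformed = sum(malformed))
}

#' Median split of health areas by smoking prevalence
#'
#' A health area is classified "higher" smoking when its prevalence is
#' strictly above the median of all estimates (midpoint convention for an
#' even count); a prevalence exactly at the median is "lower".
#'
#' @param prevalences named numeric vector (names = health area IDs) or a
#'   data.frame with `health_area_id` and `smoking_prevalence`.
#' @return named character vector of "higher"/"lower" per health area.
#' @export
median_smoking_split <- function(prevalences) {
  if (is.data.frame(prevalences)) {
    prevalences <- setNames(prevalences$smoking_prevalence,
                            prevalences$health_area_id)
  }
  if (length(prevalences) < 2)
    stop_input("median_smoking_split: need at least 2 health areas")
  if (anyNA(prevalences))
    stop_input("median_smoking_split: missing prevalence")
  m <- median(prevalences)
  setNames(ifelse(prevalences > m, "higher", "lower"), names(prevalences))
}

#' Attach ecologic strata to filtered deaths
#'
#' Each death receives, per threshold, the vulnerability class of its
#' unit, plus the smoking class of its health area. Deaths in
#' `INELIGIBLE` units are excluded from the stratified output (rather than
#' diluted into the low stratum); their per-threshold counts are attached
#' as attribute `n_excluded`.
#'
#' @param deaths filtered deaths from [filter_deaths()].
#' @param maps long map data.frame from [build_threshold_maps()] (or any
#'   data.frame with `unit_id`, `threshold`, `class`).
#' @param smoking_classes named vector from [median_smoking_split()].
#' @return long data.frame: one row per death x threshold with columns of
#'   `deaths` plus `threshold`, `vuln_class`, `smoking_class`.
#' @export
assign_strata <- function(deaths, maps, smoking_classes) {
  if (!all(deaths$unit_id %in% maps$unit_id))
    stop_input("assign_strata: some deaths fall in units absent from the map")
  thresholds <- sort(unique(maps$threshold))
  smoking <- unname(smoking_classes[deaths$health_area_id])
  out <- do.call(rbind, lapply(thresholds, function(t) {
    mt <- maps[maps$threshold == t, , drop = FALSE]
    cls <- mt$class[match(deaths$unit_id, mt$unit_id)]
    cbind(deaths,
          data.frame(threshold = t, vuln_class = cls,
                     smoking_class = smoking, stringsAsFactors = FALSE))
  }))
  n_excluded <- vapply(split(out$vuln_class, out$threshold),
                       function(cl) sum(cl == "INELIGIBLE"), integer(1))
  out <- out[out$vuln_class != "INELIGIBLE", , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_excluded = n_excluded)
}

#' Annual crude lung cancer mortality ratio series for one stratum
#'
#' Within the selected stratum, the annual sum of lung cancer deaths is
#' divided by the annual sum of all natural deaths. Years without natural
#' deaths yield a missing ratio.
#'
#' @param stratified long data.frame from [assign_strata()] (any subset of
#'   its columns containing `year`, `lung` and the stratum columns used).
#' @param threshold threshold to select (required when `stratified` spans
#'   several).
#' @param vuln_class,smoking_class,sex optional stratum selectors; `NULL`
#'   pools over that dimension.
#' @param years optional vector of years the series must cover (defaults
#'   to the observed range).
#' @return data.frame with `year`, `lung_deaths`, `natural_deaths`,
#'   `ratio`.
#' @export
annual_ratio_series <- function(stratified, threshold = NULL,
                                vuln_class = NULL, smoking_class = NULL,
                                sex = NULL, years = NULL) {
  d <- stratified
  if (!is.null(threshold)) d <- d[d$threshold == threshold, , drop = FALSE]
  if (!is.null(vuln_class)) d <- d[d$vuln_class == vuln_class, , drop = FALSE]
  if (!is.null(smoking_class))
    d <- d[d$smoking_class == smoking_class, , drop = FALSE]
  if (!is.null(sex)) d <- d[d$sex == sex, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("empty stratum: no natural deaths in any year")
    d <- d[, c("year", "lung"), drop = FALSE]
  }
  years <- years %||% (if (nrow(d)) seq(min(d$year), max(d$year)) else integer())
  natural <- vapply(years, function(y) sum(d$year == y), integer(1))
  lung <- vapply(years, function(y) sum(d$year == y & d$lung), integer(1))
  data.frame(year = years, lung_deaths = lung, natural_deaths = natural,
             ratio = ifelse(natural > 0, lung / natural, NA_real_))
}

#' Locally weighted (LOESS) smoothing of an annual ratio series
#'
#' At each year the fitted value comes from a weighted least-squares
#' polynomial of the given degree over the `q = ceiling(span * n)` nearest
#' years, with tricube weights `w = (1 - (d / d_max)^3)^3` where `d_max`
#' is the largest distance within the neighbourhood (all weights 1 when
#' `d_max = 0`). Points exactly at `d_max` get weight zero, so the
#' neighbourhood is grown until at least `degree + 1` points carry
#' strictly positive weight (keeping the local fit well determined).
#'
#' @param x,y numeric vectors (e.g. year and ratio); missing `y` values
#'   are dropped from the fit but fitted values are still returned at
#'   every `x`.
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#' @return numeric vector of fitted values at each `x`.
#' @export
loess_smooth <- function(x, y, span = 0.75, degree = 2) {
  if (!degree %in% c(1, 2)) stop_input("loess_smooth: degree must be 1 or 2")
  if (span <= 0 || span > 1) stop_input("loess_smooth: span must be in (0, 1]")
  ok <- is.finite(x) & is.finite(y)
  xs <- x[ok]; ys <- y[ok]
  n <- length(xs)
  if (n < degree + 2)
    stop_input("loess_smooth: need at least degree + 2 non-missing points")
  q0 <- max(ceiling(span * n), degree + 1)
  vapply(x, function(x0) {
    d <- abs(xs - x0)
    ord <- order(d)
    q <- q0
    repeat {
      nb <- ord[seq_len(q)]
      d_max <- max(d[nb])
      w <- if (d_max == 0) rep(1, q) else (1 - pmin(1, d[nb] / d_max)^3)^3
      if (sum(w > 0) >= degree + 1 || q >= n) break
      q <- q + 1
    }
    X <- outer(xs[nb] - x0, 0:degree, `^`)
    fit <- stats::lm.wfit(X, ys[nb], w)
    unname(fit$coefficients[1])
  }, numeric(1))
}

#' Stratum summary of deaths over the study period
#'
#' For the higher-smoking stratum and the high-radon stratum at each
#' threshold: the percentage of all natural deaths and of all lung cancer
#' deaths falling in the stratum, and the ratio of those percentages. By
#' default the ratio is computed from the percentages rounded to one
#' decimal (as printed in summary tables); set `from_rounded = FALSE` to
#' use the unrounded counts.
#'
#' @param stratified long data.frame from [assign_strata()].
#' @param from_rounded compute each ratio from the rounded percentages.
#' @return data.frame with `stratum`, `threshold`, `natural_deaths`,
#'   `lung_deaths`, `pct_natural`, `pct_lung`, `ratio_of_percentages`.
#' @export
stratum_summary_table <- function(stratified, from_rounded = TRUE) {
  thresholds <- sort(unique(stratified$threshold))
  base <- stratified[stratified$threshold == thresholds[1], , drop = FALSE]
  total_natural <- nrow(base)
  total_lung <- sum(base$lung)
  if (total_natural == 0) stop_input("stratum_summary_table: no natural deaths")

  row_for <- function(stratum, threshold, sel) {
    nat <- nrow(sel); lung <- sum(sel$lung)
    pct_nat <- 100 * nat / total_natural
    pct_lung <- 100 * lung / total_lung
    ratio <- if (from_rounded) {
      round(round(pct_lung, 1) / round(pct_nat, 1), 2)
    } else round(pct_lung / pct_nat, 2)
    data.frame(stratum = stratum, threshold = threshold,
               natural_deaths = nat, lung_deaths = lung,
               pct_natural = pct_nat, pct_lung = pct_lung,
               ratio_of_percentages = ratio, stringsAsFactors = FALSE)
  }

  out <- row_for("higher_smoking", NA_real_,
                 base[base$smoking_class == "higher", , drop = FALSE])
  for (t in rev(thresholds)) {
    st <- stratified[stratified$threshold == t &
                       stratified$vuln_class == "high", , drop = FALSE]
    out <- rbind(out, row_for("high_radon", t, st))
  }
  rownames(out) <- NULL
  out
}

#' Misclassification sensitivity of the high/low mortality ratios
#'
#' Exact expected-count correction for ecologic exposure misclassification
#' in the high group: a fraction `f_lung` of its lung cancer deaths and a
#' fraction `f_other` of its other natural deaths are assumed to truly
#' belong to the low group and are moved there; both group ratios
#' (lung / all natural within group) are recomputed on the moved counts.
#' Totals are conserved by construction.
#'
#' @param lung_high,other_high,lung_low,other_low observed death counts.
#' @param f_lung fraction of high-group lung cancer deaths truly low.
#' @param f_other fraction of high-group other natural deaths truly low.
#' @return list with corrected `ratio_high`, `ratio_low`, and the moved
#'   `counts` (a named vector).
#' @export
misclassification_sensitivity <- function(lung_high, other_high,
                                          lung_low, other_low,
                                          f_lung, f_other) {
  counts <- c(lung_high, other_high, lung_low, other_low)
  if (any(counts < 0))
    stop_input("misclassification_sensitivity: counts must be nonnegative")
  if (lung_high + other_high == 0)
    stop_input("misclassification_sensitivity: empty high group")
  if (f_lung < 0 || f_lung > 1 || f_other < 0 || f_other > 1)
    stop_input("misclassification_sensitivity: fractions must be in [0, 1]")
  moved_lung <- f_lung * lung_high
  moved_other <- f_other * other_high
  lh <- lung_high - moved_lung
  oh <- other_high - moved_other
  ll <- lung_low + moved_lung
  ol <- other_low + moved_other
  list(ratio_high = lh / (lh + oh),
       ratio_low = ll / (ll + ol),
       counts = c(lung_high = lh, other_high = oh,
                  lung_low = ll, other_low = ol))
}
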