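#' Confusion matrix of observed versus predicted vulnerability classes
#'
#' @param observed,predicted vectors of "low"/"high"; pairs with `NA` in
#'   either position (e.g. units never out-of-bag) are dropped.
#' @return 2x2 integer matrix indexed `[observed, predicted]` over
#'   `c("low", "high")`.
#' @export
confusion_matrix <- function(observed, predicted) {
  keep <- !is.na(observed) & !is.na(predicted)
  observed <- factor(observed[keep], levels = c("low", "high"))
  predicted <- factor(predicted[keep], levels = c("low", "high"))
  if (anyNA(observed) || anyNA(predicted))
    stop_input("confusion_matrix: classes must be \"low\"/\"high\"")
  cm <- table(observed = observed, predicted = predicted)
  matrix(as.integer(cm), 2, 2,
         dimnames = list(observed = c("low", "high"),
                         predicted = c("low", "high")))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || !all(dim(cm) == 2) || any(cm < 0))
    stop_input("expected a 2x2 nonnegative confusion matrix")
  if (sum(cm) == 0) stop_input("empty confusion matrix")
  cm
}

#' Per-class accuracy and precision
#'
#' Accuracy of a class is the proportion of that observed class correctly
#' classified (row-wise); precision is the proportion of that predicted
#' class correctly classified (column-wise). A zero denominator yields
#' `NA` (missing), never 0.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param class "low" or "high".
#' @return a fraction, or `NA` when the class was never observed
#'   (accuracy) / never predicted (precision).
#' @export
class_accuracy <- function(cm, class) {
  cm <- check_cm(cm)
  denom <- sum(cm[class, ])
  if (denom == 0) return(NA_real_)
  cm[class, class] / denom
}

#' @rdname class_accuracy
#' @export
class_precision <- function(cm, class) {
  cm <- check_cm(cm)
  denom <- sum(cm[, class])
  if (denom == 0) return(NA_real_)
  cm[class, class] / denom
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and expected agreement
#' `p_e = sum_c row_c * col_c / total^2`; when `p_e = 1` (both margins
#' degenerate) the statistic is 0 by convention. Kappa quantifies the
#' improvement of the classifier over a random classifier and is robust
#' for imbalanced classes.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- check_cm(cm)
  total <- sum(cm)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (p_e >= 1) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Kappa gain down the threshold ladder
#'
#' The gain at a threshold is its kappa minus the kappa of the
#' next-higher threshold's model; the highest threshold has gain 0. This
#' measures how much classification performance improves with each
#' reduction in the guideline value.
#'
#' @param thresholds numeric thresholds (any order; results follow the
#'   input order).
#' @param kappa kappa per threshold.
#' @return data.frame with `threshold`, `kappa`, `kappa_gain`.
#' @export
kappa_gain <- function(thresholds, kappa) {
  if (length(thresholds) != length(kappa))
    stop_input("kappa_gain: lengths differ")
  ord <- order(thresholds, decreasing = TRUE)
  k_sorted <- kappa[ord]
  gain_sorted <- c(0, diff(k_sorted))
  gain <- numeric(length(kappa))
  gain[ord] <- gain_sorted
  data.frame(threshold = thresholds, kappa = kappa, kappa_gain = gain)
}

#' Out-of-bag performance report for one fitted forest
#'
#' @param model a fitted [brf_fit()] model.
#' @return a list with the OOB `confusion_matrix` and the scalar metrics
#'   `accuracy_low`, `precision_low`, `accuracy_high`, `precision_high`,
#'   `kappa`.
#' @export
oob_metrics <- function(model) {
  pred <- oob_predict(model)
  cm <- confusion_matrix(model$y, pred)
  list(confusion_matrix = cm,
       accuracy_low = class_accuracy(cm, "low"),
       precision_low = class_precision(cm, "low"),
       accuracy_high = class_accuracy(cm, "high"),
       precision_high = class_precision(cm, "high"),
       kappa = cohen_kappa(cm))
}

#' Performance table across the threshold ladder
#'
#' One row per threshold with per-class OOB accuracy and precision, kappa,
#' and the kappa gain relative to the next-higher threshold.
#'
#' @param models named list of fitted [brf_fit()] models; names are the
#'   thresholds (as written by [train_ladder()]).
#' @return data.frame ordered by decreasing threshold.
#' @export
ladder_metrics <- function(models) {
  thresholds <- as.numeric(names(models))
  if (anyNA(thresholds))
    stop_input("ladder_metrics: model list names must be thresholds")
  rows <- lapply(models, function(m) {
    mt <- oob_metrics(m)
    data.frame(accuracy_low = mt$accuracy_low,
               precision_low = mt$precision_low,
               accuracy_high = mt$accuracy_high,
               precision_high = mt$precision_high,
               kappa = mt$kappa)
  })
  out <- cbind(threshold = thresholds, do.call(rbind, rows))
  out <- out[order(out$threshold, decreasing = TRUE), , drop = FALSE]
  out$kappa_gain <- kappa_gain(out$threshold, out$kappa)$kappa_gain
  rownames(out) <- NULL
  out
}

#' Symmetrised k-nearest-neighbour spatial weights
#'
#' Binary weights linking each unit to its k nearest neighbours by
#' centroid distance, symmetrised (`w_ij = max(w_ij, w_ji)`), zero
#' diagonal.
#'
#' @param coords two-column matrix of centroid coordinates.
#' @param k number of neighbours.
#' @return an n x n symmetric 0/1 weight matrix.
#' @export
knn_weights <- function(coords, k = 8) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2 || k < 1) stop_input("knn_weights: need >= 2 points and k >= 1")
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(coords))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]  # skip self
    w[i, nb] <- 1
  }
  pmax(w, t(w))
}

#' Geary's c with a permutation test
#'
#' `c = (N - 1) * sum_ij w_ij (x_i - x_j)^2 / (2 W sum_i (x_i - xbar)^2)`
#' with `W` the total weight. The expectation under no spatial
#' autocorrelation is 1; values below 1 indicate positive autocorrelation.
#' Significance comes from a two-sided permutation test: values are
#' randomly relabelled across units `n_permutations` times and the
#' add-one-corrected tail probability `(r + 1) / (B + 1)` is doubled
#' (capped at 1).
#'
#' @param values per-unit numeric values (non-constant).
#' @param weights symmetric nonnegative weight matrix with zero diagonal.
#' @param n_permutations number of random relabelings.
#' @param seed optional seed for the permutations.
#' @return list with `c`, `p_value`, `n_permutations`.
#' @export
geary_c <- function(values, weights, n_permutations = 999, seed = NULL) {
  n <- length(values)
  if (n < 3) stop_input("geary_c: need at least 3 units")
  if (!all(is.finite(values))) stop_input("geary_c: values must be finite")
  if (diff(range(values)) == 0)
    stop_input("geary_c: undefined for constant values")
  weights <- as.matrix(weights)
  if (!all(dim(weights) == n)) stop_input("geary_c: weight dimension mismatch")
  if (any(weights < 0)) stop_input("geary_c: weights must be nonnegative")
  if (any(abs(weights - t(weights)) > 1e-12))
    stop_input("geary_c: weights must be symmetric")
  if (any(diag(weights) != 0)) stop_input("geary_c: diagonal must be zero")
  W <- sum(weights)
  if (W <= 0) stop_input("geary_c: total weight must be positive")

  c_stat <- function(x) {
    num <- (n - 1) * sum(weights * outer(x, x, "-")^2)
    num / (2 * W * sum((x - mean(x))^2))
  }
  c_obs <- c_stat(values)

  if (!is.null(seed)) set.seed(seed)
  c_perm <- replicate(n_permutations, c_stat(values[sample.int(n)]))
  p_lo <- (sum(c_perm <= c_obs) + 1) / (n_permutations + 1)
  p_hi <- (sum(c_perm >= c_obs) + 1) / (n_permutations + 1)
  list(c = c_obs, p_value = min(1, 2 * min(p_lo, p_hi)),
       n_permutations = n_permutations)
}
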