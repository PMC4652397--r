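#' Configuration for the class-balanced bootstrap forest
#'
#' The study design trains, per threshold, an ensemble of class-balanced
#' bootstrap classification trees combined over several runs; pooling the
#' runs' out-of-bag vote tallies is equivalent to one larger forest, the
#' run structure is kept for seed bookkeeping. Trees are grown maximally
#' (Gini impurity splits, `min_leaf_size = 1`) on bootstrap samples that
#' draw the minority-class size from each class with replacement.
#'
#' @param n_runs number of forest runs whose votes are pooled (study
#'   design: 20).
#' @param n_trees_per_run trees per run (study design: 10,000; the desk
#'   default of 200 keeps a full 8-threshold ladder tractable).
#' @param n_features_per_split "sqrt" (ceiling of the square root of the
#'   number of covariates) or an explicit count.
#' @param min_leaf_size minimum observations in a leaf.
#' @param seed integer seed; run `r` draws from substream `seed + r`.
#' @return a list of class `radon_forest_config`.
#' @export
forest_config <- function(n_runs = 20, n_trees_per_run = 200,
                          n_features_per_split = "sqrt",
                          min_leaf_size = 1, seed = NULL) {
  if (n_runs < 1 || n_trees_per_run < 1 || min_leaf_size < 1)
    stop_input("forest_config: counts must be >= 1")
  if (!identical(n_features_per_split, "sqrt") &&
      (!is.numeric(n_features_per_split) || n_features_per_split < 1))
    stop_input("forest_config: 'n_features_per_split' must be \"sqrt\" or a count >= 1")
  structure(list(n_runs = as.integer(n_runs),
                 n_trees_per_run = as.integer(n_trees_per_run),
                 n_features_per_split = n_features_per_split,
                 min_leaf_size = as.integer(min_leaf_size),
                 seed = seed),
            class = "radon_forest_config")
}

#' Class-balanced bootstrap sample
#'
#' Draws `n_min` indices with replacement from each class, where `n_min` is
#' the minority class size, so that every bootstrap sample has equal
#' representation of both classes. Indices not drawn are out-of-bag.
#'
#' @param labels vector of class labels with exactly the classes "low" and
#'   "high" (any two-level factor/character works).
#' @param seed optional seed for this draw.
#' @return integer vector of in-bag indices (a multiset of size
#'   `2 * n_min`), with attribute `oob` holding the out-of-bag indices.
#' @export
balanced_bootstrap <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- split(seq_along(labels), as.character(labels))
  if (length(cls) < 2)
    stop_input("balanced_bootstrap: both classes must be present")
  n_min <- min(lengths(cls))
  inbag <- unlist(lapply(cls, function(idx)
    idx[sample.int(length(idx), n_min, replace = TRUE)]), use.names = FALSE)
  structure(inbag, oob = setdiff(seq_along(labels), inbag))
}

# Encode a covariate data.frame against a (possibly new) schema.
# Categorical columns become integer level codes 1..K; unseen levels map to
# NA, which marks the row ineligible for prediction.
encode_covariates <- function(x, schema = NULL) {
  if (is.null(schema)) {
    schema <- lapply(x, function(col) {
      if (is.numeric(col)) list(type = "continuous")
      else list(type = "categorical", levels = sort(unique(as.character(col))))
    })
    for (nm in names(schema)) {
      col <- x[[nm]]
      if (anyNA(col))
        stop_input("covariate '", nm, "' has missing values; not supported")
      if (schema[[nm]]$type == "categorical" &&
          length(schema[[nm]]$levels) > 52)
        stop_input("covariate '", nm, "' has more than 52 levels")
    }
  } else {
    missing_cols <- setdiff(names(schema), names(x))
    if (length(missing_cols))
      stop_input("schema error: missing covariate column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  X <- matrix(0, nrow(x), length(schema),
              dimnames = list(NULL, names(schema)))
  for (j in seq_along(schema)) {
    nm <- names(schema)[j]
    if (schema[[nm]]$type == "continuous") {
      X[, j] <- as.numeric(x[[nm]])
    } else {
      X[, j] <- match(as.character(x[[nm]]), schema[[nm]]$levels)
    }
  }
  list(X = X, is_cat = vapply(schema, function(s) s$type == "categorical",
                              logical(1)),
       schema = schema)
}

#' Fit a class-balanced bootstrap forest
#'
#' Grows `n_runs * n_trees_per_run` maximally grown classification trees.
#' Each tree's bootstrap sample is class-balanced ([balanced_bootstrap()]);
#' each split searches a random subset of covariates, considering midpoints
#' between consecutive observed values for continuous covariates and, for
#' categorical covariates, the level partition obtained by ordering levels
#' by within-node high-class proportion (optimal for binary Gini), and
#' takes the split with the largest Gini impurity decrease. Out-of-bag
#' votes are pooled across all runs.
#'
#' @param x data.frame of covariates (mixed categorical/continuous, no
#'   missing values).
#' @param y class labels, "high"/"low" (character or factor).
#' @param config a [forest_config()].
#' @param balanced set `FALSE` for a plain (unbalanced) bootstrap baseline.
#' @return an object of class `radon_brf` with out-of-bag vote tallies,
#'   per-tree in-bag class counts, the covariate schema and the flattened
#'   trees of each run.
#' @export
brf_fit <- function(x, y, config = forest_config(), balanced = TRUE) {
  y <- as.character(y)
  if (!all(y %in% c("high", "low")))
    stop_input("brf_fit: labels must be \"high\"/\"low\"")
  if (length(unique(y)) < 2)
    stop_input("brf_fit: both classes must be present in the training data")
  if (min(table(y)) < 2)
    stop_input("brf_fit: need at least 2 units per class")
  if (nrow(x) != length(y))
    stop_input("brf_fit: 'x' and 'y' sizes differ")

  enc <- encode_covariates(x)
  d <- ncol(enc$X)
  mtry <- if (identical(config$n_features_per_split, "sqrt")) {
    as.integer(ceiling(sqrt(d)))
  } else as.integer(min(config$n_features_per_split, d))
  y01 <- as.integer(y == "high")

  oob_votes <- matrix(0L, nrow(x), 2)
  inbag_counts <- NULL
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    if (!is.null(config$seed)) set.seed(substream_seed(config$seed, r))
    fr <- cpp_grow_forest(enc$X, enc$is_cat, y01,
                          config$n_trees_per_run, mtry,
                          config$min_leaf_size, balanced)
    oob_votes <- oob_votes + fr$oob_votes
    inbag_counts <- rbind(inbag_counts, fr$inbag_counts)
    runs[[r]] <- fr[c("feature", "value", "left", "right", "pred",
                      "tree_start")]
  }
  colnames(oob_votes) <- c("low", "high")
  colnames(inbag_counts) <- c("low", "high")

  coverage <- mean(rowSums(oob_votes) > 0)
  if (coverage < 0.99)
    warning(sprintf("only %.1f%% of training units are out-of-bag for at least one tree",
                    100 * coverage))

  structure(list(runs = runs, schema = enc$schema, is_cat = enc$is_cat,
                 oob_votes = oob_votes, inbag_counts = inbag_counts,
                 y = y, mtry = mtry, balanced = balanced, config = config,
                 oob_coverage = coverage),
            class = "radon_brf")
}

#' @export
print.radon_brf <- function(x, ...) {
  n_trees <- length(x$runs) * x$config$n_trees_per_run
  cat(sprintf("%s bootstrap forest: %d trees (%d runs), %d training units, mtry = %d\n",
              if (x$balanced) "Class-balanced" else "Plain",
              n_trees, length(x$runs), length(x$y), x$mtry))
  cat(sprintf("OOB coverage: %.1f%%\n", 100 * x$oob_coverage))
  invisible(x)
}

#' Out-of-bag class predictions
#'
#' Each training unit's class is the majority of its pooled out-of-bag
#' votes; ties go to "high" (conservative for a screening map). Units that
#' were never out-of-bag get `NA` and are excluded from metrics.
#'
#' @param model a fitted [brf_fit()] model.
#' @return character vector of "high"/"low" (with `NA` for uncovered
#'   units), with attribute `uncovered` giving their indices.
#' @export
oob_predict <- function(model) {
  stopifnot(inherits(model, "radon_brf"))
  v <- model$oob_votes
  pred <- ifelse(v[, "high"] >= v[, "low"], "high", "low")
  uncovered <- which(rowSums(v) == 0)
  pred[uncovered] <- NA_character_
  structure(pred, uncovered = uncovered)
}

#' Predict vulnerability classes for new units
#'
#' A unit is `INELIGIBLE` when any categorical covariate takes a level that
#' was absent from the training data (its covariate values are not
#' contained within the training dataset); otherwise its class is the
#' majority vote over all trees in all runs, ties going to "high".
#'
#' @param object a fitted [brf_fit()] model.
#' @param newdata data.frame carrying the model's covariate columns.
#' @param ... unused.
#' @return character vector of "high"/"low"/"INELIGIBLE".
#' @export
predict.radon_brf <- function(object, newdata, ...) {
  enc <- encode_covariates(newdata, schema = object$schema)
  ineligible <- rowSums(is.na(enc$X)) > 0
  out <- rep("INELIGIBLE", nrow(enc$X))
  if (any(!ineligible)) {
    Xe <- enc$X[!ineligible, , drop = FALSE]
    votes <- matrix(0L, nrow(Xe), 2)
    for (fr in object$runs) {
      votes <- votes + cpp_predict_forest(fr$feature, fr$value, fr$left,
                                          fr$right, fr$pred, fr$tree_start,
                                          Xe, object$is_cat)
    }
    out[!ineligible] <- ifelse(votes[, 2] >= votes[, 1], "high", "low")
  }
  out
}
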