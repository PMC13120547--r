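# Hybrid composite safety score.
#
# S_safe = sum_j w_j * f_j over the selected, normalized, direction-aligned
# features: Cohen's d against the safe/hazardous labels filters features
# (hypothesis-driven), a 100-tree Gini random forest supplies the weights
# via mean decrease in impurity (data-driven), and per-feature percentile
# bounds define the min-max normalization.

#' Cohen's d effect size
#'
#' `(mean(b) - mean(a)) / s_pooled`, with the pooled standard deviation from
#' the two n-1-denominator sample variances:
#' `s_pooled = sqrt(((n_a - 1) var_a + (n_b - 1) var_b) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 finite
#'   values.
#' @return The signed effect size (positive when `group_b` has the larger
#'   mean).
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("each group needs at least 2 finite values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stopf("zero pooled variance: effect size undefined")
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Fit the composite safety-score model
#'
#' Three stages: (1) features whose absolute Cohen's d between hazardous and
#' safe groups reaches `d_threshold` are retained, each with direction
#' `sign(d)` oriented so +1 means larger values are safer; (2) a random
#' forest (100 trees, Gini criterion, fixed seed) fitted on the retained
#' features supplies mean-decrease-in-impurity importances, renormalized to
#' sum to 1, as the weights; (3) the 2.5th/97.5th percentiles of each
#' retained feature over the fitting cohort become the normalization
#' bounds (percentile anchors with clipping are robust to outliers).
#' Constant features (undefined effect size) are dropped with a warning.
#'
#' @param metrics Data.frame of numeric candidate features (non-numeric
#'   columns are ignored).
#' @param labels Vector of `"safe"` / `"hazardous"` labels, one per row.
#' @param d_threshold Minimum absolute Cohen's d for retention
#'   (default 0.5, a medium effect).
#' @param seed RNG seed for the forest.
#' @return An object of class `score_model`: `selected_features`,
#'   `direction`, `bounds` (2 x p matrix), `weights`, `d_values`,
#'   `d_threshold`.
#' @export
fit_score_model <- function(metrics, labels, d_threshold = 0.5, seed = 1L) {
  labels <- as.character(labels)
  if (!all(labels %in% c("safe", "hazardous"))) {
    stopf("labels must be 'safe' or 'hazardous'")
  }
  if (nrow(metrics) < 10L) stopf("need at least 10 rows to fit a score model")
  if (length(unique(labels)) < 2L) stopf("both labels must be present")
  num <- vapply(metrics, is.numeric, TRUE)
  x <- as.data.frame(metrics[, num, drop = FALSE])

  d <- vapply(names(x), function(f) {
    tryCatch(cohens_d(x[[f]][labels == "hazardous"], x[[f]][labels == "safe"]),
             error = function(e) NA_real_)
  }, 0)
  if (any(is.na(d))) {
    warnf("dropping %d feature(s) with undefined effect size: %s",
          sum(is.na(d)), paste(names(d)[is.na(d)], collapse = ", "))
  }
  keep <- !is.na(d) & abs(d) >= d_threshold
  if (!any(keep)) {
    stopf("no feature reaches |d| >= %g; consider a lower d_threshold",
          d_threshold)
  }
  sel <- names(d)[keep]
  direction <- sign(d[keep])

  y <- factor(labels, levels = c("hazardous", "safe"))
  rf <- with_seed(seed, randomForest::randomForest(
    x = x[, sel, drop = FALSE], y = y, ntree = 100L, importance = FALSE))
  imp <- rf$importance[, "MeanDecreaseGini"]
  if (sum(imp) <= 0) imp <- rep(1, length(sel))
  w <- imp / sum(imp)

  bounds <- vapply(sel, function(f) {
    q <- stats::quantile(x[[f]], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    if (q[1] >= q[2]) q <- range(x[[f]], na.rm = TRUE)
    if (q[1] >= q[2]) q <- q + c(-0.5, 0.5)      # constant within the band
    q
  }, c(0, 0))
  rownames(bounds) <- c("low", "high")

  structure(list(selected_features = sel,
                 direction = stats::setNames(as.numeric(direction), sel),
                 bounds = bounds,
                 weights = stats::setNames(as.numeric(w), sel),
                 d_values = d,
                 d_threshold = d_threshold),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %d features (|d| >= %g)\n",
              length(x$selected_features), x$d_threshold))
  df <- data.frame(feature = x$selected_features,
                   d = round(x$d_values[x$selected_features], 3),
                   direction = x$direction,
                   weight = round(x$weights, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Composite safety score
#'
#' Min-max normalizes each selected feature to `[0, 1]` with the model's
#' bounds (clipped), flips features whose direction is -1 so that 1 always
#' means safer, and returns the weight-weighted sum. Since the weights sum
#' to 1 the score lies in `[0, 1]`.
#'
#' @param metrics Data.frame (or one-row data.frame / named list) containing
#'   every selected feature.
#' @param model A fitted [fit_score_model()] object.
#' @return Numeric vector of scores in `[0, 1]`, one per row.
#' @export
composite_score <- function(metrics, model) {
  metrics <- as.data.frame(metrics)
  missing <- setdiff(model$selected_features, names(metrics))
  if (length(missing)) {
    stopf("metrics table lacks selected feature(s): %s",
          paste(missing, collapse = ", "))
  }
  score <- rep(0, nrow(metrics))
  for (f in model$selected_features) {
    lo <- model$bounds["low", f]; hi <- model$bounds["high", f]
    fn <- clamp((metrics[[f]] - lo) / (hi - lo), 0, 1)
    if (model$direction[f] < 0) fn <- 1 - fn
    score <- score + model$weights[f] * fn
  }
  unname(score)
}

#' Serialize / restore a score model
#'
#' @param model A `score_model`.
#' @param path JSON file path.
#' @return `path` (write) or a `score_model` (read).
#' @export
write_score_model <- function(model, path) {
  obj <- list(schema = "safefall-score-model", version = 1L,
              d_threshold = model$d_threshold,
              features = lapply(model$selected_features, function(f) {
                list(name = f,
                     direction = model$direction[[f]],
                     low = model$bounds["low", f],
                     high = model$bounds["high", f],
                     weight = model$weights[[f]],
                     d = model$d_values[[f]])
              }))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "safefall-score-model")) {
    stopf("%s is not a score-model file", path)
  }
  fs <- obj$features
  sel <- vapply(fs, `[[`, "", "name")
  structure(list(
    selected_features = sel,
    direction = stats::setNames(vapply(fs, `[[`, 0, "direction"), sel),
    bounds = matrix(c(vapply(fs, `[[`, 0, "low"), vapply(fs, `[[`, 0, "high")),
                    2L, length(sel), byrow = TRUE,
                    dimnames = list(c("low", "high"), sel)),
    weights = stats::setNames(vapply(fs, `[[`, 0, "weight"), sel),
    d_values = stats::setNames(vapply(fs, `[[`, 0, "d"), sel),
    d_threshold = obj$d_threshold), class = "score_model")
}
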