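# Subject-independent supervised evaluation: grouped (and leave-one-subject-
# out) cross-validation, a five-model comparison, imbalance-robust metrics
# and impurity-based feature importances.

#' Subject-grouped cross-validation folds
#'
#' Partitions subjects (not rows) into `k` folds so that no subject appears
#' in both the training and testing side of any fold. With
#' `stratified = TRUE`, subjects are assigned greedily within each
#' subject-level label so fold label proportions stay balanced.
#'
#' @param subject_ids Subject id per row.
#' @param labels Label per row (constant within subject for stratification).
#' @param k Number of folds (>= 2); `k = number of subjects` gives LOSO.
#' @param stratified Balance subject-level label proportions (default
#'   `TRUE`).
#' @param seed RNG seed for the subject shuffle.
#' @return List of `k` folds, each `list(test_subjects, train_idx,
#'   test_idx)`. The test subject sets partition the subjects.
#' @export
grouped_split <- function(subject_ids, labels, k = 5L, stratified = TRUE,
                          seed = 1L) {
  subjects <- unique(subject_ids)
  if (length(subjects) < k) {
    stopf("fewer distinct subjects (%d) than folds (%d)", length(subjects), k)
  }
  sub_label <- vapply(subjects, function(s) {
    as.character(labels[subject_ids == s][1])
  }, "")
  fold_of <- stats::setNames(integer(length(subjects)), subjects)
  with_seed(seed, {
    if (stratified) {
      counts_total <- integer(k)
      for (lab in sample(unique(sub_label))) {
        members <- sample(subjects[sub_label == lab])
        counts_lab <- integer(k)
        for (s in members) {
          f <- order(counts_lab, counts_total)[1]
          fold_of[s] <- f
          counts_lab[f] <- counts_lab[f] + 1L
          counts_total[f] <- counts_total[f] + 1L
        }
      }
    } else {
      fold_of[] <- rep_len(seq_len(k), length(subjects))[sample(length(subjects))]
    }
  })
  lapply(seq_len(k), function(f) {
    test_subjects <- subjects[fold_of[subjects] == f]
    test_idx <- which(subject_ids %in% test_subjects)
    train_idx <- setdiff(seq_along(subject_ids), test_idx)
    stopifnot(length(intersect(subject_ids[train_idx],
                               subject_ids[test_idx])) == 0L)
    list(test_subjects = test_subjects, train_idx = train_idx,
         test_idx = test_idx)
  })
}

#' Evaluation protocol definition
#'
#' @param mode `"subject_metrics"` (one row per subject, the 15-metric task)
#'   or `"frame_level"`.
#' @param splitter `"grouped_kfold"` (default) or `"loso"`
#'   (leave-one-subject-out; `k` is then the number of subjects).
#' @param k Number of folds (default 5).
#' @param stratified Stratify folds by subject-level label (default `TRUE`).
#' @param models Subset of `c("random_forest", "gradient_boosting",
#'   "logistic_regression", "svm", "mlp")`.
#' @param seed Master seed.
#' @return List of class `eval_protocol`.
#' @export
eval_protocol <- function(mode = c("subject_metrics", "frame_level"),
                          splitter = c("grouped_kfold", "loso"),
                          k = 5L, stratified = TRUE,
                          models = c("random_forest", "gradient_boosting",
                                     "logistic_regression", "svm", "mlp"),
                          seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(mode = match.arg(mode), splitter = match.arg(splitter),
                 k = as.integer(k), stratified = stratified,
                 models = models, seed = as.integer(seed)),
            class = "eval_protocol")
}

# fit one model and return a scoring function prob(newdata) for the
# positive class (second factor level)
fit_model <- function(name, x, y, seed) {
  pos <- levels(y)[2]
  mu <- colMeans(x); sdv <- apply(x, 2L, stats::sd); sdv[sdv == 0] <- 1
  zx <- scale(x, mu, sdv)
  switch(name,
    random_forest = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = x, y = y, ntree = 100L))
      list(predict = function(nx) stats::predict(fit, nx, type = "prob")[, pos],
           importance = fit$importance[, "MeanDecreaseGini"])
    },
    gradient_boosting = {
      # predict() on a binary factor returns P(second level), i.e. P(pos)
      fit <- with_seed(seed, xgboost::xgboost(
        x = as.matrix(x), y = y, nrounds = 100L, learning_rate = 0.1,
        max_depth = 3L, nthreads = 1L, verbosity = 0))
      list(predict = function(nx) as.numeric(stats::predict(fit, as.matrix(nx))))
    },
    logistic_regression = {
      fit <- glmnet::glmnet(zx, y, family = "binomial", alpha = 0,
                            lambda = 0.01)
      list(predict = function(nx) as.numeric(stats::predict(
             fit, scale(as.matrix(nx), mu, sdv), type = "response")))
    },
    svm = {
      fit <- with_seed(seed, e1071::svm(x = zx, y = y, kernel = "radial",
                                        probability = TRUE))
      list(predict = function(nx) {
        pr <- stats::predict(fit, scale(as.matrix(nx), mu, sdv),
                             probability = TRUE)
        attr(pr, "probabilities")[, pos]
      })
    },
    mlp = {
      fit <- with_seed(seed, nnet::nnet(
        x = zx, y = as.numeric(y == pos), size = 16L, decay = 1e-3,
        maxit = 60L, MaxNWts = 50000L, trace = FALSE))
      list(predict = function(nx) as.numeric(stats::predict(
             fit, scale(as.matrix(nx), mu, sdv))))
    },
    stopf("unknown model: %s", name))
}

classification_metrics <- function(truth, prob, pos, neg, threshold = 0.5) {
  pred <- ifelse(prob >= threshold, pos, neg)
  acc <- mean(pred == truth)
  per_class <- vapply(c(neg, pos), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, c(0, 0, 0))
  auc <- if (length(unique(truth)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(response = truth, predictor = prob,
                                   levels = c(neg, pos), direction = "<",
                                   quiet = TRUE)))
  } else NA_real_
  c(accuracy = acc,
    precision = mean(per_class[1, ]),
    recall = mean(per_class[2, ]),
    f1 = mean(per_class[3, ]),
    auc = auc)
}

#' Run a subject-independent evaluation protocol
#'
#' Fits every model of the protocol on each training fold and evaluates on
#' the held-out subjects. Reported per model: accuracy, macro-averaged
#' precision/recall/F1 and AUC, as mean and sd across folds and recomputed
#' on the pooled out-of-fold predictions; in frame-level mode a
#' subject-aggregated pooling (mean predicted probability per subject) is
#' reported as well. Random-forest mean-decrease-in-impurity importances
#' are averaged over folds and renormalized. A training fold containing a
#' single class is skipped with a warning.
#'
#' @param features Data.frame or matrix of numeric features.
#' @param labels Two-class label vector.
#' @param subject_ids Subject id per row.
#' @param protocol An [eval_protocol()].
#' @return List of class `eval_report`: `per_model` (data.frame),
#'   `pooled`, `subject_pooled` (frame mode), `importance`,
#'   `fold_manifest`, `protocol`.
#' @export
run_protocol <- function(features, labels, subject_ids,
                         protocol = eval_protocol()) {
  x <- as.data.frame(features)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[, num, drop = FALSE]
  x[is.na(x)] <- 0
  y <- factor(as.character(labels))
  if (nlevels(y) != 2L) stopf("labels must have exactly 2 classes")
  neg <- levels(y)[1]; pos <- levels(y)[2]

  k <- if (protocol$splitter == "loso") length(unique(subject_ids)) else protocol$k
  folds <- grouped_split(subject_ids, y, k = k,
                         stratified = protocol$stratified,
                         seed = protocol$seed)

  fold_stats <- list()
  pooled_prob <- stats::setNames(
    replicate(length(protocol$models), rep(NA_real_, nrow(x)),
              simplify = FALSE), protocol$models)
  imps <- list()
  used_folds <- 0L
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train_idx; te <- folds[[f]]$test_idx
    if (length(unique(y[tr])) < 2L) {
      warnf("fold %d skipped: single-class training data", f)
      next
    }
    used_folds <- used_folds + 1L
    for (m in protocol$models) {
      fit <- fit_model(m, x[tr, , drop = FALSE], y[tr],
                       seed = protocol$seed + f)
      prob <- fit$predict(x[te, , drop = FALSE])
      pooled_prob[[m]][te] <- prob
      fold_stats[[length(fold_stats) + 1L]] <- data.frame(
        model = m, fold = f,
        t(classification_metrics(as.character(y[te]), prob, pos, neg)))
      if (m == "random_forest") imps[[length(imps) + 1L]] <- fit$importance
    }
  }
  if (used_folds == 0L) stopf("every fold had single-class training data")
  fs <- do.call(rbind, fold_stats)

  agg <- do.call(rbind, lapply(protocol$models, function(m) {
    g <- fs[fs$model == m, c("accuracy", "precision", "recall", "f1", "auc")]
    data.frame(model = m,
               t(stats::setNames(colMeans(g), paste0(names(g), "_mean"))),
               t(stats::setNames(apply(g, 2L, stats::sd),
                                 paste0(names(g), "_sd"))))
  }))

  pooled <- do.call(rbind, lapply(protocol$models, function(m) {
    ok <- !is.na(pooled_prob[[m]])
    data.frame(model = m, t(classification_metrics(
      as.character(y[ok]), pooled_prob[[m]][ok], pos, neg)))
  }))

  subject_pooled <- NULL
  if (protocol$mode == "frame_level") {
    subject_pooled <- do.call(rbind, lapply(protocol$models, function(m) {
      ok <- !is.na(pooled_prob[[m]])
      sp <- tapply(pooled_prob[[m]][ok], subject_ids[ok], mean)
      sl <- vapply(names(sp), function(s) {
        as.character(y[subject_ids == s][1])
      }, "")
      data.frame(model = m, t(classification_metrics(sl, as.numeric(sp),
                                                     pos, neg)))
    }))
  }

  importance <- NULL
  if (length(imps)) {
    im <- Reduce(`+`, imps) / length(imps)
    importance <- sort(im / sum(im), decreasing = TRUE)
  }

  manifest <- do.call(rbind, lapply(seq_along(folds), function(f) {
    data.frame(fold = f, subject_id = folds[[f]]$test_subjects,
               stringsAsFactors = FALSE)
  }))

  structure(list(per_model = agg, per_fold = fs, pooled = pooled,
                 subject_pooled = subject_pooled,
                 importance = importance, fold_manifest = manifest,
                 positive_class = pos, protocol = protocol),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mode=%s, %s with k=%d (positive class: %s)\n",
              x$protocol$mode, x$protocol$splitter, x$protocol$k,
              x$positive_class))
  show <- x$per_model
  show[-1] <- round(show[-1], 3)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Ranked feature-importance table
#'
#' Top features by mean impurity-based random-forest importance (averaged
#' over folds, renormalized to sum to 1); ties broken lexicographically.
#'
#' @param report An `eval_report` whose protocol included the random forest.
#' @param top_n Rows to return (default 10; capped at the feature count).
#' @return Data.frame: `rank`, `feature`, `importance`.
#' @export
importance_table <- function(report, top_n = 10L) {
  if (is.null(report$importance)) {
    stopf("report contains no random-forest importances")
  }
  imp <- report$importance
  ord <- order(-imp, names(imp))
  n <- min(top_n, length(imp))
  data.frame(rank = seq_len(n),
             feature = names(imp)[ord][seq_len(n)],
             importance = unname(imp[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}
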