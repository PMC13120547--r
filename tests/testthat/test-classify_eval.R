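make_task <- function(n_subj = 40, frames = 6, informative = TRUE,
                      seed = 1) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", 1:n_subj), each = frames)
  lab <- rep(rep(c("safe", "hazardous"), length.out = n_subj), each = frames)
  x <- data.frame(
    f1 = (lab == "safe") * (if (informative) 3 else 0) + rnorm(length(subj)),
    f2 = rnorm(length(subj)),
    f3 = rnorm(length(subj)))
  list(x = x, labels = lab, subjects = subj)
}

test_that("grouped splits partition subjects with zero overlap", {
  tk <- make_task(n_subj = 10, frames = 4)
  folds <- grouped_split(tk$subjects, tk$labels, k = 5, seed = 3)
  test_sets <- lapply(folds, `[[`, "test_subjects")
  expect_equal(vapply(test_sets, length, 0L), rep(2L, 5))
  expect_setequal(unlist(test_sets), unique(tk$subjects))
  for (f in folds) {
    expect_length(intersect(tk$subjects[f$train_idx],
                            tk$subjects[f$test_idx]), 0)
    # frame rows follow their subject
    expect_setequal(unique(tk$subjects[f$test_idx]), f$test_subjects)
  }
  expect_error(grouped_split(c("a", "b"), c(1, 2), k = 5), "fewer distinct")
})

test_that("stratified folds balance the minority share at study sizes", {
  subjects <- sprintf("S%03d", 1:415)
  labels <- rep(c("pre", "post"), c(285, 130))
  folds <- grouped_split(subjects, labels, k = 5, stratified = TRUE,
                         seed = 11)
  for (f in folds) {
    share <- mean(labels[match(f$test_subjects, subjects)] == "post")
    expect_lt(abs(share - 130 / 415), 0.05)
  }
})

test_that("a perfectly separable feature gives AUC 1 for every model", {
  tk <- make_task(n_subj = 24, frames = 5, seed = 7)
  tk$x$f1 <- ifelse(tk$labels == "safe", 10, -10)
  proto <- eval_protocol(mode = "frame_level", k = 3, seed = 2)
  report <- run_protocol(tk$x, tk$labels, tk$subjects, proto)
  expect_true(all(report$per_model$auc_mean > 0.999))
  expect_true(all(report$pooled$auc > 0.999))
  # metric identities on the pooled confusion matrix
  expect_true(all(report$pooled$accuracy >= 0.99))
  expect_true(all(report$per_model$f1_mean <= 1))
})

test_that("reports are reproducible and leakage-free", {
  tk <- make_task(n_subj = 20, frames = 4, seed = 5)
  proto <- eval_protocol(mode = "frame_level", k = 4, seed = 9)
  r1 <- run_protocol(tk$x, tk$labels, tk$subjects, proto)
  r2 <- run_protocol(tk$x, tk$labels, tk$subjects, proto)
  expect_identical(r1$per_model, r2$per_model)
  expect_identical(r1$pooled, r2$pooled)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$fold_manifest, r2$fold_manifest)
  # every subject appears in exactly one test fold
  expect_equal(sort(r1$fold_manifest$subject_id), sort(unique(tk$subjects)))
})

test_that("LOSO uses one fold per subject", {
  tk <- make_task(n_subj = 8, frames = 3, seed = 2)
  proto <- eval_protocol(mode = "frame_level", splitter = "loso",
                         models = "random_forest", seed = 1)
  report <- run_protocol(tk$x, tk$labels, tk$subjects, proto)
  expect_equal(nrow(report$fold_manifest), 8)
  expect_equal(vapply(split(report$fold_manifest$subject_id,
                            report$fold_manifest$fold), length, 0L),
               setNames(rep(1L, 8), as.character(1:8)))
})

test_that("shuffled labels give chance-level AUC", {
  tk <- make_task(n_subj = 60, frames = 1, informative = FALSE, seed = 3)
  aucs <- vapply(1:10, function(i) {
    set.seed(i + 100)
    lab <- sample(tk$labels)
    proto <- eval_protocol(models = "random_forest", k = 5, seed = i)
    run_protocol(tk$x, lab, tk$subjects, proto)$per_model$auc_mean
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("the importance table ranks informative features first", {
  tk <- make_task(n_subj = 40, frames = 3, seed = 13)
  proto <- eval_protocol(mode = "frame_level", models = "random_forest",
                         k = 4, seed = 5)
  report <- run_protocol(tk$x, tk$labels, tk$subjects, proto)
  tab <- importance_table(report, top_n = 2)
  expect_equal(tab$feature[1], "f1")
  expect_lte(sum(report$importance), 1 + 1e-9)
  full <- importance_table(report, top_n = 50)
  expect_equal(nrow(full), 3)
  proto_no_rf <- eval_protocol(models = "logistic_regression", k = 4, seed = 5)
  rep2 <- run_protocol(tk$x, tk$labels, tk$subjects, proto_no_rf)
  expect_error(importance_table(rep2), "no random-forest")
})

test_that("descent decisiveness ranks among the top skill markers", {
  # the three fall-commitment metrics are nearly collinear by construction
  # (monotone descents make the rectified descent rate proportional to the
  # net vertical change), so impurity importance splits arbitrarily within
  # the family; the scientific claim is that the family leads the ranking
  m <- cached_cohort_table(401)
  proto <- eval_protocol(models = "random_forest", k = 5, seed = 7)
  report <- run_protocol(m[, core_metric_names()], m$cohort, m$subject_id,
                         proto)
  tab <- importance_table(report, top_n = 3)
  fall_family <- c("avg_descent_rate", "max_descent_rate",
                   "total_vertical_change")
  expect_true(any(fall_family %in% tab$feature))
})

test_that("single-class training folds are skipped with a warning", {
  subj <- rep(c("a", "b", "c"), each = 4)
  lab <- rep(c("safe", "safe", "hazardous"), each = 4)
  x <- data.frame(f = rnorm(12))
  proto <- eval_protocol(mode = "frame_level", splitter = "loso",
                         models = "random_forest", seed = 1)
  expect_warning(run_protocol(x, lab, subj, proto), "single-class")
})
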