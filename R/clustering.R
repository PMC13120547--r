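# Unsupervised motor-profile analysis: standardization, PCA projection,
# k-means clustering with canonical relabeling, cluster characterization as
# percent deviation from the sample mean, and the cohort x cluster
# association test.

# z-standardize numeric columns, dropping constant ones with a warning
standardize_metrics <- function(x) {
  num <- vapply(x, is.numeric, TRUE)
  x <- as.data.frame(x[, num, drop = FALSE])
  sds <- vapply(x, function(c) stats::sd(c, na.rm = TRUE), 0)
  const <- is.na(sds) | sds == 0
  if (any(const)) {
    warnf("dropping constant column(s): %s",
          paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  scale(as.matrix(x))
}

#' PCA projection of the metric table
#'
#' z-standardizes the metric columns (constant columns are dropped with a
#' warning) and projects onto the leading principal components.
#'
#' @param metrics Data.frame of numeric metrics (non-numeric columns
#'   ignored).
#' @param n_components Number of components to keep (default 2).
#' @return List: `scores` (n x n_components), `explained_variance`
#'   (percentages, all components), `rotation`.
#' @export
project_pca <- function(metrics, n_components = 2L) {
  z <- standardize_metrics(metrics)
  if (ncol(z) < n_components) {
    stopf("only %d non-degenerate columns for %d components",
          ncol(z), n_components)
  }
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev,
       rotation = pc$rotation)
}

#' k-means motor-profile clustering
#'
#' Runs k-means (best of `n_init` random starts by within-cluster sum of
#' squares) on the z-standardized metrics, then relabels the clusters
#' canonically: descending movement-intensity centroid first (the
#' chaotic-like profile), ties broken by descending average descent rate, so
#' cluster numbering is stable across seeds.
#'
#' @param metrics Data.frame including the clustering metrics.
#' @param k Number of clusters (default 3; must be >= 2).
#' @param n_init Number of random starts (default 10).
#' @param seed RNG seed.
#' @param metric_names Columns to cluster on (default the 15 core metrics).
#' @return Integer vector of cluster assignments in `1:k`, with attributes
#'   `centers` (original-unit centroids) and `tot_withinss`.
#' @export
cluster_kmeans <- function(metrics, k = 3L, n_init = 10L, seed = 1L,
                           metric_names = core_metric_names()) {
  if (k < 2L) stopf("k must be at least 2")
  if (nrow(metrics) < k) stopf("fewer rows than clusters")
  x <- as.data.frame(metrics[, intersect(metric_names, names(metrics)),
                             drop = FALSE])
  z <- standardize_metrics(x)
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = n_init,
                                      iter.max = 100L))
  # canonical ordering on original-unit centroids
  cent <- apply(x, 2L, function(col) tapply(col, km$cluster, mean))
  ord <- order(-cent[, "movement_intensity"], -cent[, "avg_descent_rate"])
  relabel <- match(seq_len(k), ord)
  out <- relabel[km$cluster]
  attr(out, "centers") <- cent[ord, , drop = FALSE]
  attr(out, "tot_withinss") <- km$tot.withinss
  out
}

#' Characterize clusters as percent deviation from the sample mean
#'
#' For every metric and cluster, `100 * (cluster mean - sample mean) /
#' sample mean`; reported as `NA` where the sample mean is 0 (deviation
#' undefined).
#'
#' @param metrics Data.frame of numeric metrics.
#' @param assignments Cluster assignment per row.
#' @param metric_names Metrics to characterize (default the 15 core
#'   metrics present in the table).
#' @return Matrix `k x p` of percent deviations.
#' @export
characterize_clusters <- function(metrics, assignments,
                                  metric_names = core_metric_names()) {
  metric_names <- intersect(metric_names, names(metrics))
  x <- as.data.frame(metrics[, metric_names, drop = FALSE])
  ks <- sort(unique(assignments))
  out <- matrix(NA_real_, length(ks), length(metric_names),
                dimnames = list(paste0("cluster_", ks), metric_names))
  for (m in metric_names) {
    sm <- mean(x[[m]], na.rm = TRUE)
    cm <- tapply(x[[m]], assignments, mean, na.rm = TRUE)
    out[, m] <- if (is.na(sm) || sm == 0) NA_real_ else
      100 * (cm[as.character(ks)] - sm) / sm
  }
  out
}

#' Cohort x cluster association test
#'
#' Pearson chi-square test of independence (no continuity correction) on the
#' cohort-by-cluster contingency table. A warning is issued when any
#' expected count is below 5.
#'
#' @param cohort Cohort label per subject.
#' @param assignments Cluster assignment per subject.
#' @return List: `chi2`, `p`, `df`, `table` (observed), `expected`.
#' @export
cohort_cluster_association <- function(cohort, assignments) {
  tab <- table(cohort = cohort, cluster = assignments)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stopf("need at least 2 cohorts and 2 clusters (got %d x %d)",
          nrow(tab), ncol(tab))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("degenerate margins in the contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    warnf("expected count below 5 in %d cell(s); chi-square approximation may be poor",
          sum(ct$expected < 5))
  }
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), table = tab, expected = ct$expected)
}

#' Full motor-profile cluster report
#'
#' Convenience wrapper running [project_pca()], [cluster_kmeans()],
#' [characterize_clusters()] and [cohort_cluster_association()] on a cohort
#' metric table.
#'
#' @param metrics A [cohort_metrics()] table (needs a `cohort` column).
#' @param k,n_init,seed Passed to [cluster_kmeans()].
#' @return List of class `cluster_report`: `k`, `assignments`,
#'   `explained_variance`, `pc_scores`, `centroid_profiles`, `sizes`,
#'   `cohort_table`, `chi2`, `chi2_p`.
#' @export
cluster_report <- function(metrics, k = 3L, n_init = 10L, seed = 1L) {
  pca <- project_pca(metrics[, intersect(core_metric_names(), names(metrics)),
                             drop = FALSE])
  cl <- cluster_kmeans(metrics, k = k, n_init = n_init, seed = seed)
  assoc <- cohort_cluster_association(metrics$cohort, cl)
  structure(list(k = k,
                 assignments = as.integer(cl),
                 explained_variance = pca$explained_variance,
                 pc_scores = pca$scores,
                 centroid_profiles = characterize_clusters(metrics, cl),
                 sizes = as.integer(table(cl)),
                 cohort_table = assoc$table,
                 chi2 = assoc$chi2,
                 chi2_p = assoc$p),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k=%d, sizes: %s\n", x$k,
              paste(x$sizes, collapse = "/")))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$explained_variance[1], x$explained_variance[2]))
  cat(sprintf("  cohort x cluster: chi2=%.2f, p=%.4g\n", x$chi2, x$chi2_p))
  invisible(x)
}
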