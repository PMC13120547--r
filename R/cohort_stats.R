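# Pre/post cohort statistics: normality gate, Mann-Whitney U,
# Benjamini-Hochberg correction, effect sizes, percent change and
# category rollups.

#' Shapiro-Wilk normality gate
#'
#' Tests each group for normality; a constant (zero-variance) sample is
#' degenerate and reported as rejected. The non-parametric comparison path
#' is taken whenever either group rejects.
#'
#' @param groups Named list of numeric vectors (3 <= n <= 5000 each).
#' @param alpha Significance level (default 0.05).
#' @return Named logical vector: `TRUE` when normality is NOT rejected.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  vapply(groups, function(g) {
    g <- g[is.finite(g)]
    if (length(g) < 3L || length(g) > 5000L) {
      stopf("Shapiro-Wilk supports 3 <= n <= 5000 (got %d)", length(g))
    }
    if (stats::sd(g) == 0) return(FALSE)   # degenerate: flagged as non-normal
    stats::shapiro.test(g)$p.value >= alpha
  }, TRUE)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test; `U` is the number of pairs `(a_i, b_j)` with
#' `a_i > b_j` (the `wilcox.test` W statistic for the first sample). The
#' exact null distribution is used when both groups have at most 20
#' observations and there are no ties; otherwise the tie-corrected normal
#' approximation (with continuity correction) is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param sides `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return List with `U`, `p`, and `method` (`"exact"` / `"normal"`).
#' @export
mann_whitney <- function(group_a, group_b, sides = "two.sided") {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stopf("both groups must be non-empty")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- !ties && length(group_a) <= 20L && length(group_b) <= 20L
  if (stats::sd(c(group_a, group_b)) == 0) {
    # all observations identical: no evidence of a shift
    return(list(U = length(group_a) * length(group_b) / 2, p = 1,
                method = "degenerate"))
  }
  w <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                           alternative = sides,
                                           exact = exact, correct = !exact))
  list(U = unname(w$statistic), p = w$p.value,
       method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pre/post cohort comparison over the metric framework
#'
#' For every metric: group medians and means, Shapiro-Wilk gate, Mann-Whitney
#' U test (two-sided), Benjamini-Hochberg adjustment across all compared
#' metrics, Cohen's d, percent change (computed on medians for consistency
#' with median-based reporting, with the mean-based change also reported),
#' direction arrow, and a category rollup of significant counts.
#'
#' @param metrics Data.frame containing a cohort column and the metric
#'   columns.
#' @param cohort_col Name of the cohort column with `"pre"` / `"post"`
#'   values (default `"cohort"`).
#' @param metric_names Metrics to compare (default [core_metric_names()],
#'   the 15-metric framework).
#' @param alpha Significance level after adjustment (default 0.05).
#' @return List of class `cohort_comparison`: `per_metric` data.frame,
#'   `by_category` rollup, `alpha`, `n_pre`, `n_post`.
#' @export
compare_cohorts <- function(metrics, cohort_col = "cohort",
                            metric_names = core_metric_names(),
                            alpha = 0.05) {
  cohort <- metrics[[cohort_col]]
  if (is.null(cohort)) stopf("no column '%s' in the metrics table", cohort_col)
  pre <- metrics[cohort == "pre", , drop = FALSE]
  post <- metrics[cohort == "post", , drop = FALSE]
  if (nrow(pre) < 3L || nrow(post) < 3L) {
    stopf("need at least 3 rows per cohort (got %d pre, %d post)",
          nrow(pre), nrow(post))
  }
  missing <- setdiff(metric_names, names(metrics))
  if (length(missing)) stopf("metrics table lacks: %s",
                             paste(missing, collapse = ", "))

  rows <- lapply(metric_names, function(m) {
    a <- pre[[m]]; b <- post[[m]]
    gate <- vapply(list(pre = a, post = b), function(g) {
      g <- g[is.finite(g)]
      if (length(g) < 3L || stats::sd(g) == 0) return(FALSE)
      n <- length(g)
      if (n > 5000L) g <- g[round(seq(1L, n, length.out = 5000L))]
      stats::shapiro.test(g)$p.value >= alpha
    }, TRUE)
    mw <- mann_whitney(a, b)
    d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
    md_pre <- stats::median(a, na.rm = TRUE)
    md_post <- stats::median(b, na.rm = TRUE)
    mn_pre <- mean(a, na.rm = TRUE)
    mn_post <- mean(b, na.rm = TRUE)
    data.frame(
      metric = m, category = unname(metric_categories()[m]),
      median_pre = md_pre, median_post = md_post,
      mean_pre = mn_pre, mean_post = mn_post,
      normal_pre = gate[["pre"]], normal_post = gate[["post"]],
      U = mw$U, p_raw = mw$p,
      cohens_d = d,
      pct_change_median = if (md_pre != 0) 100 * (md_post - md_pre) / md_pre
                          else NA_real_,
      pct_change_mean = if (mn_pre != 0) 100 * (mn_post - mn_pre) / mn_pre
                        else NA_real_,
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per$p_adjusted <- fdr_adjust(per$p_raw)
  per$significant <- !is.na(per$p_adjusted) & per$p_adjusted < alpha
  per$direction <- ifelse(per$median_post > per$median_pre, "↑",
                          ifelse(per$median_post < per$median_pre, "↓", "="))

  by_cat <- do.call(rbind, lapply(split(per, per$category), function(g) {
    data.frame(category = g$category[1], total = nrow(g),
               significant = sum(g$significant),
               prop_significant = mean(g$significant))
  }))
  rownames(by_cat) <- NULL
  structure(list(per_metric = per, by_category = by_cat, alpha = alpha,
                 n_pre = nrow(pre), n_post = nrow(post)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> pre n=%d vs post n=%d, alpha=%g (BH-adjusted)\n",
              x$n_pre, x$n_post, x$alpha))
  p <- x$per_metric
  show <- data.frame(metric = p$metric,
                     md_pre = signif(p$median_pre, 4),
                     md_post = signif(p$median_post, 4),
                     dir = p$direction,
                     p_adj = signif(p$p_adjusted, 3),
                     sig = ifelse(p$significant, "*", ""),
                     d = round(p$cohens_d, 2))
  print(show, row.names = FALSE)
  cat(sprintf("\n%d of %d metrics significant (%.1f%%)\n",
              sum(p$significant), nrow(p), 100 * mean(p$significant)))
  print(x$by_category, row.names = FALSE)
  invisible(x)
}

#' Write a cohort comparison report
#'
#' Writes the per-metric table as CSV and a human-readable markdown summary.
#'
#' @param comparison A `cohort_comparison`.
#' @param csv_path,md_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the comparison.
#' @export
write_comparison <- function(comparison, csv_path = NULL, md_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(comparison$per_metric, csv_path, row.names = FALSE)
  }
  if (!is.null(md_path)) {
    p <- comparison$per_metric
    lines <- c(
      sprintf("# Cohort comparison (pre n=%d, post n=%d)", comparison$n_pre,
              comparison$n_post),
      "",
      "| Metric | Pre Md | Post Md | Change | p (BH) | d |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %.3f | %.3f | %s | %.4g%s | %.2f |",
              p$metric, p$median_pre, p$median_post, p$direction,
              p$p_adjusted, ifelse(p$significant, " *", ""), p$cohens_d),
      "",
      "| Category | Total | Significant |",
      "|---|---|---|",
      sprintf("| %s | %d | %d (%.1f%%) |", comparison$by_category$category,
              comparison$by_category$total, comparison$by_category$significant,
              100 * comparison$by_category$prop_significant))
    writeLines(lines, md_path)
  }
  invisible(comparison)
}
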