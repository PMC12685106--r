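# Univariate feature statistics and cohort demographic tests.

#' One-way ANOVA for a single feature
#'
#' Equal-variance one-way ANOVA across two or more groups of intensities.
#' For two groups the F statistic equals the square of the pooled-variance
#' two-sample t. Degenerate inputs follow fixed conventions: identical data
#' in all groups gives `F = 0, p = 1`; zero within-group variance with
#' differing means gives `p = 0`.
#'
#' @param values_by_group list of numeric vectors, one per group, each of
#'   length >= 2.
#' @return named vector `c(F =, p =)`.
#' @export
anova_feature <- function(values_by_group) {
  if (length(values_by_group) < 2) stop("need at least two groups", call. = FALSE)
  n <- vapply(values_by_group, length, integer(1))
  if (any(n < 2)) stop("each group needs at least 2 values", call. = FALSE)
  values <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(seq_along(values_by_group), n))
  if (stats::var(values) == 0) return(c(F = 0, p = 1))
  within_var <- vapply(values_by_group, stats::var, numeric(1))
  means <- vapply(values_by_group, mean, numeric(1))
  if (all(within_var == 0)) {
    return(if (length(unique(means)) == 1) c(F = 0, p = 1) else c(F = Inf, p = 0))
  }
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  c(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} p_(j) * n / j`, capped at 1 and returned in the input
#' order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fold change between two group means
#'
#' Ratio `mean_a / mean_b`, the convention under which a feature elevated in
#' group A reports a fold change above 1. A zero denominator yields `NA`
#' (undefined fold change) rather than an error.
#'
#' @param mean_a,mean_b group mean intensities.
#' @return the ratio, or `NA` when `mean_b` is 0.
#' @export
fold_change <- function(mean_a, mean_b) {
  ifelse(mean_b > 0, mean_a / mean_b, NA_real_)
}

#' Per-feature univariate statistics for a peak matrix
#'
#' Runs an equal-variance one-way ANOVA per consensus feature between the
#' two groups, adjusts p-values by Benjamini-Hochberg, and reports the fold
#' change (group A mean / group B mean of normalized intensities) with its
#' direction.
#'
#' @param matrix a [peak_matrix()] (normally PQN-normalized).
#' @param groups factor with two (or more) levels, one per sample; group A
#'   is the first level.
#' @return data.frame of class `feature_stats`: columns `mz`, `F`,
#'   `p_value`, `q_value`, `mean_a`, `mean_b`, `fold_change`, `direction`
#'   (`up_in_A` / `up_in_B` / `none`).
#' @export
feature_stats <- function(matrix, groups) {
  stopifnot(inherits(matrix, "peak_matrix"))
  groups <- factor(groups)
  X <- matrix$intensities
  if (length(groups) != nrow(X)) stop("groups must align with samples", call. = FALSE)
  lv <- levels(groups)
  res <- t(apply(X, 2, function(col) {
    anova_feature(split(col, groups))
  }))
  mean_a <- colMeans(X[groups == lv[1], , drop = FALSE])
  mean_b <- colMeans(X[groups == lv[2], , drop = FALSE])
  fc <- fold_change(mean_a, mean_b)
  out <- data.frame(
    mz = matrix$mz, F = res[, "F"], p_value = res[, "p"],
    q_value = bh_fdr(res[, "p"]),
    mean_a = mean_a, mean_b = mean_b, fold_change = fc,
    direction = ifelse(is.na(fc) | fc == 1, "none",
                       ifelse(fc > 1, "up_in_A", "up_in_B")),
    row.names = NULL
  )
  attr(out, "groups") <- lv
  class(out) <- c("feature_stats", "data.frame")
  out
}

#' Select discriminatory features
#'
#' Features with `q_value` below the threshold, ranked by ascending q.
#'
#' @param stats a [feature_stats()] data.frame.
#' @param q_threshold FDR threshold (default 0.05).
#' @return the selected rows, ordered by `q_value`.
#' @export
select_discriminatory <- function(stats, q_threshold = 0.05) {
  sel <- stats[!is.na(stats$q_value) & stats$q_value < q_threshold, , drop = FALSE]
  sel[order(sel$q_value, sel$p_value), , drop = FALSE]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' small numerical slack for ties).
#'
#' @param table 2x2 matrix of non-negative integer counts; both margins
#'   must be positive.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}

#' Two-sample t test
#'
#' Welch's t by default (unequal variances); the pooled-variance variant is
#' available via `pooled = TRUE`. Two identical constant groups return
#' `t = 0, p = 1` by convention.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param pooled use the equal-variance (pooled) statistic.
#' @return named vector `c(t =, p =)`.
#' @export
welch_t <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    return(if (mean(group_a) == mean(group_b)) c(t = 0, p = 1) else c(t = Inf, p = 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = pooled)
  c(t = unname(tt$statistic), p = unname(tt$p.value))
}

#' Demographic 2x2 tests for a cohort metadata table
#'
#' Convenience wrapper running [fisher_exact_2x2()] on cancer-vs-benign
#' contingency tables of a binary patient characteristic.
#'
#' @param meta metadata data.frame with a `diagnosis` column.
#' @param column name of the characteristic column.
#' @param level the level counted in the first row of the 2x2 table; all
#'   other non-missing levels form the second row.
#' @return the two-sided Fisher p-value.
#' @export
demographic_fisher <- function(meta, column, level) {
  v <- meta[[column]]
  keep <- !is.na(v)
  tab <- table(factor(v[keep] == level, levels = c(TRUE, FALSE)),
               factor(meta$diagnosis[keep], levels = c("cancer", "benign")))
  fisher_exact_2x2(t(tab))
}
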