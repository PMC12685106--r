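# Protein-level differential analysis for reverse phase protein array data:
# per-protein univariate logistic regression of tissue status on expression,
# odds ratios with Wald 95% confidence intervals, FDR correction and group
# summaries.

#' Univariate logistic regression of tissue status on one protein
#'
#' Maximum-likelihood fit of `status ~ intercept + expression` with a
#' binomial link via iteratively reweighted least squares. The odds ratio is
#' `exp(beta)` per expression unit (or per SD with `per_sd = TRUE`) and the
#' 95% CI is the Wald interval `exp(beta +/- 1.96 se)`. Complete or
#' quasi-complete separation is detected and flagged rather than reported as
#' a finite estimate.
#'
#' @param expression numeric vector of per-patient expression values.
#' @param labels per-patient class labels; `positive` is coded 1.
#' @param positive the outcome class modelled as 1 (default `"cancer"`).
#' @param per_sd standardize expression to unit SD before fitting.
#' @return list with `beta`, `se`, `p`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `separated` (logical flag; estimates are `Inf`-marked when set).
#' @export
fit_logistic_univariate <- function(expression, labels, positive = "cancer",
                                    per_sd = FALSE) {
  labels <- as.character(labels)
  y <- as.integer(labels == positive)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (stats::var(expression) == 0) stop("expression has zero variance", call. = FALSE)
  x <- if (per_sd) expression / stats::sd(expression) else expression
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-8,
                                                                  maxit = 100)))
  beta <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  # separation: fitted probabilities pinned to 0/1 or exploding estimates
  eta <- stats::predict(fit, type = "link")
  separated <- !fit$converged || any(abs(eta) > 15) || se > 1e3
  if (separated) {
    return(list(beta = sign(beta) * Inf, se = Inf, p = NA_real_,
                odds_ratio = if (beta > 0) Inf else 0,
                ci_low = NA_real_, ci_high = NA_real_, separated = TRUE))
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(beta = beta, se = se, p = p, odds_ratio = exp(beta),
       ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
       separated = FALSE)
}

#' Group expression summaries for one protein
#'
#' Arithmetic mean and sample SD (n - 1) per class, with the dysregulation
#' direction in cancer.
#'
#' @param expression numeric vector of expression values.
#' @param labels per-patient class labels.
#' @param positive the class reported as "cancer" (default `"cancer"`).
#' @return list with `mean_cancer`, `sd_cancer`, `mean_benign`, `sd_benign`,
#'   `direction` (`"Increased"`, `"Decreased"` or `"Tie"`); SDs are `NA`
#'   for single-value groups.
#' @export
summarize_groups <- function(expression, labels, positive = "cancer") {
  labels <- as.character(labels)
  a <- expression[labels == positive]
  b <- expression[labels != positive]
  if (length(a) == 0 || length(b) == 0) stop("a group is empty", call. = FALSE)
  list(
    mean_cancer = mean(a), sd_cancer = if (length(a) > 1) stats::sd(a) else NA_real_,
    mean_benign = mean(b), sd_benign = if (length(b) > 1) stats::sd(b) else NA_real_,
    direction = if (mean(a) > mean(b)) "Increased"
                else if (mean(a) < mean(b)) "Decreased" else "Tie"
  )
}

#' Per-protein differential analysis of a protein table
#'
#' Fits a univariate logistic regression for every protein, adjusts the
#' p-values of successful fits by Benjamini-Hochberg, and attaches group
#' summaries. Failed or separated fits are flagged and excluded from the
#' FDR denominator; the run continues.
#'
#' @param table patients x proteins matrix (class `protein_table` or plain).
#' @param meta metadata data.frame whose `patient_id`/`diagnosis` cover the
#'   table's rows.
#' @param positive outcome class (default `"cancer"`).
#' @param q_threshold significance threshold on the q-value.
#' @param per_sd report odds ratios per SD of expression.
#' @return data.frame of class `rppa_stats`: one row per protein with
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `q_value`, group
#'   means/SDs, `direction`, `separated` and `significant`.
#' @export
rppa_pipeline <- function(table, meta, positive = "cancer", q_threshold = 0.05,
                          per_sd = FALSE) {
  m <- as.matrix(table)
  if (ncol(m) == 0 || nrow(m) == 0) {
    out <- data.frame(protein = character(0))
    class(out) <- c("rppa_stats", "data.frame")
    return(out)
  }
  idx <- match(rownames(m), meta$patient_id)
  if (any(is.na(idx))) stop("metadata does not cover all table patients", call. = FALSE)
  labels <- meta$diagnosis[idx]
  rows <- lapply(seq_len(ncol(m)), function(j) {
    expr <- m[, j]
    smry <- summarize_groups(expr, labels, positive)
    fit <- tryCatch(fit_logistic_univariate(expr, labels, positive, per_sd),
                    error = function(e) NULL)
    if (is.null(fit)) {
      fit <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  separated = NA)
    }
    data.frame(protein = colnames(m)[j], beta = fit$beta, se = fit$se,
               odds_ratio = fit$odds_ratio, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p_value = fit$p,
               mean_cancer = smry$mean_cancer, sd_cancer = smry$sd_cancer,
               mean_benign = smry$mean_benign, sd_benign = smry$sd_benign,
               direction = smry$direction, separated = fit$separated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out$significant <- !is.na(out$q_value) & out$q_value < q_threshold
  rownames(out) <- NULL
  class(out) <- c("rppa_stats", "data.frame")
  attr(out, "n_failed") <- sum(!ok)
  out
}
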