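#' Recursive maximum margin criterion discriminant analysis
#'
#' Supervised dimensionality reduction for two-class (or multi-class)
#' profiles. The maximum margin criterion seeks directions `w` maximizing
#' `w' (S_b - S_w) w`, where `S_b` and `S_w` are the between- and
#' within-class scatter matrices of the (optionally standardized,
#' mean-centered) data. Unlike classical LDA it requires no inversion of
#' `S_w`, so it is well defined when features outnumber samples. Components
#' are extracted recursively: the leading eigenvector of the symmetrized
#' `S_b - S_w` is taken, the data are deflated by projecting that direction
#' out, the scatters are recomputed, and the next component extracted, `k`
#' times. Class assignment is by nearest class mean in score space.
#'
#' @param x numeric matrix, samples x features.
#' @param labels factor (or coercible) of class labels, one per row;
#'   every class needs at least two samples.
#' @param k number of components (default 1; must not exceed
#'   `min(ncol(x), nrow(x) - 1)`).
#' @param standardize scale features to unit variance before fitting
#'   (default `FALSE`: with a few dozen patients and hundreds of features,
#'   giving every feature equal scatter weight lets the margin criterion
#'   overfit sampling noise, while on the intensity scale the scatter is
#'   concentrated in the high-intensity lipids that carry the signal;
#'   zero-variance features are left unscaled when enabled).
#' @return an object of class `"rmmc"`: list with `projection` (features x k,
#'   unit-norm orthogonal columns), `center`, `scale`, `class_means` (class x
#'   k score means), `scatter_between`, `scatter_within`, `scores`, `labels`,
#'   `levels`, `k`, `margin` (criterion value per component).
#' @seealso [predict.rmmc()], [lopo_cv()], [metrics()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100, 0), 20), matrix(rnorm(100, 1), 20))
#' fit <- rmmc(x, rep(c("a", "b"), each = 20))
#' table(predict(fit, x)$class)
#' @export
rmmc <- function(x, labels, k = 1, standardize = FALSE) {
  rmmc_impl(x, labels, k = k, standardize = standardize, min_per_class = 2L)
}

# min_per_class = 1 is used by LOPO folds: a singleton training class is
# well defined (it contributes zero within-class scatter) even though a
# top-level fit rejects it.
rmmc_impl <- function(x, labels, k, standardize, min_per_class) {
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x); p <- ncol(x)
  if (length(labels) != n) stop("labels must have one entry per row", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two classes", call. = FALSE)
  if (any(tab < min_per_class)) {
    stop(sprintf("degenerate class '%s' (fewer than %d samples)",
                 names(tab)[which(tab < min_per_class)[1]], min_per_class),
         call. = FALSE)
  }
  if (!is_count(k) || k < 1 || k > min(p, n - 1)) {
    stop(sprintf("k must be between 1 and min(features, samples - 1) = %d",
                 min(p, n - 1)), call. = FALSE)
  }

  center <- colMeans(x)
  scl <- if (standardize) {
    s <- apply(x, 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    s
  } else {
    rep(1, p)
  }
  xs <- sweep(sweep(x, 2, center), 2, scl, `/`)

  scatters <- function(z) {
    mu <- colMeans(z)
    sb <- matrix(0, ncol(z), ncol(z))
    sw <- matrix(0, ncol(z), ncol(z))
    for (lv in levels(labels)) {
      zi <- z[labels == lv, , drop = FALSE]
      mi <- colMeans(zi)
      d <- mi - mu
      sb <- sb + nrow(zi) * tcrossprod(d)
      sw <- sw + crossprod(sweep(zi, 2, mi))
    }
    list(sb = sb, sw = sw)
  }

  sc0 <- scatters(xs)
  W <- matrix(0, p, k)
  margin <- numeric(k)
  z <- xs
  for (j in seq_len(k)) {
    sc <- if (j == 1) sc0 else scatters(z)
    m <- sc$sb - sc$sw
    m <- (m + t(m)) / 2
    if (j == 1) {
      w <- eigen(m, symmetric = TRUE)$vectors[, 1]
    } else {
      # solve the eigenproblem restricted to the orthogonal complement of
      # the components found so far (a deflated component has eigenvalue 0
      # and would otherwise be re-selected once the spectrum turns negative)
      prev <- W[, seq_len(j - 1), drop = FALSE]
      q <- qr.Q(qr(cbind(prev, diag(p))))[, j:p, drop = FALSE]
      mq <- crossprod(q, m %*% q)
      mq <- (mq + t(mq)) / 2
      w <- drop(q %*% eigen(mq, symmetric = TRUE)$vectors[, 1])
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) stop("deflated scatter is degenerate; reduce k", call. = FALSE)
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w # deterministic sign
    W[, j] <- w
    margin[j] <- drop(crossprod(w, m %*% w))
    z <- z - z %*% tcrossprod(w)
  }

  scores <- xs %*% W
  class_means <- rowsum(scores, labels) / as.vector(tab)
  structure(
    list(projection = W, center = center, scale = scl, standardize = standardize,
         class_means = class_means, scatter_between = sc0$sb,
         scatter_within = sc0$sw, scores = scores, labels = labels,
         levels = levels(labels), k = k, margin = margin,
         feature_names = colnames(x), call = match.call()),
    class = "rmmc"
  )
}

#' Predict class membership from a fitted RMMC model
#'
#' Projects new profiles onto the fitted components and assigns each to the
#' class with the nearest class-mean score (Euclidean). Ties break toward
#' the first class level in the model's declared order.
#'
#' @param object an `rmmc` fit.
#' @param newdata numeric matrix (or single profile vector) with the model's
#'   feature count.
#' @param ... unused.
#' @return `list(class = factor of assignments, scores = projected
#'   coordinates)`.
#' @export
predict.rmmc <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    stop(sprintf("profile has %d features; model expects %d",
                 ncol(newdata), length(object$center)), call. = FALSE)
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  scores <- xs %*% object$projection
  d2 <- vapply(seq_along(object$levels), function(i) {
    rowSums(sweep(scores, 2, object$class_means[object$levels[i], ])^2)
  }, numeric(nrow(scores)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  cls <- factor(object$levels[apply(d2, 1, which.min)], levels = object$levels)
  list(class = cls, scores = scores)
}

#' @export
print.rmmc <- function(x, ...) {
  cat("Recursive maximum margin criterion discriminant fit\n")
  cat(sprintf("  %d samples, %d features, %d component(s)\n",
              length(x$labels), nrow(x$projection), x$k))
  cat(sprintf("  classes: %s\n", paste(sprintf(
    "%s (n=%d)", x$levels, as.vector(table(x$labels))), collapse = ", ")))
  cat(sprintf("  margin criterion per component: %s\n",
              paste(signif(x$margin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.rmmc <- function(object, ...) {
  # resubstitution performance on the training scores
  d2 <- vapply(object$levels, function(lv) {
    rowSums(sweep(object$scores, 2, object$class_means[lv, ])^2)
  }, numeric(nrow(object$scores)))
  cls <- factor(object$levels[apply(d2, 1, which.min)], levels = object$levels)
  out <- list(fit = object,
              resubstitution = table(truth = object$labels, predicted = cls))
  class(out) <- "summary.rmmc"
  out
}

#' @export
print.summary.rmmc <- function(x, ...) {
  print(x$fit)
  cat("Resubstitution confusion:\n")
  print(x$resubstitution)
  invisible(x)
}

#' @export
coef.rmmc <- function(object, ...) {
  w <- object$projection
  rownames(w) <- object$feature_names
  colnames(w) <- paste0("MMC", seq_len(ncol(w)))
  w
}

#' Scores plot of an RMMC fit
#'
#' Component-1 scores per class (stripchart), or component 1 vs 2 when the
#' model has two or more components.
#'
#' @param x an `rmmc` fit.
#' @param ... passed to the underlying plot.
#' @export
plot.rmmc <- function(x, ...) {
  if (x$k >= 2) {
    graphics::plot(x$scores[, 1], x$scores[, 2], col = as.integer(x$labels),
                   pch = 19, xlab = "MMC1", ylab = "MMC2", ...)
    graphics::legend("topright", legend = x$levels,
                     col = seq_along(x$levels), pch = 19)
  } else {
    graphics::stripchart(x$scores[, 1] ~ x$labels, vertical = TRUE,
                         method = "jitter", pch = 19, ylab = "MMC1 score", ...)
  }
  invisible(x)
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient, all of that patient's rows are held out, the model is
#' refit on the remaining patients, and the held-out rows are predicted; the
#' patient-level call is the majority vote over the patient's rows (ties
#' toward the first class level). Patient-level calls are aggregated into a
#' confusion matrix with `positive` as the positive class.
#'
#' @param x samples x features matrix.
#' @param labels class label per row.
#' @param patient_ids patient identifier per row; rows sharing an id are
#'   held out jointly.
#' @param k,standardize passed to [rmmc()].
#' @param positive positive class for the confusion matrix (default
#'   `"cancer"` when present, else the second level).
#' @return object of class `rmmc_cv`: list with `confusion` (a
#'   `confusion_matrix`), `predictions` (per-patient data.frame with truth,
#'   call and component-1 score), and `folds` (audit log: held-out patient
#'   and training size per fold).
#' @export
lopo_cv <- function(x, labels, patient_ids, k = 1, standardize = FALSE,
                    positive = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != nrow(x)) {
    stop("patient_ids must align with rows", call. = FALSE)
  }
  positive <- positive %||% if ("cancer" %in% levels(labels)) "cancer" else levels(labels)[2]
  patients <- unique(patient_ids)
  truth <- character(length(patients))
  call_ <- character(length(patients))
  score1 <- numeric(length(patients))
  folds <- data.frame(patient = patients, n_train = NA_integer_,
                      leaked = NA, stringsAsFactors = FALSE)
  for (i in seq_along(patients)) {
    test <- patient_ids == patients[i]
    train_lab <- droplevels(labels[!test])
    if (nlevels(train_lab) < nlevels(droplevels(labels))) {
      stop(sprintf("class vanishes from training fold when holding out patient '%s'",
                   patients[i]), call. = FALSE)
    }
    fit <- rmmc_impl(x[!test, , drop = FALSE], labels[!test], k = k,
                     standardize = standardize, min_per_class = 1L)
    pr <- predict(fit, x[test, , drop = FALSE])
    votes <- table(factor(pr$class, levels = levels(labels)))
    call_[i] <- names(votes)[which.max(votes)]
    truth_i <- unique(as.character(labels[test]))
    if (length(truth_i) != 1) {
      stop(sprintf("patient '%s' carries conflicting labels", patients[i]), call. = FALSE)
    }
    truth[i] <- truth_i
    score1[i] <- mean(pr$scores[, 1])
    folds$n_train[i] <- sum(!test)
    folds$leaked[i] <- any(patient_ids[!test] == patients[i])
  }
  stopifnot(!any(folds$leaked))
  cm <- confusion_matrix(factor(truth, levels = levels(labels)),
                         factor(call_, levels = levels(labels)), positive)
  structure(
    list(confusion = cm,
         predictions = data.frame(patient = patients, truth = truth,
                                  predicted = call_, score = score1,
                                  stringsAsFactors = FALSE),
         folds = folds, positive = positive, k = k),
    class = "rmmc_cv"
  )
}

#' @export
print.rmmc_cv <- function(x, ...) {
  cat(sprintf("Leave-one-patient-out cross-validation (%d patients, k = %d)\n",
              nrow(x$predictions), x$k))
  print(x$confusion)
  m <- metrics(x$confusion)
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              m["sensitivity"], m["specificity"], m["accuracy"]))
  invisible(x)
}

#' Two-class confusion matrix
#'
#' @param truth,predicted factors with identical levels.
#' @param positive the positive class (e.g. `"cancer"`).
#' @return object of class `confusion_matrix`: list with counts `tp`, `fn`,
#'   `tn`, `fp` and the positive class.
#' @export
confusion_matrix <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  pos_t <- truth == positive
  pos_p <- predicted == positive
  structure(
    list(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
         tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p),
         positive = positive),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(
                truth = c(x$positive, paste0("not_", x$positive)),
                predicted = c(x$positive, paste0("not_", x$positive))))
  print(m)
  invisible(x)
}

#' Diagnostic performance metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy from a
#' confusion matrix (or a cross-validation result).
#'
#' @param cm a [confusion_matrix()] or `rmmc_cv` object.
#' @return named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
metrics <- function(cm) {
  if (inherits(cm, "rmmc_cv")) cm <- cm$confusion
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    stop("metrics undefined: one class is empty", call. = FALSE)
  }
  c(sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$tn + cm$fp),
    accuracy = (cm$tp + cm$tn) / (cm$tp + cm$fn + cm$tn + cm$fp))
}
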