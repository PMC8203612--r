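#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the probability a random positive
#' scores above a random negative, with half credit for ties (computed via
#' midranks, equivalent to trapezoidal integration over the tie-grouped
#' curve).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary reference labels (0/1 or logical).
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  check_binary(scores, labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) summation: thresholds descend over the
#' distinct scores, and each block of newly predicted positives contributes
#' its recall increment times the precision after including the whole block.
#' Not trapezoidal — PR interpolation conventions differ, this one is the
#' standard average-precision form.
#'
#' @inheritParams roc_auc
#' @return Scalar AUC in (0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  check_binary(scores, labels)
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; tp <- 0; fp <- 0
  for (t in thr) {
    in_block <- scores == t
    tp_new <- sum(labels[in_block] == 1)
    fp <- fp + sum(labels[in_block] == 0)
    tp <- tp + tp_new
    if (tp_new > 0) ap <- ap + (tp_new / n_pos) * (tp / (tp + fp))
  }
  ap
}

check_binary <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  if (!all(labels %in% 0:1) || length(unique(labels)) < 2) {
    stop("labels must contain both classes (0 and 1)", call. = FALSE)
  }
}

#' Operating point maximizing the F1 score
#'
#' Scans all distinct scores as thresholds (predict positive when
#' score >= threshold) and returns the threshold with the best F1, breaking
#' ties toward the higher threshold, together with the sensitivity,
#' specificity and accuracy of the thresholded predictions.
#'
#' @inheritParams roc_auc
#' @return Tibble with one row: threshold, f1, sensitivity, specificity,
#'   accuracy.
#' @export
best_f1_operating_point <- function(scores, labels) {
  labels <- as.integer(labels)
  check_binary(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    tn <- sum(pred == 0 & labels == 0)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    # strict > keeps the earliest (= highest) threshold on ties
    if (is.null(best) || f1 > best$f1) {
      best <- tibble::tibble(threshold = t, f1 = f1,
                             sensitivity = tp / (tp + fn),
                             specificity = tn / (tn + fp),
                             accuracy = (tp + tn) / length(labels))
    }
  }
  best
}

#' Confusion matrix of grade-group predictions
#'
#' @param reference,predicted Integer grade groups in `0..(k-1)`.
#' @param k Number of classes (6: benign plus grade groups 1-5).
#' @return `k x k` integer matrix, rows = reference, columns = predicted.
#' @export
confusion_matrix <- function(reference, predicted, k = 6) {
  stopifnot(length(reference) == length(predicted))
  lv <- 0:(k - 1)
  if (!all(reference %in% lv) || !all(predicted %in% lv)) {
    stop("grade groups must be in 0..", k - 1, call. = FALSE)
  }
  m <- table(factor(reference, levels = lv), factor(predicted, levels = lv))
  m <- unclass(m)
  dimnames(m) <- list(reference = lv, predicted = lv)
  m
}

#' Cohen's kappa, unweighted or quadratically weighted
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' expected agreement from the marginal products. Quadratic weighting scores
#' agreement between classes i and j as \eqn{w_{ij} = 1 - (i-j)^2/(K-1)^2},
#' applied to both the observed and the expected proportions, so
#' near-diagonal disagreements are forgiven in proportion to squared class
#' distance. The confidence interval uses the large-sample standard error
#' \eqn{SE = \sqrt{p_o(1-p_o)} / ((1-p_e)\sqrt{n})} (the McHugh
#' presentation), with the analogous weighted form — a documented choice —
#' for weighted kappa, and a normal quantile at the requested level.
#'
#' @param cm Square confusion matrix of counts (see [confusion_matrix()]).
#' @param weighting `"none"` or `"quadratic"`.
#' @param level Confidence level (default 0.95).
#' @return A `kappa_result`: list with `estimate`, `ci_low`, `ci_high`,
#'   `weighting`, `se`, `n`.
#' @export
cohens_kappa <- function(cm, weighting = c("none", "quadratic"),
                         level = 0.95) {
  weighting <- match.arg(weighting)
  cm <- as.matrix(cm)
  K <- nrow(cm)
  stopifnot(ncol(cm) == K)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  p <- cm / n
  w <- if (weighting == "quadratic" && K > 1) {
    1 - (outer(seq_len(K), seq_len(K), "-"))^2 / (K - 1)^2
  } else {
    diag(K)
  }
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  est <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  se <- if (pe == 1) 0 else sqrt(po * (1 - po) / n) / (1 - pe)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = est,
                 ci_low = max(-1, est - z * se),
                 ci_high = min(1, est + z * se),
                 weighting = weighting, se = se, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s): %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$weighting, x$estimate, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Normal-approximation binomial confidence interval for an accuracy
#'
#' \eqn{p \pm z\sqrt{p(1-p)/n}}, clipped to \[0, 1\].
#'
#' @param correct Number of correct predictions.
#' @param total Total predictions (> 0).
#' @param level Confidence level.
#' @return Tibble with estimate, ci_low, ci_high.
#' @export
accuracy_ci <- function(correct, total, level = 0.95) {
  stopifnot(total > 0, correct >= 0, correct <= total)
  p <- correct / total
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / total)
  tibble::tibble(estimate = p,
                 ci_low = max(0, p - half),
                 ci_high = min(1, p + half))
}

#' Evaluate grade-group predictions
#'
#' Computes the full agreement report between reference and predicted grade
#' groups: accuracy with its normal-approximation binomial interval, Cohen's
#' kappa with and without quadratic weighting (with their large-sample
#' intervals), and the confusion matrix.
#'
#' @param predictions Data frame with `reference` and `predicted` integer
#'   grade-group columns (as returned by [grade_slides()]).
#' @param k Number of classes.
#' @return A `grading_eval` object.
#' @export
evaluate_predictions <- function(predictions, k = 6) {
  cm <- confusion_matrix(predictions$reference, predictions$predicted, k)
  n <- sum(cm)
  structure(list(
    confusion = cm,
    n = n,
    accuracy = accuracy_ci(sum(diag(cm)), n),
    kappa = cohens_kappa(cm, "none"),
    kappa_quad = cohens_kappa(cm, "quadratic")
  ), class = "grading_eval")
}

#' @export
print.grading_eval <- function(x, ...) {
  cat(sprintf("Grade-group agreement on %d slides\n", x$n))
  cat(sprintf("  accuracy:   %5.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * x$accuracy$estimate, 100 * x$accuracy$ci_low,
              100 * x$accuracy$ci_high))
  cat(sprintf("  kappa:      %.3f (95%% CI %.3f-%.3f)\n",
              x$kappa$estimate, x$kappa$ci_low, x$kappa$ci_high))
  cat(sprintf("  kappa_quad: %.3f (95%% CI %.3f-%.3f)\n",
              x$kappa_quad$estimate, x$kappa_quad$ci_low, x$kappa_quad$ci_high))
  cat("  confusion matrix (rows = reference):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Point estimates and intervals for accuracy and both kappas, plus the
#' confusion matrix. The weighted-kappa interval uses the package's
#' documented weighted standard-error form; the report flags this.
#'
#' @param eval A `grading_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(eval, path) {
  out <- list(
    n = eval$n,
    accuracy = as.list(eval$accuracy),
    kappa = eval$kappa[c("estimate", "ci_low", "ci_high")],
    kappa_quad = c(eval$kappa_quad[c("estimate", "ci_low", "ci_high")],
                   list(ci_note = "weighted-kappa CI uses the analogous weighted SE form")),
    confusion = unname(apply(eval$confusion, 1, as.integer, simplify = FALSE))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
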