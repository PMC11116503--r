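# Classifier performance metrics, implemented to the stated contracts:
# ROC-AUC as the probability of correct pairwise ranking (ties 0.5) and
# PR-AUC by step-wise interpolation over score thresholds.

#' ROC AUC (pairwise-ranking probability)
#'
#' Equals the probability that a random positive outranks a random negative,
#' with ties counted 0.5 (rank statistic).
#'
#' @param y 0/1 labels.
#' @param p scores.
#' @return scalar AUC.
#' @export
roc_auc <- function(y, p) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes required to compute ROC-AUC")
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

curve_points <- function(y, p) {
  ord <- order(p, decreasing = TRUE)
  y <- as.integer(y)[ord]; p <- p[ord]
  # one point per distinct threshold (ties grouped)
  grp <- !duplicated(p)
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(which(grp)[-1] - 1, length(y))
  tibble(threshold = p[grp], tp = tp[last], fp = fp[last],
         n1 = sum(y), n0 = sum(1 - y))
}

#' Precision-recall AUC (step-wise interpolation)
#'
#' Average-precision form: the sum over thresholds of the recall increment
#' times the precision at that threshold.
#'
#' @inheritParams roc_auc
#' @return scalar AUC.
#' @export
pr_auc <- function(y, p) {
  cp <- curve_points(y, p)
  if (cp$n1[1] == 0 || cp$n0[1] == 0) {
    abort("both classes required to compute PR-AUC")
  }
  recall <- cp$tp / cp$n1
  precision <- cp$tp / (cp$tp + cp$fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate classifier scores
#'
#' @inheritParams roc_auc
#' @return an `rnasm_eval` list with `roc_auc`, `pr_auc`, and point lists
#'   `roc` (fpr, tpr) and `pr` (recall, precision).
#' @export
evaluate_classifier <- function(y, p) {
  cp <- curve_points(y, p)
  if (cp$n1[1] == 0 || cp$n0[1] == 0) {
    abort("both classes required for evaluation")
  }
  roc <- tibble(threshold = c(Inf, cp$threshold),
                fpr = c(0, cp$fp / cp$n0),
                tpr = c(0, cp$tp / cp$n1))
  pr <- tibble(threshold = cp$threshold,
               recall = cp$tp / cp$n1,
               precision = cp$tp / (cp$tp + cp$fp))
  structure(list(roc_auc = roc_auc(y, p), pr_auc = pr_auc(y, p),
                 roc = roc, pr = pr),
            class = "rnasm_eval")
}

#' @export
print.rnasm_eval <- function(x, ...) {
  cat(sprintf("<rnasm_eval> ROC-AUC %.4f, PR-AUC %.4f\n",
              x$roc_auc, x$pr_auc))
  invisible(x)
}

#' @export
glance.rnasm_eval <- function(x, ...) {
  tibble(roc_auc = x$roc_auc, pr_auc = x$pr_auc)
}

#' Plot ROC and PR curves
#' @param object an `rnasm_eval`.
#' @param which `"roc"` or `"pr"`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rnasm_eval <- function(object, which = "roc", ...) {
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = 3) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    subtitle = sprintf("ROC-AUC = %.3f", object$roc_auc))
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "recall", y = "precision",
                    subtitle = sprintf("PR-AUC = %.3f", object$pr_auc))
  }
}
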