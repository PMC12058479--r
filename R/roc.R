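#' ROC curve and rank-based AUC
#'
#' `roc_points()` returns the operating points of the receiver operating
#' characteristic at every distinct score threshold (sensitivity against
#' 1 - specificity, classifying `score >= threshold` as positive).
#' `roc_auc()` computes the area under the curve in its Mann–Whitney
#' concordance form from midranks, so tied scores count one half — the AUC
#' equals the probability that a random event report scores above a random
#' non-event report, ties split evenly.
#'
#' @param score Numeric vector of risk scores (e.g. fitted probabilities).
#' @param y Binary outcome vector (0/1) of the same length.
#' @return `roc_points()`: a tibble with columns `threshold`, `tpr`,
#'   `fpr`, prepended with the (0, 0) corner; `roc_auc()`: a single number
#'   in `[0, 1]`.
#' @export
roc_auc <- function(score, y) {
  check_roc_input(score, y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(score)   # midranks: ties count 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
roc_points <- function(score, y) {
  check_roc_input(score, y)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  yy <- y[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each threshold
  tp <- cumsum(yy)[last]
  fp <- cumsum(1 - yy)[last]
  tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp / sum(y == 1)),
    fpr = c(0, fp / sum(y == 0))
  )
}

#' @rdname roc_auc
#' @param fit A `logistic_fit` object.
#' @return `model_roc()`: list with `points` (tibble) and `auc`.
#' @export
model_roc <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  list(points = roc_points(fit$fitted, fit$y),
       auc = roc_auc(fit$fitted, fit$y))
}

check_roc_input <- function(score, y) {
  if (length(score) != length(y)) abort("score and y lengths differ")
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1")
  if (length(unique(y)) < 2) {
    abort("ROC needs both outcome classes present")
  }
  invisible(TRUE)
}

#' @rdname roc_auc
#' @param ... Unused.
#' @export
plot_roc <- function(score, y, ...) {
  pts <- roc_points(score, y)
  auc <- roc_auc(score, y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", auc)) +
    ggplot2::theme_minimal()
}
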