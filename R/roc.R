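#' ROC curve of a per-photo score against a gold standard
#'
#' Sweeps the decision threshold over all distinct values of the score
#' (typically the crowd's vote fraction) and records the true- and
#' false-positive fractions relative to the gold standard. Tied scores
#' are grouped into a single step, producing diagonal segments; with
#' this convention the trapezoidal area equals the Mann-Whitney
#' estimator exactly.
#'
#' @param scores numeric per-photo classifier scores.
#' @param labels gold-standard labels: logical, 0/1, or
#'   `"present"`/`"absent"` strings. Must contain both classes.
#' @param positive label counted as positive when `labels` is character.
#' @return object of class `roc_points`: data frame with columns
#'   `threshold` (score cut-off; a photo is called positive when
#'   `score >= threshold`), `fpf`, `tpf`, beginning at (0, 0) and ending
#'   at (1, 1); attributes `n_pos`, `n_neg`.
#' @examples
#' roc_points(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
#' @export
roc_points <- function(scores, labels, positive = "present") {
  y <- as_binary_labels(labels, positive)
  if (length(scores) != length(y)) stop_pc("scores and labels differ in length")
  if (anyNA(scores)) stop_pc("scores must not be missing")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop_pc("AUC undefined: gold standard has only one class")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!y & scores >= t), numeric(1))
  out <- data.frame(threshold = c(Inf, thr),
                    fpf = c(0, fp / n_neg),
                    tpf = c(0, tp / n_pos))
  structure(out, class = c("roc_points", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

as_binary_labels <- function(labels, positive = "present") {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop_pc("numeric labels must be 0/1")
    return(labels == 1)
  }
  as.character(labels) == positive
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the tie-grouped ROC curve. By construction
#' this equals the Mann-Whitney two-sample statistic
#' `(#\{score_pos > score_neg\} + 0.5 #\{ties\}) / (n_pos * n_neg)`:
#' the probability a random positive photo outscores a random negative
#' one, with ties counted half. An AUC of 1 is perfect correspondence
#' with the gold standard; 0.5 is chance.
#'
#' @param x an `roc_points` object, or raw numeric scores (then `labels`
#'   is required).
#' @param labels,positive as in [roc_points()] when `x` is raw scores.
#' @param ... unused.
#' @return object of class `auc_estimate`: list with `auc`, `n_pos`,
#'   `n_neg`.
#' @examples
#' auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.roc_points <- function(x, ...) {
  a <- sum(diff(x$fpf) * (head(x$tpf, -1) + x$tpf[-1]) / 2)
  structure(list(auc = a, n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg")),
            class = "auc_estimate")
}

#' @rdname auc
#' @export
auc.default <- function(x, labels, positive = "present", ...) {
  auc(roc_points(x, labels, positive = positive))
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d positive, %d negative photos)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}
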