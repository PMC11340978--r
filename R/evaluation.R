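#' ROC curve and AUC by threshold sweep
#'
#' Standard ROC construction: scores are swept from high to low, tied
#' scores are grouped into a single point, and the area under the curve is
#' computed by the trapezoidal rule (equal to the concordant-pair
#' Mann-Whitney statistic with ties counted half).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return A `roc_curve` list: `points` data frame (`threshold`, `fpr`,
#'   `tpr`), `auc`. The points run from (0, 0) (threshold above all scores)
#'   to (1, 1).
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes present (", n_pos, " positives, ",
         n_neg, " negatives)")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores: cumulative counts at each distinct score
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last_of_group]
  fp <- cumsum(1L - l)[last_of_group]
  pts <- data.frame(
    threshold = c(Inf, s[last_of_group]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.4f (%d pos / %d neg, %d points)>\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Vertical averaging of ROC curves
#'
#' Evaluates every curve's TPR at a common grid of FPR values by linear
#' interpolation along the curve (vertical segments at tied FPRs evaluate
#' to their upper end) and reports the per-grid-point mean and standard
#' deviation. Vertical (rather than threshold) averaging is used because
#' the individual classifiers' scores need not be calibrated against each
#' other.
#'
#' @param curves List of `roc_curve` objects (>= 1).
#' @param fpr_grid Grid of FPR values (default 0 to 1 in steps of 0.01).
#' @return Data frame with `fpr`, `tpr_mean`, `tpr_sd`, plus attribute
#'   `auc_mean` (trapezoidal area under the mean curve).
#' @export
vertical_average <- function(curves, fpr_grid = seq(0, 1, by = 0.01)) {
  if (length(curves) == 0L) stop("no curves to average")
  tpr_mat <- vapply(curves, function(cv) {
    roc_tpr_at(cv$points, fpr_grid)
  }, numeric(length(fpr_grid)))
  tpr_mat <- matrix(tpr_mat, nrow = length(fpr_grid))
  out <- data.frame(
    fpr = fpr_grid,
    tpr_mean = rowMeans(tpr_mat),
    tpr_sd = apply(tpr_mat, 1L, stats::sd)
  )
  if (length(curves) == 1L) out$tpr_sd <- 0
  attr(out, "auc_mean") <- sum(diff(out$fpr) *
    (utils::head(out$tpr_mean, -1) + utils::tail(out$tpr_mean, -1)) / 2)
  out
}

# Evaluate a ROC curve's TPR at arbitrary FPR values. The curve is the
# piecewise-linear path through its points; at an FPR with a vertical
# segment the attainable (upper) TPR is returned, and between distinct
# FPRs the segment runs from the upper TPR of the left FPR to the lower
# TPR of the right FPR, tracing the true threshold sweep rather than the
# chord that tie-collapsing interpolation would cut.
roc_tpr_at <- function(points, x) {
  xs <- unique(points$fpr)
  top <- vapply(xs, function(v) max(points$tpr[points$fpr == v]), numeric(1))
  bot <- vapply(xs, function(v) min(points$tpr[points$fpr == v]), numeric(1))
  j <- findInterval(x, xs)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (j[i] == 0L) {
      out[i] <- bot[1L]
    } else if (j[i] >= length(xs) || x[i] == xs[j[i]]) {
      out[i] <- top[min(j[i], length(xs))]
    } else {
      x0 <- xs[j[i]]; x1 <- xs[j[i] + 1L]
      out[i] <- top[j[i]] + (bot[j[i] + 1L] - top[j[i]]) * (x[i] - x0) / (x1 - x0)
    }
  }
  out
}

#' Operating-point selection on a ROC curve
#'
#' `"youden"` returns the curve point maximising sensitivity + specificity
#' (the Youden index); `"high_sensitivity"` returns the point with the best
#' specificity among those with sensitivity at or above `sensitivity_floor`,
#' for screening-style deployment. Ties are broken towards the lowest
#' threshold.
#'
#' @param curve A `roc_curve`.
#' @param mode `"youden"` or `"high_sensitivity"`.
#' @param sensitivity_floor Minimum sensitivity for the high-sensitivity
#'   mode (default 0.80).
#' @return List with `sensitivity`, `specificity`, `threshold`.
#' @export
operating_point <- function(curve, mode = c("youden", "high_sensitivity"),
                            sensitivity_floor = 0.80) {
  mode <- match.arg(mode)
  pts <- curve$points
  sens <- pts$tpr
  spec <- 1 - pts$fpr
  if (mode == "youden") {
    j <- sens + spec
    best <- which(j == max(j))
  } else {
    ok <- which(sens >= sensitivity_floor)
    if (length(ok) == 0L) ok <- which(sens == max(sens))
    best <- ok[spec[ok] == max(spec[ok])]
  }
  i <- best[length(best)]   # lowest threshold among ties (points sorted desc)
  list(sensitivity = sens[i], specificity = spec[i],
       threshold = pts$threshold[i])
}

#' One-vs-rest precision, recall and F1 per grade
#'
#' Computes per-grade precision, recall, F1 and support from decoded and
#' true grades. Cells with a zero denominator (no predictions, or no true
#' members, of a grade) are reported as 0 and flagged in `undefined`.
#'
#' @param decoded_grades Integer predictions in 0..3.
#' @param true_grades Integer truth in 0..3.
#' @return Data frame with one row per grade 0..3: `grade`, `precision`,
#'   `recall`, `f1` (all in percent), `support`, `undefined`.
#' @export
per_class_metrics <- function(decoded_grades, true_grades) {
  stopifnot(length(decoded_grades) == length(true_grades),
            all(decoded_grades %in% 0:3), all(true_grades %in% 0:3))
  cm <- table(factor(true_grades, levels = 0:3),
              factor(decoded_grades, levels = 0:3))
  out <- data.frame(grade = 0:3, precision = 0, recall = 0, f1 = 0,
                    support = as.integer(rowSums(cm)), undefined = FALSE)
  for (g in 0:3) {
    i <- g + 1L
    tp <- cm[i, i]
    pred_n <- sum(cm[, i])
    true_n <- sum(cm[i, ])
    prec <- if (pred_n > 0) tp / pred_n else NA_real_
    rec <- if (true_n > 0) tp / true_n else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    out$undefined[i] <- any(is.na(c(prec, rec, f1)))
    out$precision[i] <- 100 * ifelse(is.na(prec), 0, prec)
    out$recall[i] <- 100 * ifelse(is.na(rec), 0, rec)
    out$f1[i] <- 100 * ifelse(is.na(f1), 0, f1)
  }
  out
}

#' Average per-class metrics across runs
#'
#' Applies [per_class_metrics()] to each run's predictions and reports the
#' per-grade mean and standard deviation of every metric across runs.
#'
#' @param per_run List of data frames as returned by [per_class_metrics()].
#' @return Data frame with per-grade mean/sd columns for precision, recall,
#'   F1 and support.
#' @export
summarise_per_class <- function(per_run) {
  stopifnot(length(per_run) >= 1L)
  agg <- function(col, f) {
    apply(vapply(per_run, function(d) d[[col]], numeric(4)), 1L, f)
  }
  data.frame(
    grade = 0:3,
    precision_mean = agg("precision", mean), precision_sd = agg("precision", stats::sd),
    recall_mean = agg("recall", mean), recall_sd = agg("recall", stats::sd),
    f1_mean = agg("f1", mean), f1_sd = agg("f1", stats::sd),
    support_mean = agg("support", mean), support_sd = agg("support", stats::sd)
  )
}

#' Drop post-operative encounters from test metrics
#'
#' The grading pipeline is a screening tool for new cases, so encounters
#' recorded after corrective surgery are excluded from reported test
#' metrics (they remain usable for training).
#'
#' @param predictions Data frame with a logical `post_op` column.
#' @return The filtered data frame.
#' @export
exclude_post_op <- function(predictions) {
  stopifnot("post_op" %in% names(predictions))
  kept <- predictions[!predictions$post_op, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("all encounters are post-operative; no test rows remain")
  }
  kept
}

#' Plot a vertically averaged ROC curve
#'
#' Draws the mean ROC with a +/- 1 SD band and the chance diagonal.
#'
#' @param avg Output of [vertical_average()].
#' @param main Plot title.
#' @return `avg`, invisibly.
#' @export
plot_mean_roc <- function(avg, main = "Mean ROC (vertical averaging)") {
  graphics::plot(avg$fpr, avg$tpr_mean, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = main, xlim = c(0, 1), ylim = c(0, 1))
  graphics::polygon(c(avg$fpr, rev(avg$fpr)),
                    c(pmin(avg$tpr_mean + avg$tpr_sd, 1),
                      rev(pmax(avg$tpr_mean - avg$tpr_sd, 0))),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(avg$fpr, avg$tpr_mean, lwd = 2)
  graphics::abline(0, 1, lty = 2)
  invisible(avg)
}
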