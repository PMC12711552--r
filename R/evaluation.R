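#' Confusion-matrix metric panel
#'
#' Accuracy, sensitivity, specificity, PPV and NPV with AC as the
#' positive class. Ratios with zero denominators are reported as `NA`
#' rather than 0.
#'
#' @param y_true,y_pred Character vectors of `"SCC"`/`"AC"`, same length.
#' @param positive Positive class (default `"AC"`).
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `tp`, `fp`, `tn`, `fn`, `n_pos`, `n_neg`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = "AC") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  list(accuracy = sdiv(tp + tn, tp + tn + fp + fn),
       sensitivity = sdiv(tp, tp + fn),
       specificity = sdiv(tn, tn + fp),
       ppv = sdiv(tp, tp + fp),
       npv = sdiv(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn,
       n_pos = tp + fn, n_neg = tn + fp)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random positive scores
#' above a random negative, with ties counted one half. Computed from
#' mid-ranks, so it is exact including ties.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param y_true Character labels (`"SCC"`/`"AC"`) or 0/1.
#' @param positive Positive class label (default `"AC"`).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, y_true, positive = "AC") {
  pos <- if (is.numeric(y_true)) y_true == 1 else
    as.character(y_true) == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUROC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples at the case level (so clustered slides stay together),
#' recomputes the metric on each resample, and returns the 2.5/97.5
#' percentile bounds. Resamples that collapse to a single class are
#' redrawn, with the redraw count recorded.
#'
#' @param metric_fn Function of a data.frame returning one number.
#' @param data A data.frame; one row per observation.
#' @param case_ids Grouping vector for resampling (default: row-level
#'   resampling).
#' @param B Bootstrap replicates (default 2000, minimum 200).
#' @param seed Integer seed (default 0).
#' @param conf Confidence level (default 0.95).
#' @return List with `lo`, `hi`, `replicates` and `n_redrawn`; the
#'   bounds collapse to the point value for a constant metric.
#' @export
bootstrap_ci <- function(metric_fn, data, case_ids = NULL, B = 2000L,
                         seed = 0L, conf = 0.95) {
  stopifnot(B >= 200)
  if (is.null(case_ids)) case_ids <- seq_len(nrow(data))
  cases <- unique(case_ids)
  rows_of <- split(seq_len(nrow(data)), factor(case_ids, levels = cases))
  old <- .subtyper_seed_state(seed)
  on.exit(.subtyper_restore_seed(old), add = TRUE)
  stats_b <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- unlist(rows_of[sample.int(length(cases), replace = TRUE)],
                    use.names = FALSE)
      v <- tryCatch(metric_fn(data[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
      if (!is.na(v)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 50L * B) stop("bootstrap: too many degenerate resamples")
    }
    stats_b[b] <- v
  }
  a <- (1 - conf) / 2
  q <- stats::quantile(stats_b, c(a, 1 - a), names = FALSE, type = 7)
  list(lo = q[1], hi = q[2], replicates = stats_b, n_redrawn = n_redrawn)
}

# structural components of the Mann-Whitney kernel
.delong_components <- function(scores, pos) {
  xs <- scores[pos]; ys <- scores[!pos]
  m <- length(xs); n <- length(ys)
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), theta = mean(psi))
}

#' DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors computed on the same cases
#' using the structural-components estimator of the variance of the
#' paired AUROC difference, with a two-sided normal-approximation
#' p-value.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param y_true Labels (`"SCC"`/`"AC"` or 0/1).
#' @param positive Positive class (default `"AC"`).
#' @return List with `auroc_a`, `auroc_b`, `z`, `p` and `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, y_true, positive = "AC") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y_true)) {
    stop("delong_test: score and label vectors must be paired")
  }
  pos <- if (is.numeric(y_true)) y_true == 1 else
    as.character(y_true) == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ca <- .delong_components(scores_a, pos)
  cb <- .delong_components(scores_b, pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$theta - cb$theta
  z <- if (var_diff <= 0) 0 else d / sqrt(var_diff)
  list(auroc_a = ca$theta, auroc_b = cb$theta, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' Calibration curve
#'
#' Bins predicted probabilities into equal-width bins and compares the
#' mean prediction with the observed positive fraction per bin; empty
#' bins are omitted.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param y_true Labels (`"SCC"`/`"AC"` or 0/1).
#' @param n_bins Number of bins (default 10).
#' @param positive Positive class (default `"AC"`).
#' @return data.frame of class `calibration_curve`: `bin_mid`,
#'   `mean_predicted`, `observed_fraction`, `bin_count`.
#' @export
calibration <- function(probs, y_true, n_bins = 10L, positive = "AC") {
  stopifnot(all(probs >= 0 & probs <= 1))
  y <- if (is.numeric(y_true)) y_true else
    as.numeric(as.character(y_true) == positive)
  idx <- pmin(floor(probs * n_bins) + 1L, n_bins)
  out <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    data.frame(bin_mid = (b - 0.5) / n_bins,
               mean_predicted = mean(probs[sel]),
               observed_fraction = mean(y[sel]),
               bin_count = sum(sel))
  }))
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability t:
#' `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)`, where a case is called positive
#' when its predicted probability is at least t. The treat-all reference
#' is `prevalence - (1 - prevalence) * t/(1-t)`; treat-none is 0.
#'
#' @param probs Predicted probabilities.
#' @param y_true Labels (`"SCC"`/`"AC"` or 0/1).
#' @param thresholds Threshold grid in (0, 1)
#'   (default `seq(0.01, 0.99, 0.01)`).
#' @param positive Positive class (default `"AC"`).
#' @return data.frame of class `decision_curve`: `threshold`,
#'   `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probs, y_true,
                           thresholds = seq(0.01, 0.99, by = 0.01),
                           positive = "AC") {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  y <- if (is.numeric(y_true)) y_true else
    as.numeric(as.character(y_true) == positive)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(t) {
    call_pos <- probs >= t
    sum(call_pos & y == 1) / n - sum(call_pos & y == 0) / n * t / (1 - t)
  }, numeric(1))
  out <- data.frame(threshold = thresholds, net_benefit = nb,
                    treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
                    treat_none = 0)
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' Full slide-level evaluation report
#'
#' The Table-style metric panel (accuracy, sensitivity, specificity, PPV,
#' NPV, AUROC) with case-level percentile-bootstrap 95% confidence
#' intervals.
#'
#' @param y_true True labels.
#' @param probs Predicted AC probabilities.
#' @param case_ids Case grouping for the bootstrap (default: one case per
#'   row).
#' @param threshold Label threshold (default 0.5).
#' @param B Bootstrap replicates (default 2000).
#' @param seed Integer seed (default 0).
#' @param positive Positive class (default `"AC"`).
#' @return Object of class `eval_report`: a data.frame with one row per
#'   metric (`estimate`, `lo`, `hi`), plus attributes `n_pos`, `n_neg`.
#' @export
eval_report <- function(y_true, probs, case_ids = NULL, threshold = 0.5,
                        B = 2000L, seed = 0L, positive = "AC") {
  y_true <- as.character(y_true)
  y_pred <- ifelse(probs >= threshold, positive,
                   setdiff(c("SCC", "AC"), positive))
  data <- data.frame(y = y_true, p = probs, stringsAsFactors = FALSE)
  metric_fns <- list(
    accuracy = function(d) confusion_metrics(d$y, ifelse(d$p >= threshold,
      positive, setdiff(c("SCC", "AC"), positive)), positive)$accuracy,
    sensitivity = function(d) confusion_metrics(d$y, ifelse(d$p >= threshold,
      positive, setdiff(c("SCC", "AC"), positive)), positive)$sensitivity,
    specificity = function(d) confusion_metrics(d$y, ifelse(d$p >= threshold,
      positive, setdiff(c("SCC", "AC"), positive)), positive)$specificity,
    ppv = function(d) confusion_metrics(d$y, ifelse(d$p >= threshold,
      positive, setdiff(c("SCC", "AC"), positive)), positive)$ppv,
    npv = function(d) confusion_metrics(d$y, ifelse(d$p >= threshold,
      positive, setdiff(c("SCC", "AC"), positive)), positive)$npv,
    auroc = function(d) auroc(d$p, d$y, positive))
  cm <- confusion_metrics(y_true, y_pred, positive)
  rows <- lapply(names(metric_fns), function(nm) {
    est <- tryCatch(metric_fns[[nm]](data), error = function(e) NA_real_)
    ci <- if (is.na(est)) list(lo = NA_real_, hi = NA_real_) else
      bootstrap_ci(metric_fns[[nm]], data, case_ids = case_ids, B = B,
                   seed = seed)
    data.frame(metric = nm, estimate = est, lo = ci$lo, hi = ci$hi)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_pos") <- cm$n_pos
  attr(out, "n_neg") <- cm$n_neg
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Slide-level evaluation (positive class AC; %d pos / %d neg)\n",
              attr(x, "n_pos"), attr(x, "n_neg")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %.3f (%.3f, %.3f)\n", x$metric[i], x$estimate[i],
                x$lo[i], x$hi[i]))
  }
  invisible(x)
}

#' Plot an ROC curve
#' @param scores Scores; @param y_true labels; @param positive positive
#'   class; @param ... passed to [graphics::plot()].
#' @return Invisibly, the data.frame of (fpr, tpr) points.
#' @export
plot_roc <- function(scores, y_true, positive = "AC", ...) {
  pos <- as.character(y_true) == positive
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[ord]) / sum(pos))
  fpr <- c(0, cumsum(!pos[ord]) / sum(!pos))
  graphics::plot(fpr, tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(data.frame(fpr = fpr, tpr = tpr))
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$mean_predicted, x$observed_fraction, type = "b",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "mean predicted probability",
                 ylab = "observed fraction", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
plot.decision_curve <- function(x, ...) {
  graphics::plot(x$threshold, x$net_benefit, type = "l",
                 xlab = "threshold probability", ylab = "net benefit",
                 ylim = range(c(x$net_benefit, x$treat_all, 0)), ...)
  graphics::lines(x$threshold, x$treat_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = 1:3, bty = "n")
  invisible(x)
}
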