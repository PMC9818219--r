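# Slide-level evaluation: ROC/AUC, log-loss, threshold metrics, percentile
# bootstrap confidence intervals, and the equal-balance / clinical-balance
# test-split builders.
#
# The positive-call convention is "score >= threshold" throughout, and the
# ROC is swept over all distinct scores with sentinels above the maximum
# (nothing called positive) and at 0 (everything called positive).

as_scored <- function(scored) {
  stopifnot(all(c("score", "true_label") %in% names(scored)))
  if (any(scored$score < 0 | scored$score > 1)) stopf("scores must lie in [0,1]")
  scored$y <- as.numeric(scored$true_label == "neoplastic")
  scored
}

#' ROC curve by threshold sweep
#'
#' @param scored data.frame with columns `score` (in [0,1]) and `true_label`
#'   ("negative"/"neoplastic").
#' @return a `roc_curve`: descending `thresholds` with `fpr` and `tpr`,
#'   starting at (0,0) and ending at (1,1).
#' @export
roc_curve <- function(scored) {
  scored <- as_scored(scored)
  P <- sum(scored$y == 1); N <- sum(scored$y == 0)
  if (P == 0 || N == 0) stopf("ROC undefined: both labels must be present")
  o <- order(scored$score, decreasing = TRUE)
  s <- scored$score[o]; y <- scored$y[o]
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each distinct score
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  thresholds <- c(max(s) + 1, s[last])
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  if (thresholds[length(thresholds)] > 0) {  # sentinel at 0: everything positive
    thresholds <- c(thresholds, 0)
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr),
            class = "roc_curve")
}

#' Area under a ROC curve (trapezoidal)
#' @param curve a `roc_curve`.
#' @return AUC in [0,1].
#' @export
auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Slide-level AUC of scored slides
#' @param scored as in [roc_curve()].
#' @return AUC.
#' @export
auc_scored <- function(scored) auc(roc_curve(scored))

#' Mean binary cross-entropy of scored slides
#'
#' Probabilities are clipped to [1e-15, 1 - 1e-15] so degenerate scores stay
#' finite.
#'
#' @param scored as in [roc_curve()].
#' @return log-loss >= 0.
#' @export
log_loss <- function(scored) {
  scored <- as_scored(scored)
  p <- clamp(scored$score, 1e-15, 1 - 1e-15)
  -mean(scored$y * log(p) + (1 - scored$y) * log(1 - p))
}

#' Accuracy, sensitivity and specificity at a decision threshold
#'
#' Positive call iff score >= threshold.
#'
#' @param scored as in [roc_curve()].
#' @param threshold decision threshold (default 0.5).
#' @return list(accuracy, sensitivity, specificity).
#' @export
threshold_metrics <- function(scored, threshold = 0.5) {
  scored <- as_scored(scored)
  call_pos <- scored$score >= threshold
  tp <- sum(call_pos & scored$y == 1); fn <- sum(!call_pos & scored$y == 1)
  tn <- sum(!call_pos & scored$y == 0); fp <- sum(call_pos & scored$y == 0)
  if (tp + fn == 0) stopf("sensitivity undefined: no positive slides")
  if (tn + fp == 0) stopf("specificity undefined: no negative slides")
  list(accuracy = (tp + tn) / nrow(scored),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Percentile bootstrap confidence interval of a slide-level metric
#'
#' Resamples slides with replacement `n_iter` times and takes the
#' (alpha/2, 1-alpha/2) percentiles. Resamples on which the metric is
#' undefined (e.g. single-class draws for AUC) are discarded and redrawn.
#'
#' @param scored as in [roc_curve()].
#' @param metric function(scored) -> numeric, e.g. [auc_scored()].
#' @param n_iter bootstrap iterations (default 1000).
#' @param alpha 1 - confidence level (default 0.05).
#' @param seed RNG seed; same seed, same interval.
#' @return c(lo, hi).
#' @export
bootstrap_ci <- function(scored, metric, n_iter = 1000, alpha = 0.05, seed = 1) {
  stopifnot(nrow(scored) > 0)
  n <- nrow(scored)
  with_seed(seed, {
    vals <- numeric(n_iter)
    max_attempts <- 100 * n_iter
    attempts <- 0
    i <- 1
    while (i <= n_iter) {
      attempts <- attempts + 1
      if (attempts > max_attempts) stopf("metric undefined on virtually all bootstrap resamples")
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric(scored[idx, , drop = FALSE]), error = function(e) NA_real_)
      if (is.na(v)) next
      vals[i] <- v
      i <- i + 1
    }
    unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), type = 7))
  })
}

# ---- test-split designs ---------------------------------------------------

#' Specification of a test-split design
#'
#' `equal_balance` draws as many negatives as neoplastics (1:1);
#' `clinical_balance` draws `negative_to_neoplastic_ratio` negatives per
#' neoplastic slide (default 10:1, the reported clinical prevalence regime).
#' Optional per-class quotas (named counts over classes I-V) are honoured
#' exactly.
#'
#' @param design "equal_balance" or "clinical_balance".
#' @param n_neoplastic neoplastic slides in the split.
#' @param negative_to_neoplastic_ratio integer ratio >= 1 (clinical design).
#' @param class_quotas optional named integer vector over "I".."V".
#' @return a `split_spec`.
#' @export
split_spec <- function(design = c("equal_balance", "clinical_balance"),
                       n_neoplastic, negative_to_neoplastic_ratio = 10,
                       class_quotas = NULL) {
  design <- match.arg(design)
  if (negative_to_neoplastic_ratio < 1) stopf("ratio must be >= 1")
  n_negative <- if (design == "equal_balance") n_neoplastic
                else n_neoplastic * negative_to_neoplastic_ratio
  if (!is.null(class_quotas)) {
    if (!all(names(class_quotas) %in% cytology_classes())) stopf("quota names must be classes I-V")
    neg_q <- sum(class_quotas[names(class_quotas) %in% c("I", "II")])
    neo_q <- sum(class_quotas[names(class_quotas) %in% c("III", "IV", "V")])
    if (neg_q != n_negative || neo_q != n_neoplastic) {
      stopf("class quotas (neg %d, neo %d) must sum to the design totals (neg %d, neo %d)",
            neg_q, neo_q, n_negative, n_neoplastic)
    }
  }
  structure(list(design = design, n_neoplastic = n_neoplastic,
                 n_negative = n_negative,
                 negative_to_neoplastic_ratio = negative_to_neoplastic_ratio,
                 class_quotas = class_quotas),
            class = "split_spec")
}

#' Draw a test split from a slide pool
#'
#' Seeded sampling without replacement; per-class quotas, when given, are
#' honoured exactly. A pool too small for the request fails with an error
#' naming the deficient class.
#'
#' @param pool data.frame of slide records with `cytology_class` (and
#'   `slide_id`).
#' @param spec a [split_spec()].
#' @param seed RNG seed.
#' @return the selected records with `split` set to "test".
#' @export
build_test_split <- function(pool, spec, seed = 1) {
  pool$binary_label <- vapply(pool$cytology_class, binary_label, character(1))
  take <- function(sub, n, what) {
    if (nrow(sub) < n) {
      stopf("pool shortfall for %s: need %d, have %d", what, n, nrow(sub))
    }
    sub[sample.int(nrow(sub), n), , drop = FALSE]
  }
  with_seed(seed, {
    picked <- if (!is.null(spec$class_quotas)) {
      do.call(rbind, lapply(names(spec$class_quotas), function(cls) {
        take(pool[pool$cytology_class == cls, , drop = FALSE],
             spec$class_quotas[[cls]], sprintf("class %s", cls))
      }))
    } else {
      rbind(take(pool[pool$binary_label == "negative", , drop = FALSE],
                 spec$n_negative, "negative (classes I-II)"),
            take(pool[pool$binary_label == "neoplastic", , drop = FALSE],
                 spec$n_neoplastic, "neoplastic (classes III-V)"))
    }
    picked$split <- "test"
    picked[order(picked$slide_id), , drop = FALSE]
  })
}

# ---- report orchestration --------------------------------------------------

metric_functions <- function(threshold) {
  list(
    roc_auc = auc_scored,
    log_loss = log_loss,
    accuracy = function(s) threshold_metrics(s, threshold)$accuracy,
    sensitivity = function(s) threshold_metrics(s, threshold)$sensitivity,
    specificity = function(s) threshold_metrics(s, threshold)$specificity
  )
}

#' Slide-level metrics report with bootstrap confidence intervals
#'
#' Joins predictions to the manifest's test slides, computes ROC-AUC,
#' log-loss, accuracy, sensitivity and specificity, each with a percentile
#' bootstrap 95% CI.
#'
#' @param predictions data.frame(slide_id, score) or path to a
#'   predictions.csv.
#' @param manifest manifest data.frame or path; only `split == "test"` rows
#'   are evaluated (all rows if no test split is present).
#' @param threshold decision threshold for the thresholded metrics.
#' @param n_bootstrap bootstrap iterations.
#' @param seed RNG seed.
#' @return a `metrics_report`: per-metric list(point, lo, hi) plus metadata.
#' @export
evaluate_predictions <- function(predictions, manifest, threshold = 0.5,
                                 n_bootstrap = 1000, seed = 1) {
  if (is.character(predictions)) predictions <- utils::read.csv(predictions, stringsAsFactors = FALSE)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  test <- if (any(manifest$split == "test")) manifest[manifest$split == "test", ] else manifest
  missing <- setdiff(test$slide_id, predictions$slide_id)
  if (length(missing)) {
    stopf("missing prediction(s) for slide(s): %s", paste(missing, collapse = ", "))
  }
  scored <- merge(test[, c("slide_id", "cytology_class")], predictions, by = "slide_id")
  scored$true_label <- vapply(scored$cytology_class, binary_label, character(1))
  fns <- metric_functions(threshold)
  metrics <- lapply(seq_along(fns), function(i) {
    point <- fns[[i]](scored)
    ci <- bootstrap_ci(scored, fns[[i]], n_iter = n_bootstrap, seed = seed + i)
    list(point = point, lo = ci[1], hi = ci[2])
  })
  names(metrics) <- names(fns)
  structure(list(metrics = metrics, n_slides = nrow(scored),
                 n_bootstrap = n_bootstrap, decision_threshold = threshold,
                 curve = roc_curve(scored), scored = scored),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Slide-level metrics (n = %d, threshold %.2f, %d bootstrap iterations)\n",
              x$n_slides, x$decision_threshold, x$n_bootstrap))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-12s %.3f [%.3f-%.3f]\n", nm, m$point, m$lo, m$hi))
  }
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report a `metrics_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report[c("metrics", "n_slides", "n_bootstrap",
                                "decision_threshold")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a ROC curve to a PNG file
#' @param curve a `roc_curve` (or `metrics_report`).
#' @param path output PNG path.
#' @export
plot_roc <- function(curve, path) {
  if (inherits(curve, "metrics_report")) curve <- curve$curve
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(curve$fpr, curve$tpr, type = "l", lwd = 2, col = "steelblue",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", auc(curve)))
  graphics::abline(0, 1, lty = 3, col = "gray")
  invisible(path)
}
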