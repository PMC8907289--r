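#' Confusion counts with Grade II as the positive class
#'
#' A subject is predicted Grade II when its Grade-II probability is greater
#' than or equal to the threshold (ties go to the positive class). True
#' positives are pathologic Grade II subjects correctly called Grade II.
#'
#' @param predictions numeric Grade-II probabilities.
#' @param labels aligned labels, `"I"`/`"II"` (factor or character).
#' @param threshold decision threshold on the Grade-II probability.
#' @return a `confusion_counts`: list with `tp`, `fp`, `tn`, `fn`,
#'   `positive_class = "II"`.
#' @export
confusion_from_predictions <- function(predictions, labels,
                                       threshold = 0.5) {
  labels <- as.character(labels)
  if (length(predictions) != length(labels))
    stop("confusion_from_predictions: length mismatch")
  if (!all(labels %in% c("I", "II")))
    stop("confusion_from_predictions: labels must be 'I' or 'II'")
  pred2 <- predictions >= threshold
  structure(list(tp = sum(pred2 & labels == "II"),
                 fp = sum(pred2 & labels == "I"),
                 tn = sum(!pred2 & labels == "I"),
                 fn = sum(!pred2 & labels == "II"),
                 positive_class = "II"),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' accuracy = (tp+tn)/total; sensitivity = tp/(tp+fn) (fraction of Grade II
#' called II); specificity = tn/(tn+fp) (fraction of Grade I called I).
#' A metric with a zero denominator is returned as `NA` (flagged undefined),
#' never as 0.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/tn/fn).
#' @return named numeric: accuracy, sensitivity, specificity.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) stop("compute_metrics: negative counts")
  total <- tp + fp + tn + fn
  if (total == 0) stop("compute_metrics: no evaluated subjects")
  c(accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' ROC curve and AUC
#'
#' The ROC is traced by sweeping the decision threshold over the unique
#' predicted probabilities; the AUC is the trapezoidal integral, which
#' equals the Mann-Whitney rank statistic (ties counted 1/2).
#'
#' @param predictions numeric Grade-II probabilities.
#' @param labels aligned `"I"`/`"II"` labels; both classes must be present.
#' @return list with `auc` and `roc` (data.frame threshold, fpr, tpr).
#' @export
roc_auc <- function(predictions, labels) {
  labels <- as.character(labels)
  if (length(predictions) != length(labels))
    stop("roc_auc: length mismatch")
  pos <- labels == "II"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc: both classes must be present")
  thr <- c(Inf, sort(unique(predictions), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(predictions >= t & pos) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(predictions >= t & !pos) / n0,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Per-metric min and max over folds
#'
#' @param per_fold data.frame or matrix of per-fold metric values (one row
#'   per fold, named columns). Undefined (`NA`) fold values are excluded
#'   with a warning.
#' @return data.frame with columns metric, min, max.
#' @export
fold_ranges <- function(per_fold) {
  per_fold <- as.data.frame(per_fold)
  if (nrow(per_fold) < 1) stop("fold_ranges: need at least one fold")
  out <- lapply(names(per_fold), function(m) {
    v <- per_fold[[m]]
    if (anyNA(v)) {
      warning("fold_ranges: excluding undefined values for ", m)
      v <- v[!is.na(v)]
    }
    if (!length(v)) stop("fold_ranges: all fold values undefined for ", m)
    data.frame(metric = m, min = min(v), max = max(v))
  })
  do.call(rbind, out)
}

#' Accuracy stratified by a categorical covariate (e.g. tumor location)
#'
#' @param predictions numeric Grade-II probabilities.
#' @param labels aligned `"I"`/`"II"` labels.
#' @param strata aligned stratum labels.
#' @param threshold decision threshold.
#' @param digits rounding of the reported accuracy (default 2, the report
#'   convention); full precision kept in `accuracy_full`.
#' @return data.frame with stratum, n, n_correct, accuracy, accuracy_full.
#' @export
stratified_accuracy <- function(predictions, labels, strata,
                                threshold = 0.5, digits = 2) {
  labels <- as.character(labels)
  strata <- as.character(strata)
  if (length(predictions) != length(labels) ||
      length(labels) != length(strata))
    stop("stratified_accuracy: length mismatch")
  correct <- (predictions >= threshold) == (labels == "II")
  out <- lapply(unique(strata), function(s) {
    i <- strata == s
    data.frame(stratum = s, n = sum(i), n_correct = sum(correct[i]),
               accuracy = round(mean(correct[i]), digits),
               accuracy_full = mean(correct[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Volume-ratio summary of misclassified subjects
#'
#' Lists R = V_T1CE / V_T2FLAIR for every misclassified subject, split by
#' true grade, together with cohort summary statistics (mean, SD, median,
#' IQR with linear-interpolation quantiles).
#'
#' @param predictions numeric Grade-II probabilities.
#' @param labels aligned `"I"`/`"II"` labels.
#' @param r_values aligned R ratios.
#' @param threshold decision threshold.
#' @return list with `misclassified_grade1`, `misclassified_grade2`
#'   (R values), and `cohort` (mean, sd, median, iqr).
#' @export
misclassified_r_summary <- function(predictions, labels, r_values,
                                    threshold = 0.5) {
  labels <- as.character(labels)
  if (length(predictions) != length(labels) ||
      length(labels) != length(r_values))
    stop("misclassified_r_summary: length mismatch")
  pred2 <- predictions >= threshold
  wrong <- pred2 != (labels == "II")
  list(misclassified_grade1 = r_values[wrong & labels == "I"],
       misclassified_grade2 = r_values[wrong & labels == "II"],
       cohort = c(mean = mean(r_values), sd = stats::sd(r_values),
                  median = stats::median(r_values),
                  iqr = stats::IQR(r_values)))
}

#' Full evaluation report for one prediction set
#'
#' Pools out-of-fold probabilities into one confusion matrix, ROC/AUC,
#' per-fold metric ranges and, when strata or R values are supplied,
#' stratified accuracies and the misclassified-R analysis.
#'
#' @param predictions data.frame with columns `subject_id`, `grade`,
#'   `p_grade2` and optionally `fold`.
#' @param strata optional stratum per subject (aligned with rows).
#' @param r_values optional R ratio per subject (aligned with rows).
#' @param threshold decision threshold.
#' @return a `metrics_report` list.
#' @export
metrics_report <- function(predictions, strata = NULL, r_values = NULL,
                           threshold = 0.5) {
  need <- c("subject_id", "grade", "p_grade2")
  if (!all(need %in% names(predictions)))
    stop("metrics_report: predictions need columns ",
         paste(need, collapse = ", "))
  counts <- confusion_from_predictions(predictions$p_grade2,
                                       predictions$grade, threshold)
  pooled <- compute_metrics(counts)
  roc <- roc_auc(predictions$p_grade2, predictions$grade)
  per_fold <- NULL
  ranges <- NULL
  if (!is.null(predictions$fold)) {
    per_fold <- do.call(rbind, lapply(split(predictions, predictions$fold),
                                      function(d) {
      m <- compute_metrics(confusion_from_predictions(d$p_grade2, d$grade,
                                                      threshold))
      data.frame(fold = d$fold[1], accuracy = m["accuracy"],
                 sensitivity = m["sensitivity"],
                 specificity = m["specificity"], row.names = NULL)
    }))
    ranges <- suppressWarnings(
      fold_ranges(per_fold[, c("accuracy", "sensitivity", "specificity")]))
  }
  out <- list(counts = counts, metrics = pooled, auc = roc$auc,
              roc = roc$roc, per_fold = per_fold, fold_ranges = ranges)
  if (!is.null(strata))
    out$per_stratum <- stratified_accuracy(predictions$p_grade2,
                                           predictions$grade, strata,
                                           threshold)
  if (!is.null(r_values))
    out$r_summary <- misclassified_r_summary(predictions$p_grade2,
                                             predictions$grade, r_values,
                                             threshold)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("accuracy %.2f  sensitivity %.2f  specificity %.2f  AUC %.2f\n",
              m["accuracy"], m["sensitivity"], m["specificity"], x$auc))
  cat(sprintf("counts: tp %d fp %d tn %d fn %d (positive = Grade II)\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  if (!is.null(x$fold_ranges)) {
    r <- x$fold_ranges
    for (i in seq_len(nrow(r)))
      cat(sprintf("  %s fold range (%.2f-%.2f)\n", r$metric[i], r$min[i],
                  r$max[i]))
  }
  invisible(x)
}

#' Plain-text comparison table over model variants
#'
#' One row per variant with pooled accuracy/sensitivity/specificity (2
#' decimals, per-fold ranges in parentheses) and AUC.
#'
#' @param reports named list of `metrics_report`s.
#' @param digits rounding (default 2).
#' @return character vector of table lines.
#' @export
format_comparison_table <- function(reports, digits = 2) {
  fmt <- function(x) formatC(round(x, digits), format = "f",
                             digits = digits)
  header <- sprintf("%-8s %-14s %-14s %-14s %5s", "model", "accuracy",
                    "sensitivity", "specificity", "AUC")
  rows <- vapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    cell <- function(metric) {
      v <- fmt(rep$metrics[metric])
      if (!is.null(rep$fold_ranges)) {
        r <- rep$fold_ranges[rep$fold_ranges$metric == metric, ]
        if (nrow(r) == 1)
          v <- sprintf("%s (%s-%s)", v, fmt(r$min), fmt(r$max))
      }
      v
    }
    sprintf("%-8s %-14s %-14s %-14s %5s", nm, cell("accuracy"),
            cell("sensitivity"), cell("specificity"), fmt(rep$auc))
  }, character(1))
  c(header, unname(rows))
}
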