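#' F1 score from precision and recall
#'
#' The harmonic mean `2 * p * r / (p + r)`, reported as 0 when both inputs
#' are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @examples
#' f1_score(0.994, 0.931) # 0.961
#' f1_score(0.92, 0.64)   # 0.75
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Score binary detections against ground truth
#'
#' Tabulates true/false positives and negatives and computes precision
#' (`tp / (tp + fp)`), recall (`tp / (tp + fn)`) and their harmonic mean F1.
#' A metric whose denominator is zero is reported as 0 and flagged in the
#' `degenerate` field.
#'
#' @param predictions,truths Logical vectors of equal, positive length.
#' @return An object of class `evaluation_report`: a list of counts (`tp`,
#'   `fp`, `fn`, `tn`), metrics (`precision`, `recall`, `f1`) and a
#'   character vector `degenerate` naming any undefined metrics.
#' @export
score_detections <- function(predictions, truths) {
  predictions <- as.logical(predictions)
  truths <- as.logical(truths)
  if (length(predictions) != length(truths)) {
    stop("`predictions` and `truths` must have equal length", call. = FALSE)
  }
  if (!length(predictions)) stop("need at least one case", call. = FALSE)
  tp <- sum(predictions & truths)
  fp <- sum(predictions & !truths)
  fn <- sum(!predictions & truths)
  tn <- sum(!predictions & !truths)
  degenerate <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "recall"); 0
  }
  f1 <- if (precision + recall > 0) f1_score(precision, recall) else {
    degenerate <- c(degenerate, "f1"); 0
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall, f1 = f1,
         degenerate = degenerate),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  if (length(x$degenerate)) {
    cat("degenerate (0/0) metrics:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC for a detector statistic
#'
#' Sweeps the trigger threshold over every unique statistic value (plus
#' -Inf and +Inf endpoints; a case triggers when its statistic is `>=` the
#' threshold) and reports the true- and false-positive rate at each
#' threshold, with the area under the curve computed by trapezoidal
#' integration. As the threshold increases both rates are non-increasing.
#'
#' @param statistics Numeric detector statistics, one per case.
#' @param truths Logical ground truth per case; both classes must occur.
#' @return A list with `roc` (data frame `threshold`, `fpr`, `tpr`, sorted
#'   by increasing threshold) and `auc`.
#' @export
roc_curve <- function(statistics, truths) {
  truths <- as.logical(truths)
  if (length(statistics) != length(truths)) {
    stop("`statistics` and `truths` must have equal length", call. = FALSE)
  }
  n_pos <- sum(truths)
  n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative case",
         call. = FALSE)
  }
  thresholds <- c(-Inf, sort(unique(statistics)), Inf)
  tpr <- vapply(thresholds, function(th) sum(statistics >= th & truths),
                numeric(1)) / n_pos
  fpr <- vapply(thresholds, function(th) sum(statistics >= th & !truths),
                numeric(1)) / n_neg
  # Trapezoid over the curve traced from (1,1) down to (0,0).
  auc <- -sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Select a trigger threshold under a false-positive-rate cap
#'
#' Among ROC points with `fpr <= max_fpr`, returns the threshold attaining
#' the highest true-positive rate; ties are broken toward lower
#' false-positive rate, then toward the higher (more conservative)
#' threshold. A cap of 0 always has a solution at the `+Inf` endpoint.
#'
#' @param roc A result of [roc_curve()], or its `roc` data frame.
#' @param max_fpr Maximum tolerated false-positive rate (e.g. 0.01).
#' @return The selected threshold.
#' @export
select_threshold <- function(roc, max_fpr) {
  pts <- if (is.data.frame(roc)) roc else roc$roc
  if (!nrow(pts)) stop("empty ROC", call. = FALSE)
  ok <- pts[pts$fpr <= max_fpr, , drop = FALSE]
  if (!nrow(ok)) {
    stop(sprintf(
      "no threshold attains a false-positive rate of %g or lower; increase the cap",
      max_fpr
    ), call. = FALSE)
  }
  ok <- ok[order(-ok$tpr, ok$fpr, -ok$threshold), , drop = FALSE]
  ok$threshold[1L]
}

#' Storage required per recording night
#'
#' For a device recording continuously: `hours * 3600 * sample_rate *
#' bytes_per_sample` bytes. The mebibyte figure uses the binary convention
#' (2^20 bytes), rounded to the nearest integer.
#'
#' @param record_hours Hours recorded per night.
#' @param sample_rate_hz Sample rate (Hz).
#' @param bytes_per_sample Bytes per sample (2 for 16-bit PCM).
#' @return A list with `bytes` and `mib`.
#' @examples
#' storage_per_night(12, 8000, 2)$mib # 659
#' @export
storage_per_night <- function(record_hours, sample_rate_hz,
                              bytes_per_sample = 2) {
  if (record_hours <= 0 || sample_rate_hz <= 0 || bytes_per_sample <= 0) {
    stop("all arguments must be positive", call. = FALSE)
  }
  bytes <- record_hours * 3600 * sample_rate_hz * bytes_per_sample
  list(bytes = bytes, mib = round(bytes / 2^20))
}

#' Expected battery lifetime under a duty cycle
#'
#' Time-weights the supply current over one sleep/listen/analyse cycle,
#' averages it over the day (the device draws the sleep current outside its
#' active hours), and divides the battery capacity by the mean draw.
#'
#' @param cycle Named list or vector with durations `sleep_s`, `listen_s`,
#'   `analyse_s` (seconds; at least one positive).
#' @param currents_ma Named list or vector with `sleep_ma`, `listen_ma`,
#'   `analyse_ma` (milliamps).
#' @param battery_mah Battery capacity in mAh.
#' @param active_hours_per_day Hours per day the duty cycle runs; the
#'   remainder is spent at the sleep current.
#' @return Expected lifetime in days.
#' @export
duty_cycle_budget <- function(cycle, currents_ma, battery_mah,
                              active_hours_per_day = 24) {
  cycle <- as.list(cycle)
  currents_ma <- as.list(currents_ma)
  dur <- c(cycle$sleep_s, cycle$listen_s, cycle$analyse_s)
  cur <- c(currents_ma$sleep_ma, currents_ma$listen_ma, currents_ma$analyse_ma)
  if (length(dur) != 3 || length(cur) != 3 || any(dur < 0) || any(cur < 0)) {
    stop("cycle durations and currents must be three non-negative values",
         call. = FALSE)
  }
  period <- sum(dur)
  if (period <= 0) stop("duty cycle period must be positive", call. = FALSE)
  if (battery_mah <= 0 || active_hours_per_day <= 0 ||
      active_hours_per_day > 24) {
    stop("invalid battery capacity or active hours", call. = FALSE)
  }
  active_mean <- sum(dur * cur) / period
  daily_mean <- (active_hours_per_day * active_mean +
                   (24 - active_hours_per_day) * currents_ma$sleep_ma) / 24
  battery_mah / daily_mean / 24
}

#' Expected false triggers over a listening period
#'
#' With one trigger opportunity per duty cycle, the expected count is
#' `hours * 3600 / cycle_period_s * fpr`.
#'
#' @param fpr Per-opportunity false-positive rate.
#' @param hours Listening hours.
#' @param cycle_period_s Duty-cycle period in seconds (sleep + listen).
#' @return Expected number of false triggers.
#' @examples
#' false_triggers(0.01, 8, 5.171) # about 56
#' @export
false_triggers <- function(fpr, hours, cycle_period_s) {
  if (cycle_period_s <= 0) stop("cycle period must be positive", call. = FALSE)
  if (fpr < 0 || fpr > 1 || hours < 0) {
    stop("`fpr` must lie in [0, 1] and `hours` be non-negative", call. = FALSE)
  }
  hours * 3600 / cycle_period_s * fpr
}

#' Match detected events against ground-truth intervals
#'
#' Event-level confusion counts: a truth interval counts as a true positive
#' when at least one detection falls within it (padded by `tol_s` on each
#' side); detections matching no interval are false positives; unmatched
#' intervals are false negatives. True negatives are not defined for
#' event-level matching and are reported as 0.
#'
#' @param events Event data frame with a `time_s` column.
#' @param truth Data frame with `onset_s` and `end_s` columns.
#' @param tol_s Matching tolerance in seconds.
#' @return An `evaluation_report` (with `tn = 0`).
#' @export
match_events <- function(events, truth, tol_s = 0.5) {
  matched_truth <- rep(FALSE, nrow(truth))
  matched_event <- rep(FALSE, nrow(events))
  for (k in seq_len(nrow(truth))) {
    hit <- events$time_s >= truth$onset_s[k] - tol_s &
      events$time_s <= truth$end_s[k] + tol_s
    if (any(hit)) {
      matched_truth[k] <- TRUE
      matched_event[hit] <- TRUE
    }
  }
  tp <- sum(matched_truth)
  fp <- sum(!matched_event)
  fn <- sum(!matched_truth)
  degenerate <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "recall"); 0
  }
  f1 <- if (precision + recall > 0) f1_score(precision, recall) else {
    degenerate <- c(degenerate, "f1"); 0
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = 0L,
         precision = precision, recall = recall, f1 = f1,
         degenerate = degenerate),
    class = "evaluation_report"
  )
}
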