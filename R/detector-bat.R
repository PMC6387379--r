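#' Bat detector configuration
#'
#' Configuration for the sliding-median ultrasonic pulse detector. Defaults
#' target a 60 kHz echolocation component at a 250 kHz sample rate: one
#' 128,000-sample partition (512 ms) is analysed per wake-up, split into 500
#' Goertzel windows of 256 samples, and a width-5 sliding window takes the
#' median of consecutive magnitudes. The sliding window must be tuned to the
#' call length: its span in samples should lie between one and two call
#' lengths, otherwise the median is dominated by background windows and
#' calls are missed.
#'
#' @param threshold Trigger threshold on the median squared magnitude
#'   (normalized-sample scale). There is no universal value: the shipped
#'   default sits at the geometric midpoint of the gap between background
#'   and call statistics on the package's synthetic 20 dB pulse fixtures,
#'   and should be recalibrated (see [roc_curve()] and
#'   [select_threshold()]) for real deployments.
#' @param centre_freq_hz Goertzel centre frequency (Hz).
#' @param bandwidth_hz Nominal bandwidth (Hz).
#' @param window_len Goertzel window length; default 256 so a partition
#'   divides into exactly 500 windows.
#' @param partition_samples Samples analysed per wake-up.
#' @param sample_rate_hz Capture sample rate (Hz).
#' @param sliding_width Number of Goertzel outputs per sliding window.
#' @param sliding_step Step between sliding windows; default
#'   `floor(sliding_width / 2)` so every output is covered at least twice.
#' @param sleep_s Sleep between listening windows in the duty cycle (s).
#' @param recording_s Length of the recording made on trigger (s).
#' @return An object of class `bat_detector_config`.
#' @export
bat_config <- function(threshold = 0.8,
                       centre_freq_hz = 60000,
                       bandwidth_hz = 4000,
                       window_len = 256,
                       partition_samples = 128000,
                       sample_rate_hz = 250000,
                       sliding_width = 5,
                       sliding_step = max(1L, sliding_width %/% 2L),
                       sleep_s = 2.0,
                       recording_s = 10.0) {
  if (partition_samples %% window_len != 0) {
    stop("`partition_samples` must be divisible by `window_len`",
         call. = FALSE)
  }
  if (sliding_step < 1 || sliding_step > sliding_width / 2) {
    stop("`sliding_step` must satisfy 1 <= step <= width / 2 so every output is processed two or more times",
         call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be non-negative", call. = FALSE)
  cfg <- structure(
    list(
      threshold = threshold,
      centre_freq_hz = centre_freq_hz,
      bandwidth_hz = bandwidth_hz,
      window_len = as.integer(window_len),
      partition_samples = as.integer(partition_samples),
      sample_rate_hz = sample_rate_hz,
      sliding_width = as.integer(sliding_width),
      sliding_step = as.integer(sliding_step),
      sleep_s = sleep_s,
      recording_s = recording_s
    ),
    class = c("bat_detector_config", "detector_config")
  )
  # A sliding window spanning more than twice a typical 5 ms call splits the
  # call across windows and the median stops responding.
  call_samples <- 0.005 * sample_rate_hz
  if (sliding_width * window_len > 2 * call_samples) {
    warning(sprintf(
      "sliding window spans %d samples, more than twice a 5 ms call (%g samples); calls may be missed",
      sliding_width * as.integer(window_len), call_samples
    ), call. = FALSE)
  }
  cfg
}

bat_goertzel_spec <- function(config) {
  goertzel_spec(config$centre_freq_hz, config$sample_rate_hz,
                bandwidth_hz = config$bandwidth_hz,
                window_len = config$window_len)
}

#' Sliding median over a magnitude series
#'
#' Moves a window of `width` values across the series in steps of `step`
#' (default half the width, so each value is covered at least twice) and
#' reports the median of each window. Only full windows are produced; the
#' final full window is always included even when the stepping would
#' overshoot it.
#'
#' @param magnitudes A `magnitude_series` or plain numeric vector.
#' @param width Window width in number of values.
#' @param step Step size (>= 1).
#' @return A data frame with columns `start` (1-based index of the first
#'   value in the window) and `median`.
#' @examples
#' sliding_median(c(0, 0, 10, 10, 10, 0, 0), width = 3, step = 1)
#' @export
sliding_median <- function(magnitudes, width, step = max(1L, width %/% 2L)) {
  v <- if (inherits(magnitudes, "magnitude_series")) magnitudes$values
       else as.numeric(magnitudes)
  if (step < 1) stop("`step` must be >= 1", call. = FALSE)
  n <- length(v)
  if (width > n) {
    warning("sliding window width exceeds series length; no windows produced",
            call. = FALSE)
    return(data.frame(start = integer(0), median = numeric(0)))
  }
  last <- n - width + 1L
  starts <- seq.int(1L, last, by = step)
  if (starts[length(starts)] != last) starts <- c(starts, last)
  med <- vapply(starts,
                function(s) stats::median(v[s:(s + width - 1L)]),
                numeric(1))
  data.frame(start = as.integer(starts), median = med)
}

# Trigger scan of a single partition's magnitudes. Returns the first sliding
# window whose median reaches the threshold (ties trigger), or NULL.
bat_partition_trigger <- function(values, config) {
  sm <- suppressWarnings(
    sliding_median(values, config$sliding_width, config$sliding_step)
  )
  hit <- which(sm$median >= config$threshold)
  if (!length(hit)) return(NULL)
  list(start = sm$start[hit[1L]], median = sm$median[hit[1L]])
}

#' Detect bat echolocation pulses in a buffer
#'
#' Splits the buffer into consecutive partitions of
#' `config$partition_samples`, extracts Goertzel magnitudes at the target
#' frequency, and runs the sliding median over each partition. The first
#' sliding window whose median reaches the threshold triggers at most one
#' event per partition (mirroring record-on-trigger firmware behaviour); the
#' event time is the partition start plus the offset of the triggering
#' window's first Goertzel output. A trailing partial partition is not
#' analysed.
#'
#' @param buffer An [audio_buffer()] at the configured sample rate.
#' @param config A [bat_config()].
#' @param verbose If `TRUE`, emit a per-partition trace of the trigger
#'   statistic for pipeline inspection.
#' @return A data frame of events with columns `time_s`, `kind`,
#'   `statistic` (the triggering median).
#' @export
detect_bat <- function(buffer, config = bat_config(), verbose = FALSE) {
  stopifnot(inherits(buffer, "audio_buffer"),
            inherits(config, "bat_detector_config"))
  if (buffer$sample_rate_hz != config$sample_rate_hz) {
    stop("buffer sample rate does not match detector configuration",
         call. = FALSE)
  }
  spec <- bat_goertzel_spec(config)
  fs <- config$sample_rate_hz
  P <- config$partition_samples
  n_part <- length(buffer$samples) %/% P
  events <- empty_events()
  for (p in seq_len(n_part)) {
    offset <- (p - 1L) * P
    part <- audio_buffer(buffer$samples[(offset + 1L):(offset + P)], fs)
    ms <- goertzel_magnitudes(part, spec)
    trig <- bat_partition_trigger(ms$values, config)
    if (verbose) {
      message(sprintf("partition %d (%.3f s): %s", p, offset / fs,
                      if (is.null(trig)) "no trigger"
                      else sprintf("trigger, median %.4g", trig$median)))
    }
    if (!is.null(trig)) {
      t0 <- (offset + (trig$start - 1L) * config$window_len) / fs
      events <- rbind(events, data.frame(
        time_s = t0, kind = "bat", statistic = trig$median,
        stringsAsFactors = FALSE
      ))
    }
  }
  events
}

#' Per-partition trigger statistics for the bat detector
#'
#' Computes, for every full partition, the maximum sliding-window median at
#' the target frequency. These statistics are what [roc_curve()] and
#' [select_threshold()] consume when calibrating the trigger threshold.
#'
#' @inheritParams detect_bat
#' @return A data frame with columns `partition`, `start_s`, `statistic`.
#' @export
bat_partition_statistics <- function(buffer, config = bat_config()) {
  stopifnot(inherits(buffer, "audio_buffer"),
            inherits(config, "bat_detector_config"))
  if (buffer$sample_rate_hz != config$sample_rate_hz) {
    stop("buffer sample rate does not match detector configuration",
         call. = FALSE)
  }
  spec <- bat_goertzel_spec(config)
  P <- config$partition_samples
  n_part <- length(buffer$samples) %/% P
  stat <- numeric(n_part)
  for (p in seq_len(n_part)) {
    offset <- (p - 1L) * P
    part <- audio_buffer(buffer$samples[(offset + 1L):(offset + P)],
                         config$sample_rate_hz)
    ms <- goertzel_magnitudes(part, spec)
    sm <- suppressWarnings(
      sliding_median(ms$values, config$sliding_width, config$sliding_step)
    )
    stat[p] <- if (nrow(sm)) max(sm$median) else 0
  }
  data.frame(
    partition = seq_len(n_part),
    start_s = (seq_len(n_part) - 1L) * P / config$sample_rate_hz,
    statistic = stat
  )
}

#' Emulate the duty-cycled bat deployment schedule offline
#'
#' Replays the device schedule against a recorded stream: sleep for
#' `sleep_s`, listen for one partition (512 ms at defaults), analyse it, and
#' on a trigger mark a `recording_s` recording window and resume listening
#' after it. At most one event is produced per listening window.
#'
#' @param stream An [audio_buffer()] at the configured sample rate.
#' @param config A [bat_config()].
#' @return A data frame of events (`time_s`, `kind`, `statistic`).
#' @export
run_duty_cycled <- function(stream, config = bat_config()) {
  stopifnot(inherits(stream, "audio_buffer"),
            inherits(config, "bat_detector_config"))
  if (stream$sample_rate_hz != config$sample_rate_hz) {
    stop("stream sample rate does not match detector configuration",
         call. = FALSE)
  }
  spec <- bat_goertzel_spec(config)
  fs <- config$sample_rate_hz
  P <- config$partition_samples
  sleep_n <- round(config$sleep_s * fs)
  rec_n <- round(config$recording_s * fs)
  n <- length(stream$samples)
  cur <- 0L
  events <- empty_events()
  repeat {
    cur <- cur + sleep_n
    if (cur + P > n) break
    part <- audio_buffer(stream$samples[(cur + 1L):(cur + P)], fs)
    ms <- goertzel_magnitudes(part, spec)
    trig <- bat_partition_trigger(ms$values, config)
    part_start <- cur
    cur <- cur + P
    if (!is.null(trig)) {
      t0 <- (part_start + (trig$start - 1L) * config$window_len) / fs
      events <- rbind(events, data.frame(
        time_s = t0, kind = "bat", statistic = trig$median,
        stringsAsFactors = FALSE
      ))
      cur <- cur + rec_n
    }
  }
  events
}

empty_events <- function() {
  data.frame(time_s = numeric(0), kind = character(0),
             statistic = numeric(0), stringsAsFactors = FALSE)
}
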