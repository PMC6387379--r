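#' Gunshot detector configuration
#'
#' Configuration for the HMM-based gunshot detector. Audio is captured at
#' 8 kHz into 16,384-sample partitions (2.048 s); each analysis span covers
#' two consecutive partitions (4.096 s, 32,768 samples), and spans overlap
#' by one partition so a gunshot straddling a partition boundary still
#' appears whole in one span. Features are Goertzel magnitudes at 400, 1200
#' and 2000 Hz with a 250 Hz bandwidth (window length 128), giving 256
#' three-band observation windows per span.
#'
#' @param model A [gunshot_hmm()]; defaults to [default_gunshot_model()].
#' @param sample_rate_hz Capture sample rate (Hz).
#' @param partition_samples Samples per circular-buffer partition.
#' @param window_len Goertzel window length.
#' @param band_freqs_hz Three feature band centres (Hz).
#' @param bandwidth_hz Bandwidth of the feature filters (Hz).
#' @param merge_window_s Events closer together than this are merged
#'   (deduplicates the overlapping double analysis); default one partition
#'   of new audio per iteration, 2.048 s.
#' @return An object of class `gunshot_detector_config`.
#' @export
gunshot_config <- function(model = default_gunshot_model(),
                           sample_rate_hz = 8000,
                           partition_samples = 16384,
                           window_len = 128,
                           band_freqs_hz = c(400, 1200, 2000),
                           bandwidth_hz = 250,
                           merge_window_s = 2.048) {
  stopifnot(inherits(model, "gunshot_hmm"))
  if (partition_samples %% window_len != 0) {
    stop("`partition_samples` must be divisible by `window_len`",
         call. = FALSE)
  }
  if (length(band_freqs_hz) != 3) {
    stop("`band_freqs_hz` must name exactly three bands", call. = FALSE)
  }
  structure(
    list(
      model = model,
      sample_rate_hz = sample_rate_hz,
      partition_samples = as.integer(partition_samples),
      window_len = as.integer(window_len),
      band_freqs_hz = band_freqs_hz,
      bandwidth_hz = bandwidth_hz,
      merge_window_s = merge_window_s
    ),
    class = c("gunshot_detector_config", "detector_config")
  )
}

gunshot_goertzel_specs <- function(config) {
  lapply(config$band_freqs_hz, function(f) {
    goertzel_spec(f, config$sample_rate_hz,
                  bandwidth_hz = config$bandwidth_hz,
                  window_len = config$window_len)
  })
}

#' Three-band Goertzel features of one analysis span
#'
#' Runs the span (two partitions, 32,768 samples at defaults) through the
#' three feature filters and zips the outputs into one three-band magnitude
#' triple per window (256 windows at defaults).
#'
#' @param buffer An [audio_buffer()] of exactly `2 * partition_samples`
#'   samples.
#' @param config A [gunshot_config()].
#' @return An `N x 3` matrix of non-negative band magnitudes, with column
#'   names giving the band centre frequencies.
#' @export
extract_features <- function(buffer, config = gunshot_config()) {
  stopifnot(inherits(buffer, "audio_buffer"),
            inherits(config, "gunshot_detector_config"))
  if (buffer$sample_rate_hz != config$sample_rate_hz) {
    stop("buffer sample rate does not match detector configuration",
         call. = FALSE)
  }
  span_len <- 2L * config$partition_samples
  if (length(buffer$samples) != span_len) {
    stop(sprintf("analysis span must contain exactly %d samples, got %d",
                 span_len, length(buffer$samples)), call. = FALSE)
  }
  specs <- gunshot_goertzel_specs(config)
  cols <- lapply(specs, function(sp) goertzel_magnitudes(buffer, sp)$values)
  feats <- do.call(cbind, cols)
  colnames(feats) <- paste0(config$band_freqs_hz, "Hz")
  feats
}

#' Decode one analysis span and test the gunshot detection rule
#'
#' Viterbi-decodes the span's feature triples and reports an event when the
#' decoded path runs through all three gunshot states in order: some
#' initial-impulse window `I`, followed (not necessarily adjacently) by a
#' decay window `D`, followed by a tail window `T`. The event time is the
#' time of the first `I` window; the decoded path is attached.
#'
#' @param buffer An [audio_buffer()] of exactly one analysis span.
#' @param config A [gunshot_config()].
#' @return A one-row event data frame (`time_s`, `kind`, `statistic`) with
#'   the decoded path in attribute `"path"`, or `NULL` when no gunshot
#'   signature is present. The statistic is the fraction of windows decoded
#'   as gunshot states.
#' @export
detect_gunshot_span <- function(buffer, config = gunshot_config()) {
  feats <- extract_features(buffer, config)
  path <- viterbi(feats, config$model)
  if (!gunshot_path_rule(path)) return(NULL)
  first_i <- which(path == "I")[1L]
  t0 <- (first_i - 1L) * config$window_len / config$sample_rate_hz
  ev <- data.frame(time_s = t0, kind = "gunshot",
                   statistic = mean(path %in% c("I", "D", "T")),
                   stringsAsFactors = FALSE)
  attr(ev, "path") <- path
  ev
}

# Ordered-containment rule: an I, later a D, later still a T.
gunshot_path_rule <- function(path) {
  i <- which(path == "I")
  if (!length(i)) return(FALSE)
  d <- which(path == "D" & seq_along(path) > i[1L])
  if (!length(d)) return(FALSE)
  any(path == "T" & seq_along(path) > d[1L])
}

#' Scan a continuous stream for gunshots
#'
#' Partitions the stream into consecutive 2.048 s partitions and analyses
#' overlapping two-partition spans (1,2), (2,3), (3,4), ... so that every
#' partition is analysed twice and a gunshot split across a partition
#' boundary still appears whole in one span — the offline equivalent of the
#' device's three-partition circular buffer. No duty cycle is applied; the
#' detector listens continuously. Events from overlapping spans that fall
#' within `merge_window_s` of each other are merged, keeping the earliest.
#'
#' @param stream An [audio_buffer()] at the configured sample rate.
#' @param config A [gunshot_config()].
#' @return A data frame of events (`time_s`, `kind`, `statistic`).
#' @export
scan_stream <- function(stream, config = gunshot_config()) {
  stopifnot(inherits(stream, "audio_buffer"),
            inherits(config, "gunshot_detector_config"))
  if (stream$sample_rate_hz != config$sample_rate_hz) {
    stop("stream sample rate does not match detector configuration",
         call. = FALSE)
  }
  P <- config$partition_samples
  fs <- config$sample_rate_hz
  n_part <- length(stream$samples) %/% P
  events <- empty_events()
  if (n_part >= 2) {
    for (i in seq_len(n_part - 1L)) {
      offset <- (i - 1L) * P
      span <- audio_buffer(stream$samples[(offset + 1L):(offset + 2L * P)], fs)
      ev <- detect_gunshot_span(span, config)
      if (!is.null(ev)) {
        ev$time_s <- ev$time_s + offset / fs
        attr(ev, "path") <- NULL
        events <- rbind(events, ev)
      }
    }
  }
  merge_events(events, config$merge_window_s)
}

# Greedy time-ordered merge: drop events within `window_s` of the last kept.
merge_events <- function(events, window_s) {
  if (nrow(events) < 2) return(events)
  events <- events[order(events$time_s), , drop = FALSE]
  keep <- logical(nrow(events))
  last <- -Inf
  for (k in seq_len(nrow(events))) {
    if (events$time_s[k] - last > window_s) {
      keep[k] <- TRUE
      last <- events$time_s[k]
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
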