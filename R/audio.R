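#' Mono audio buffer
#'
#' The unit of audio that every detector consumes: a mono sample sequence on
#' the normalized scale together with its sample rate. Samples decoded from
#' 16-bit PCM are divided by 32768, so they lie in `[-1, 1)` and all detector
#' thresholds are device-independent.
#'
#' @param samples Numeric vector of samples, each finite and in `[-1, 1)`.
#' @param sample_rate_hz Sampling rate in Hz (positive scalar).
#'
#' @return An object of class `audio_buffer`: a list with elements `samples`
#'   and `sample_rate_hz`.
#' @examples
#' buf <- audio_buffer(sin(2 * pi * 440 * (0:799) / 8000) * 0.5, 8000)
#' audio_duration(buf)
#' @export
audio_buffer <- function(samples, sample_rate_hz) {
  if (!is.numeric(samples)) {
    stop("`samples` must be numeric", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (length(samples) && (anyNA(samples) || !all(is.finite(samples)))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (length(samples) && (min(samples) < -1 || max(samples) >= 1)) {
    stop("samples must lie in [-1, 1) on the normalized 16-bit scale",
         call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a positive scalar", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "audio_buffer"
  )
}

#' @export
length.audio_buffer <- function(x) length(x$samples)

#' Duration of an audio buffer in seconds
#' @param buffer An [audio_buffer()].
#' @return Duration in seconds.
#' @export
audio_duration <- function(buffer) {
  stopifnot(inherits(buffer, "audio_buffer"))
  length(buffer$samples) / buffer$sample_rate_hz
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Split a buffer into consecutive device partitions
#'
#' Emulates the recorder's sample memory: consecutive, non-overlapping
#' partitions of `partition_samples`, in order; a trailing partial
#' partition is not yielded.
#'
#' @param buffer An [audio_buffer()].
#' @param partition_samples Samples per partition.
#' @return A data frame with columns `partition`, `start_sample` (1-based),
#'   `end_sample` and `start_s`.
#' @export
partition_stream <- function(buffer, partition_samples) {
  stopifnot(inherits(buffer, "audio_buffer"), partition_samples >= 1)
  n_part <- length(buffer$samples) %/% partition_samples
  idx <- seq_len(n_part)
  data.frame(
    partition = idx,
    start_sample = (idx - 1L) * as.integer(partition_samples) + 1L,
    end_sample = idx * as.integer(partition_samples),
    start_s = (idx - 1L) * partition_samples / buffer$sample_rate_hz
  )
}
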