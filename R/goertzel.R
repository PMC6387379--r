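#' Goertzel filter length for a target bandwidth
#'
#' The length `L` of a Goertzel filter sets its bandwidth: a window of `L`
#' samples at sample rate `fs` has a (Hamming-windowed) half-power bandwidth
#' of roughly `4 * fs / L`. The filter length that attains bandwidth `B` is
#' therefore `L = 4 * fs / B`, rounded to the nearest integer.
#'
#' Detector configurations may override the computed length with an explicit
#' `window_len`; the bat detector, for example, uses L = 256 so that its
#' 128,000-sample partition divides into exactly 500 windows.
#'
#' @param sample_rate_hz Sample rate `fs` in Hz.
#' @param bandwidth_hz Desired bandwidth `B` in Hz.
#' @return Filter length `L` (integer number of samples).
#' @examples
#' filter_length(48000, 1500) # 128
#' filter_length(8000, 250)   # 128
#' @export
filter_length <- function(sample_rate_hz, bandwidth_hz) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(bandwidth_hz) || length(bandwidth_hz) != 1L ||
      bandwidth_hz <= 0) {
    stop("`bandwidth_hz` must be a positive scalar", call. = FALSE)
  }
  len <- round(4 * sample_rate_hz / bandwidth_hz)
  if (len < 2) {
    stop("bandwidth too wide: filter length must be at least 2 samples",
         call. = FALSE)
  }
  as.integer(len)
}

#' Goertzel recurrence constant
#'
#' Precomputes the constant `c = 2 * cos(2 * pi * f / fs)` driving the
#' second-order Goertzel recurrence for target frequency `f`. For any target
#' frequency up to Nyquist, `|c| <= 2`.
#'
#' @param centre_freq_hz Target frequency `f` in Hz.
#' @param sample_rate_hz Sample rate `fs` in Hz.
#' @return The recurrence constant, a real number in `[-2, 2]`.
#' @export
goertzel_constant <- function(centre_freq_hz, sample_rate_hz) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(centre_freq_hz) || length(centre_freq_hz) != 1L ||
      centre_freq_hz < 0) {
    stop("`centre_freq_hz` must be a non-negative scalar", call. = FALSE)
  }
  if (centre_freq_hz > sample_rate_hz / 2) {
    stop(sprintf(
      "target frequency %g Hz exceeds the Nyquist frequency %g Hz",
      centre_freq_hz, sample_rate_hz / 2
    ), call. = FALSE)
  }
  2 * cos(2 * pi * centre_freq_hz / sample_rate_hz)
}

#' Hamming window coefficients
#'
#' Tapering weights `h_j = alpha - (1 - alpha) * cos(2 * pi * j / L)` for
#' `j = 1, ..., L`, applied to each window before the Goertzel recurrence to
#' limit spectral leakage. Note the denominator is `L` and the index runs
#' from 1, not the `L - 1` denominator of the textbook Hamming window; this
#' matches the filter design the detectors were calibrated against. All
#' coefficients lie in `[2 * alpha - 1, 1] = [0.08, 1]`.
#'
#' @param window_len Window length `L` (at least 2).
#' @param alpha Window shape constant, default 0.54.
#' @return Numeric vector of `L` coefficients.
#' @export
hamming_coefficients <- function(window_len, alpha = 0.54) {
  if (!is.numeric(window_len) || length(window_len) != 1L || window_len < 2) {
    stop("`window_len` must be an integer >= 2", call. = FALSE)
  }
  j <- seq_len(window_len)
  alpha - (1 - alpha) * cos(2 * pi * j / window_len)
}

#' Goertzel filter specification
#'
#' Bundles a narrowband Goertzel filter: centre frequency, bandwidth, sample
#' rate, window length and the precomputed recurrence constant and Hamming
#' coefficients. If `window_len` is omitted it is derived from the bandwidth
#' with [filter_length()]; passing it explicitly overrides that choice (as
#' the bat detector does with L = 256).
#'
#' @param centre_freq_hz Target frequency in Hz.
#' @param sample_rate_hz Sample rate in Hz.
#' @param bandwidth_hz Desired bandwidth in Hz (used to derive `window_len`
#'   when that is not given).
#' @param window_len Optional explicit window length.
#' @param alpha Hamming window shape constant.
#' @return An object of class `goertzel_spec`.
#' @examples
#' spec <- goertzel_spec(14000, 48000, bandwidth_hz = 1500)
#' spec$window_len # 128
#' @export
goertzel_spec <- function(centre_freq_hz, sample_rate_hz,
                          bandwidth_hz = NULL, window_len = NULL,
                          alpha = 0.54) {
  if (is.null(window_len)) {
    if (is.null(bandwidth_hz)) {
      stop("supply either `bandwidth_hz` or `window_len`", call. = FALSE)
    }
    window_len <- filter_length(sample_rate_hz, bandwidth_hz)
  }
  window_len <- as.integer(window_len)
  if (window_len < 2) stop("`window_len` must be >= 2", call. = FALSE)
  structure(
    list(
      centre_freq_hz = centre_freq_hz,
      bandwidth_hz = bandwidth_hz,
      sample_rate_hz = sample_rate_hz,
      window_len = window_len,
      constant = goertzel_constant(centre_freq_hz, sample_rate_hz),
      hamming = hamming_coefficients(window_len, alpha),
      alpha = alpha,
      beta = 1 - alpha
    ),
    class = "goertzel_spec"
  )
}

#' @export
print.goertzel_spec <- function(x, ...) {
  cat(sprintf("<goertzel_spec> f = %g Hz, fs = %g Hz, L = %d, c = %.5f\n",
              x$centre_freq_hz, x$sample_rate_hz, x$window_len, x$constant))
  invisible(x)
}

#' Windowed Goertzel band magnitudes
#'
#' Splits the buffer into consecutive non-overlapping windows of
#' `spec$window_len` samples and evaluates one Goertzel magnitude per window.
#' Within window `i`, the Hamming-weighted samples drive the recurrence
#' `y_j = h_j * s_j + c * y_{j-1} - y_{j-2}` (with `y_0 = y_{-1} = 0`), and
#' the reported value is the squared magnitude
#' `m_i = y_L^2 + y_{L-1}^2 - c * y_L * y_{L-1}`, identical to the squared
#' modulus of the Hamming-windowed DFT evaluated at the centre frequency. No
#' square root is taken: thresholds are calibrated on the squared scale.
#'
#' A trailing partial window (buffer length not divisible by `L`) is dropped,
#' as a partial window cannot produce a valid magnitude.
#'
#' @param buffer An [audio_buffer()] whose sample rate matches the spec.
#' @param spec A [goertzel_spec()].
#' @return An object of class `magnitude_series`: list with `values` (one
#'   non-negative magnitude per window), `window_len` and `spec`.
#' @examples
#' fs <- 48000
#' spec <- goertzel_spec(14000, fs, bandwidth_hz = 1500)
#' tone <- audio_buffer(0.5 * sin(2 * pi * 14000 * (1:8192) / fs), fs)
#' ms <- goertzel_magnitudes(tone, spec)
#' length(ms$values) # 64
#' @export
goertzel_magnitudes <- function(buffer, spec) {
  stopifnot(inherits(buffer, "audio_buffer"), inherits(spec, "goertzel_spec"))
  if (buffer$sample_rate_hz != spec$sample_rate_hz) {
    stop(sprintf(
      "buffer sample rate (%g Hz) does not match filter spec (%g Hz)",
      buffer$sample_rate_hz, spec$sample_rate_hz
    ), call. = FALSE)
  }
  n <- length(buffer$samples)
  L <- spec$window_len
  if (n == 0L) {
    return(structure(list(values = numeric(0), window_len = L, spec = spec),
                     class = "magnitude_series"))
  }
  if (L > n) {
    stop("window length exceeds buffer length", call. = FALSE)
  }
  n_win <- n %/% L
  # One recurrence step per row, vectorized across all windows at once.
  x <- matrix(buffer$samples[seq_len(n_win * L)], nrow = L) * spec$hamming
  c0 <- spec$constant
  y1 <- numeric(n_win) # y_{j-1}
  y2 <- numeric(n_win) # y_{j-2}
  for (j in seq_len(L)) {
    y <- x[j, ] + c0 * y1 - y2
    y2 <- y1
    y1 <- y
  }
  values <- y1^2 + y2^2 - c0 * y1 * y2
  # Guard against tiny negative values from floating-point cancellation.
  values[values < 0 & values > -1e-12] <- 0
  structure(list(values = values, window_len = L, spec = spec),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %d windows of %d samples at %g Hz\n",
              length(x$values), x$window_len, x$spec$centre_freq_hz))
  invisible(x)
}
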