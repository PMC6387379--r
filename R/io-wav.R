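#' Read a mono 16-bit PCM WAV file
#'
#' Decodes the RIFF/WAVE container, accepting only the uncompressed mono
#' 16-bit PCM format the field recorders write. Samples are normalized to
#' `[-1, 1)` by dividing the 16-bit integers by 32768. Other bit depths,
#' compressed formats and multi-channel files are rejected with an error
#' naming the deviation.
#'
#' @param path Path to the WAV file.
#' @return An [audio_buffer()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("unsupported format: not a RIFF container", call. = FALSE)
  }
  readBin(con, "integer", 1, size = 4, endian = "little") # total size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("unsupported format: not a WAVE file", call. = FALSE)
  }
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size %/% 2, size = 2,
                     endian = "little", signed = FALSE)
      audio_format <- fmt[1]
      n_channels <- fmt[2]
      sample_rate <- fmt[3] + fmt[4] * 65536
      bits <- fmt[8]
      if (audio_format != 1) {
        stop("unsupported format: not uncompressed PCM (format tag ",
             audio_format, ")", call. = FALSE)
      }
      if (n_channels != 1) {
        stop("unsupported format: expected mono audio, got ",
             n_channels, " channels", call. = FALSE)
      }
      if (bits != 16) {
        stop("unsupported format: expected 16-bit samples, got ",
             bits, "-bit", call. = FALSE)
      }
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
  }
  if (is.null(sample_rate) || is.null(samples)) {
    stop("unsupported format: missing fmt or data chunk", call. = FALSE)
  }
  audio_buffer(samples / 32768, sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Quantizes normalized samples back to 16-bit integers. Samples outside
#' the representable range `[-1, 1 - 2^-15]` are clamped to the extreme
#' codes with a warning.
#'
#' @param buffer An [audio_buffer()] (or list with `samples` and
#'   `sample_rate_hz`, which may exceed the normalized range and will be
#'   clamped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(buffer, path) {
  samples <- buffer$samples
  fs <- buffer$sample_rate_hz
  ints <- round(samples * 32768)
  n_clip <- sum(ints < -32768 | ints > 32767)
  if (n_clip > 0) {
    warning(sprintf("%d sample(s) outside the 16-bit range were clamped",
                    n_clip), call. = FALSE)
    ints <- pmin(pmax(ints, -32768), 32767)
  }
  n <- length(ints)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")  # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(as.integer(ints), con, size = 2, endian = "little")
  invisible(path)
}
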