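#' Specification for a synthetic acoustic fixture
#'
#' Describes a seeded, fully reproducible test signal with the spectral and
#' temporal structure each detector assumes:
#'
#' * `bat_pulse_train` — 5 ms ultrasonic echolocation pulses in white
#'   background noise at 250 kHz, modelled with the FM-CF shape of
#'   pipistrelle-type calls: a fast down-sweep (70 kHz by default) into a
#'   quasi-constant-frequency tail at the terminal frequency (60 kHz),
#'   where the call's energy dwells. A pure constant-tone pulse is
#'   available via `constant_tone = TRUE`.
#' * `cicada_buzz` — a sustained 14 kHz tone (the cicada song surrogate) in
#'   white noise at 48 kHz.
#' * `cricket_chirps` — intermittent 20 ms broad-spectrum noise bursts at
#'   one-second intervals (a dark-bush-cricket surrogate).
#' * `wind_noise` — low-pass-shaped Gaussian noise with substantial energy
#'   at both 8 and 14 kHz, the false-positive source the cicada band ratio
#'   is designed to reject.
#' * `gunshot` — a broadband impulse followed by per-band exponential
#'   decays whose time constants shrink with frequency (the 2000 Hz band
#'   dies before the 400 Hz band), lasting about one second, at 8 kHz.
#' * `background` — stationary white noise with no events.
#'
#' Signal-to-noise ratio is set in-band: the clean signal is scaled so that
#' the ratio of its RMS within the detector's analysis band (measured over
#' the event span) to the background's in-band RMS equals `snr_db`.
#'
#' @param kind One of the fixture kinds above.
#' @param duration_s Total fixture duration in seconds.
#' @param snr_db Target in-band signal-to-noise ratio in dB.
#' @param seed Integer seed; identical spec and seed give bit-identical
#'   samples.
#' @param sample_rate_hz Sample rate; defaults to the detector the kind
#'   targets (250 kHz bat, 48 kHz cicada/cricket/wind, 8 kHz gunshot).
#' @param ... Kind-specific parameters: `pulse_len_s`, `sweep_from_hz`,
#'   `pulse_freq_hz`, `fm_fraction`, `constant_tone`, `inter_pulse_s`,
#'   `pulse_times_s`; `buzz_freq_hz`, `buzz_start_s`, `buzz_dur_s`;
#'   `chirp_len_s`, `chirp_interval_s`; `ar_coef`; `onset_s`,
#'   `shot_times_s`, `impulse_s`, `decay_end_s`, `tail_end_s`,
#'   `band_taus_s`; `noise_rms`.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("bat_pulse_train", "cicada_buzz",
                                  "cricket_chirps", "wind_noise",
                                  "gunshot", "background"),
                         duration_s, snr_db = 20, seed = 1L,
                         sample_rate_hz = NULL, ...) {
  kind <- match.arg(kind)
  default_fs <- switch(kind,
    bat_pulse_train = 250000,
    cicada_buzz = 48000,
    cricket_chirps = 48000,
    wind_noise = 48000,
    gunshot = 8000,
    background = 48000
  )
  params <- list(...)
  defaults <- switch(kind,
    bat_pulse_train = list(pulse_len_s = 0.005, sweep_from_hz = 70000,
                           pulse_freq_hz = 60000, fm_fraction = 0.3,
                           constant_tone = FALSE, inter_pulse_s = 0.1,
                           pulse_times_s = NULL, noise_rms = 0.02),
    cicada_buzz = list(buzz_freq_hz = 14000, buzz_start_s = 0,
                       buzz_dur_s = NULL, noise_rms = 0.02),
    cricket_chirps = list(chirp_len_s = 0.02, chirp_interval_s = 1,
                          noise_rms = 0.02),
    wind_noise = list(ar_coef = 0.5, noise_rms = 0.05),
    gunshot = list(onset_s = 0.5, shot_times_s = NULL, impulse_s = 0.032,
                   decay_end_s = 0.30, tail_end_s = 1.0,
                   band_taus_s = c(0.35, 0.18, 0.08), noise_rms = 0.02),
    background = list(noise_rms = 0.02)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s) for kind '%s': %s",
                 kind, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(params)] <- params
  structure(
    c(list(kind = kind, duration_s = duration_s, snr_db = snr_db,
           seed = as.integer(seed),
           sample_rate_hz = if (is.null(sample_rate_hz)) default_fs
                            else sample_rate_hz),
      defaults),
    class = "fixture_spec"
  )
}

# In-band RMS of a signal via the mean Goertzel magnitude (consistent,
# arbitrary units; only ratios of these values are ever used).
band_rms <- function(x, fs, centre_hz, bandwidth_hz, window_len) {
  if (length(x) < window_len) return(0)
  spec <- goertzel_spec(centre_hz, fs, bandwidth_hz = bandwidth_hz,
                        window_len = window_len)
  # Bypass audio_buffer range checks: the unscaled clean signal may exceed 1.
  buf <- structure(list(samples = as.numeric(x), sample_rate_hz = fs),
                   class = "audio_buffer")
  sqrt(mean(goertzel_magnitudes(buf, spec)$values))
}

# The analysis band each fixture kind is calibrated against.
fixture_band <- function(spec) {
  switch(spec$kind,
    bat_pulse_train = list(f = 60000, B = 4000, L = 256),
    cicada_buzz = list(f = 14000, B = 1500, L = 128),
    cricket_chirps = list(f = 14000, B = 1500, L = 128),
    gunshot = list(f = 400, B = 250, L = 128),
    NULL
  )
}

#' Generate a synthetic fixture with ground truth
#'
#' Realises a [fixture_spec()] into audio plus machine-readable truth. The
#' generator is deterministic for a given spec and seed, never clips (peak
#' amplitude is kept at or below `1 - 2^-15`; the whole mixture is rescaled
#' if necessary, which detectors using amplitude-invariant statistics do
#' not notice), and reports the events it constructed.
#'
#' @param spec A [fixture_spec()].
#' @return An object of class `acoustic_fixture`: a list with `buffer` (an
#'   [audio_buffer()]), `events` (data frame `onset_s`, `end_s`, `kind`;
#'   zero rows for background kinds), `segments` (gunshot only: data frame
#'   `start_s`, `end_s`, `state` covering the whole fixture) and `spec`.
#' @examples
#' fx <- generate_fixture(fixture_spec("cicada_buzz", duration_s = 1,
#'                                     snr_db = 10, seed = 42))
#' nrow(fx$events)
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  local_seed(spec$seed, {
    fs <- spec$sample_rate_hz
    n <- round(spec$duration_s * fs)
    build <- switch(spec$kind,
      bat_pulse_train = build_bat_pulse_train(spec, n, fs),
      cicada_buzz = build_cicada_buzz(spec, n, fs),
      cricket_chirps = build_cricket_chirps(spec, n, fs),
      wind_noise = build_wind_noise(spec, n, fs),
      gunshot = build_gunshot(spec, n, fs),
      background = build_background(spec, n, fs)
    )
    samples <- mix_to_snr(build, spec, fs)
    peak_cap <- 1 - 2^-15
    peak <- max(abs(samples), peak_cap / 2)
    if (peak > peak_cap) samples <- samples * (peak_cap / peak)
    structure(
      list(buffer = audio_buffer(samples, fs),
           events = build$events,
           segments = build$segments,
           spec = spec),
      class = "acoustic_fixture"
    )
  })
}

#' @export
print.acoustic_fixture <- function(x, ...) {
  cat(sprintf("<acoustic_fixture> kind '%s', %.3f s @ %g Hz, %d event(s)\n",
              x$spec$kind, audio_duration(x$buffer),
              x$buffer$sample_rate_hz, nrow(x$events)))
  invisible(x)
}

# Scale the clean signal against the noise floor to hit the target in-band
# SNR, then mix. Event-free kinds pass through.
mix_to_snr <- function(build, spec, fs) {
  if (is.null(build$signal)) return(build$noise)
  band <- fixture_band(spec)
  if (is.null(band) || spec$noise_rms == 0 || !nrow(build$events)) {
    sig <- build$signal
    if (max(abs(sig)) > 0) sig <- sig * (0.5 / max(abs(sig)))
    return(sig + build$noise)
  }
  ev_idx <- unlist(lapply(seq_len(nrow(build$events)), function(k) {
    seq.int(max(1L, round(build$events$onset_s[k] * fs) + 1L),
            min(length(build$signal), round(build$events$end_s[k] * fs)))
  }))
  s_rms <- band_rms(build$signal[ev_idx], fs, band$f, band$B, band$L)
  n_rms <- band_rms(build$noise, fs, band$f, band$B, band$L)
  if (s_rms == 0) stop("degenerate fixture: no in-band signal energy",
                       call. = FALSE)
  scale <- 10^(spec$snr_db / 20) * n_rms / s_rms
  build$signal * scale + build$noise
}

build_background <- function(spec, n, fs) {
  list(signal = NULL, noise = stats::rnorm(n, sd = spec$noise_rms),
       events = data.frame(onset_s = numeric(0), end_s = numeric(0),
                           kind = character(0)),
       segments = NULL)
}

build_wind_noise <- function(spec, n, fs) {
  # AR(1)-shaped noise: a gently falling spectrum that still carries
  # substantial energy at both the 8 and 14 kHz bands.
  raw <- as.numeric(stats::filter(stats::rnorm(n), spec$ar_coef,
                                  method = "recursive"))
  raw <- raw / stats::sd(raw) * spec$noise_rms
  list(signal = NULL, noise = raw,
       events = data.frame(onset_s = numeric(0), end_s = numeric(0),
                           kind = character(0)),
       segments = NULL)
}

build_bat_pulse_train <- function(spec, n, fs) {
  n_p <- round(spec$pulse_len_s * fs)
  onsets <- spec$pulse_times_s
  if (is.null(onsets)) {
    onsets <- seq(0.05, spec$duration_s - spec$pulse_len_s - 0.01,
                  by = spec$inter_pulse_s)
  }
  t <- (seq_len(n_p) - 1) / fs
  T_p <- spec$pulse_len_s
  # individual call variation: the terminal frequency wanders a little
  # between fixtures (well inside the 4 kHz detection band)
  f_cf <- spec$pulse_freq_hz + stats::runif(1, -500, 500)
  if (spec$constant_tone) {
    freq <- rep(f_cf, n_p)
  } else {
    # FM-CF call shape: a fast down-sweep into a quasi-constant-frequency
    # tail at the terminal frequency, where the call's energy dwells.
    n_fm <- round(spec$fm_fraction * n_p)
    freq <- c(
      seq(spec$sweep_from_hz, f_cf, length.out = n_fm),
      rep(f_cf, n_p - n_fm)
    )
  }
  phase <- 2 * pi * cumsum(freq) / fs + stats::runif(1, 0, 2 * pi)
  # Amplitude grows through the FM lead-in and tapers at the tip.
  ramp_up <- round(max(1, spec$fm_fraction * n_p))
  ramp_dn <- max(1L, n_p %/% 10L)
  envelope <- rep(1, n_p)
  envelope[seq_len(ramp_up)] <- seq(0, 1, length.out = ramp_up)
  envelope[(n_p - ramp_dn + 1):n_p] <-
    seq(1, 0, length.out = ramp_dn)
  pulse <- sin(phase) * envelope
  signal <- numeric(n)
  for (on in onsets) {
    i0 <- round(on * fs)
    idx <- (i0 + 1L):(i0 + n_p)
    idx_ok <- idx[idx <= n]
    signal[idx_ok] <- signal[idx_ok] + pulse[seq_along(idx_ok)]
  }
  list(signal = signal, noise = stats::rnorm(n, sd = spec$noise_rms),
       events = data.frame(onset_s = onsets,
                           end_s = onsets + spec$pulse_len_s,
                           kind = "bat"),
       segments = NULL)
}

build_cicada_buzz <- function(spec, n, fs) {
  start <- spec$buzz_start_s
  dur <- if (is.null(spec$buzz_dur_s)) spec$duration_s - start
         else min(spec$buzz_dur_s, spec$duration_s - start)
  i0 <- round(start * fs)
  n_b <- round(dur * fs)
  t <- (seq_len(n_b) - 1) / fs
  # song-to-song variation: dominant frequency wanders a little between
  # fixtures (well inside the 1.5 kHz detection band)
  f_buzz <- spec$buzz_freq_hz + stats::runif(1, -50, 50)
  tone <- sin(2 * pi * f_buzz * t + stats::runif(1, 0, 2 * pi))
  taper_n <- min(round(0.005 * fs), n_b %/% 2)
  if (taper_n > 0) {
    ramp <- seq(0, 1, length.out = taper_n)
    tone[seq_len(taper_n)] <- tone[seq_len(taper_n)] * ramp
    tone[(n_b - taper_n + 1):n_b] <- tone[(n_b - taper_n + 1):n_b] * rev(ramp)
  }
  signal <- numeric(n)
  signal[(i0 + 1L):(i0 + n_b)] <- tone
  list(signal = signal, noise = stats::rnorm(n, sd = spec$noise_rms),
       events = data.frame(onset_s = start, end_s = start + dur,
                           kind = "cicada"),
       segments = NULL)
}

build_cricket_chirps <- function(spec, n, fs) {
  n_c <- round(spec$chirp_len_s * fs)
  onsets <- seq(0.1, spec$duration_s - spec$chirp_len_s - 0.01,
                by = spec$chirp_interval_s)
  signal <- numeric(n)
  for (on in onsets) {
    i0 <- round(on * fs)
    idx <- (i0 + 1L):(i0 + n_c)
    idx <- idx[idx <= n]
    signal[idx] <- signal[idx] + stats::rnorm(length(idx))
  }
  list(signal = signal, noise = stats::rnorm(n, sd = spec$noise_rms),
       events = data.frame(onset_s = onsets,
                           end_s = onsets + spec$chirp_len_s,
                           kind = "cricket"),
       segments = NULL)
}

build_gunshot <- function(spec, n, fs) {
  shots <- spec$shot_times_s
  if (is.null(shots)) shots <- spec$onset_s
  band_freqs <- c(400, 1200, 2000)
  taus <- spec$band_taus_s
  tail_n <- round(spec$tail_end_s * fs)
  t <- (seq_len(tail_n) - 1) / fs
  one_shot <- numeric(tail_n)
  for (b in 1:3) {
    one_shot <- one_shot +
      sin(2 * pi * band_freqs[b] * t + stats::runif(1, 0, 2 * pi)) *
      exp(-t / taus[b])
  }
  # Broadband muzzle-blast click at the onset.
  click_n <- round(spec$impulse_s * fs)
  one_shot[seq_len(click_n)] <- one_shot[seq_len(click_n)] +
    stats::rnorm(click_n) * 1.5 * exp(-t[seq_len(click_n)] / 0.01)
  signal <- numeric(n)
  for (on in shots) {
    i0 <- round(on * fs)
    idx <- (i0 + 1L):(i0 + tail_n)
    idx <- idx[idx <= n & idx >= 1L]
    signal[idx] <- signal[idx] + one_shot[seq_along(idx)]
  }
  segments <- gunshot_segments(shots, spec, n / fs)
  list(signal = signal, noise = stats::rnorm(n, sd = spec$noise_rms),
       events = data.frame(onset_s = shots,
                           end_s = pmin(shots + spec$tail_end_s, n / fs),
                           kind = "gunshot"),
       segments = segments)
}

# Ground-truth state segments covering the whole fixture: N outside shots,
# I/D/T phases within each shot.
gunshot_segments <- function(shots, spec, duration_s) {
  segs <- list()
  cursor <- 0
  for (on in sort(shots)) {
    if (on > cursor) {
      segs[[length(segs) + 1L]] <- c(cursor, on, "N")
    }
    i_end <- on + spec$impulse_s
    d_end <- on + spec$decay_end_s
    t_end <- min(on + spec$tail_end_s, duration_s)
    segs[[length(segs) + 1L]] <- c(on, i_end, "I")
    segs[[length(segs) + 1L]] <- c(i_end, d_end, "D")
    if (t_end > d_end) segs[[length(segs) + 1L]] <- c(d_end, t_end, "T")
    cursor <- t_end
  }
  if (cursor < duration_s) {
    segs[[length(segs) + 1L]] <- c(cursor, duration_s, "N")
  }
  out <- do.call(rbind, segs)
  data.frame(start_s = as.numeric(out[, 1]), end_s = as.numeric(out[, 2]),
             state = out[, 3], stringsAsFactors = FALSE)
}
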