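# One-partition fixtures with a single pulse centred at 0.25 s, plus matched
# background partitions, shared across the bat tests.
bat_fixture <- function(seed, snr_db = 20, pulse_at = 0.25) {
  generate_fixture(fixture_spec("bat_pulse_train", duration_s = 0.512,
                                snr_db = snr_db, seed = seed,
                                pulse_times_s = pulse_at))
}
bat_background <- function(seed) {
  generate_fixture(fixture_spec("background", duration_s = 0.512,
                                seed = seed, sample_rate_hz = 250000))
}

test_that("sliding median agrees with brute-force enumeration", {
  sm <- sliding_median(c(0, 0, 10, 10, 10, 0, 0), width = 3, step = 1)
  expect_equal(sm$median, c(0, 10, 10, 10, 0))
  expect_equal(sm$start, 1:5)
  # constant series: every median is the constant
  expect_equal(sliding_median(rep(4.2, 11), 5, 2)$median, rep(4.2, 4))
  # random series against the oracle, including a step that overshoots
  set.seed(3)
  for (rep in 1:10) {
    v <- runif(sample(10:40, 1))
    width <- sample(2:7, 1)
    step <- sample(1:3, 1)
    expect_equal(sliding_median(v, width, step)$median,
                 brute_sliding_median(v, width, step))
  }
})

test_that("the final full sliding window is always produced", {
  sm <- sliding_median(1:6, width = 3, step = 2)
  expect_equal(sm$start, c(1L, 3L, 4L))
})

test_that("sliding median is invariant to permutations within a window", {
  v <- c(5, 1, 9, 2, 7)
  expect_equal(sliding_median(v, 5, 2)$median,
               sliding_median(rev(v), 5, 2)$median)
})

test_that("a width wider than the series yields no windows, with a warning", {
  expect_warning(sm <- sliding_median(1:3, width = 5), "width exceeds")
  expect_equal(nrow(sm), 0)
})

test_that("configuration guards reject inconsistent sliding parameters", {
  expect_error(bat_config(partition_samples = 1000, window_len = 256),
               "divisible")
  expect_error(bat_config(sliding_width = 5, sliding_step = 3),
               "two or more times")
  expect_warning(bat_config(sliding_width = 15), "twice")
})

test_that("background noise alone never triggers at the default threshold", {
  cfg <- bat_config()
  for (seed in 1:3) {
    expect_equal(nrow(detect_bat(bat_background(seed)$buffer, cfg)), 0)
  }
})

test_that("a clean 20 dB pulse triggers once, near the pulse onset", {
  cfg <- bat_config()
  for (seed in 1:5) {
    fx <- bat_fixture(seed)
    ev <- detect_bat(fx$buffer, cfg)
    expect_equal(nrow(ev), 1)
    # half a sliding window of slack: 5 * 256 / 2 samples = 2.56 ms
    expect_lt(abs(ev$time_s - 0.25), 0.00256 + 1e-9)
    # the event statistic matches the best brute-force scan statistic region
    stats <- bat_partition_statistics(fx$buffer, cfg)
    expect_gte(stats$statistic[1], ev$statistic)
  }
})

test_that("threshold zero triggers at the first window of non-silent audio", {
  cfg <- bat_config(threshold = 0)
  fx <- bat_fixture(9)
  ev <- detect_bat(fx$buffer, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, 0)
})

test_that("buffers shorter than one partition produce no events", {
  cfg <- bat_config()
  short <- audio_buffer(numeric(1000), 250000)
  expect_equal(nrow(detect_bat(short, cfg)), 0)
  expect_error(detect_bat(audio_buffer(numeric(1000), 48000), cfg),
               "sample rate")
})

test_that("width-5 windows separate calls from background better than width-15", {
  fx <- bat_fixture(21)
  spec <- goertzel_spec(60000, 250000, bandwidth_hz = 4000, window_len = 256)
  ms <- goertzel_magnitudes(fx$buffer, spec)$values
  sep <- function(width) {
    sm <- sliding_median(ms, width)$median
    max(sm) / median(sm)
  }
  expect_gt(sep(5), sep(15))
})

test_that("a sliding window of three call-lengths misses a call that width 5 catches", {
  fx <- bat_fixture(22)
  # calibrate a matched threshold between background and call response
  cfg5 <- bat_config()
  stats_pos <- bat_partition_statistics(fx$buffer, cfg5)$statistic
  stats_neg <- bat_partition_statistics(bat_background(22)$buffer,
                                        cfg5)$statistic
  thr <- sqrt(max(stats_neg) * min(stats_pos)) # geometric midpoint
  cfg5$threshold <- thr
  cfg15 <- suppressWarnings(bat_config(threshold = thr, sliding_width = 15,
                                       sliding_step = 7))
  expect_equal(nrow(detect_bat(fx$buffer, cfg5)), 1)
  expect_equal(nrow(detect_bat(fx$buffer, cfg15)), 0)
})

test_that("k isolated calls in k partitions give k events", {
  # 4 partitions of 0.512 s; one pulse centred in each
  pulse_times <- 0.25 + 0.512 * (0:3)
  fx <- generate_fixture(fixture_spec("bat_pulse_train",
                                      duration_s = 4 * 0.512, snr_db = 20,
                                      seed = 31,
                                      pulse_times_s = pulse_times))
  ev <- detect_bat(fx$buffer, bat_config())
  expect_equal(nrow(ev), 4)
})

test_that("the duty-cycled schedule listens, triggers and skips recordings", {
  cfg <- bat_config()
  # pure silence: no events
  silence <- audio_buffer(numeric(6 * 250000), 250000)
  expect_equal(nrow(run_duty_cycled(silence, cfg)), 0)
  # 15 s pulse train: events only in listening windows, at most one each
  fx <- generate_fixture(fixture_spec("bat_pulse_train", duration_s = 15,
                                      snr_db = 20, seed = 33))
  ev <- run_duty_cycled(fx$buffer, cfg)
  n_listen_max <- ceiling(15 / (cfg$sleep_s + 0.512))
  expect_gte(nrow(ev), 1)
  expect_lte(nrow(ev), n_listen_max)
  # with a 100 ms inter-pulse interval every listening window holds pulses,
  # so consecutive events are separated by at least the recording span
  if (nrow(ev) > 1) {
    expect_true(all(diff(ev$time_s) >= cfg$recording_s))
  }
})
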