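span_s <- 2 * 16384 / 8000 # 4.096 s

gunshot_span_fixture <- function(seed, snr_db = 20, onset_s = 0.8) {
  generate_fixture(fixture_spec("gunshot", duration_s = span_s,
                                snr_db = snr_db, seed = seed,
                                onset_s = onset_s))
}

shared_model <- function() {
  cached("gunshot_model", default_gunshot_model)
}

test_that("feature extraction zips 256 three-band triples per span", {
  cfg <- gunshot_config(model = shared_model())
  silence <- audio_buffer(numeric(2 * 16384), 8000)
  feats <- extract_features(silence, cfg)
  expect_equal(dim(feats), c(256L, 3L))
  expect_true(all(feats == 0))
  # a 400 Hz tone dominates its own band in every window
  tone <- audio_buffer(0.5 * sin(2 * pi * 400 * (1:(2 * 16384)) / 8000), 8000)
  ft <- extract_features(tone, cfg)
  expect_true(all(ft[, 1] > 10 * ft[, 2]))
  expect_true(all(ft[, 1] > 10 * ft[, 3]))
  expect_error(extract_features(audio_buffer(numeric(100), 8000), cfg),
               "exactly")
})

test_that("gunshot fixtures decay faster in the high band than the low band", {
  cfg <- gunshot_config(model = shared_model())
  for (seed in 1:3) {
    fx <- gunshot_span_fixture(seed)
    feats <- extract_features(fx$buffer, cfg)
    below_frac <- function(v) {
      pk <- which.max(v)
      pk + which(v[pk:length(v)] < 0.1 * max(v))[1] - 1L
    }
    expect_lt(below_frac(feats[, 3]), below_frac(feats[, 1]))
  }
})

test_that("emission log-likelihood spread is capped at log(100)", {
  set.seed(11)
  model <- shared_model()
  for (rep in 1:50) {
    triple <- rlnorm(3, rnorm(1, -3, 4), 1)
    ll <- emission_loglik(triple, model)
    expect_lte(max(ll) - min(ll), log(model$cap_factor) + 1e-9)
  }
  # matrix input matches per-row evaluation
  m <- matrix(rlnorm(12, -2, 1), 4, 3)
  block <- emission_loglik(m, model)
  expect_equal(block[2, ], emission_loglik(m[2, ], model))
})

test_that("a triple at a state's emission mode is scored highest by that state", {
  model <- shared_model()
  for (s in 1:5) {
    triple <- exp(model$mu[s, ])
    ll <- emission_loglik(triple, model)
    expect_equal(names(which.max(ll)), model$states[s])
  }
})

test_that("capping matches an independent clamp reference on random triples", {
  set.seed(12)
  model <- shared_model()
  uncapped <- function(triple) {
    sapply(1:5, function(s) {
      sum(dlnorm(pmax(triple, 1e-30), model$mu[s, ], model$sigma[s, ],
                 log = TRUE))
    })
  }
  for (rep in 1:20) {
    triple <- rlnorm(3, rnorm(1, -4, 5), 2)
    raw <- uncapped(triple)
    ref <- pmax(raw, max(raw) - log(100))
    expect_equal(unname(emission_loglik(triple, model)), ref)
  }
})

test_that("viterbi matches exhaustive path enumeration for short sequences", {
  set.seed(13)
  for (trial in 1:100) {
    model <- random_hmm()
    n <- sample(1:6, 1)
    obs <- matrix(rlnorm(3 * n, rnorm(1, 0, 2), 1.5), n, 3)
    e <- emission_loglik(obs, model)
    if (is.null(dim(e))) e <- matrix(e, nrow = 1)
    expect_identical(viterbi(obs, model), brute_viterbi(e, model))
  }
  # a handful of longer sequences at the enumeration limit
  for (trial in 1:4) {
    model <- random_hmm()
    n <- 8
    obs <- matrix(rlnorm(3 * n, 0, 1.5), n, 3)
    expect_identical(viterbi(obs, model),
                     brute_viterbi(emission_loglik(obs, model), model))
  }
})

test_that("viterbi degenerate cases decode as expected", {
  # emissions overwhelmingly favouring silence give an all-S path
  topo <- gunshot_topology()
  trans <- topo / rowSums(topo)
  mu <- matrix(c(-20, 0, 5, 3, 1), 5, 3) # S at exp(-20), far from the rest
  model <- gunshot_hmm(trans, mu, matrix(0.3, 5, 3))
  obs <- matrix(exp(-20), 10, 3)
  expect_true(all(viterbi(obs, model) == "S"))
})

test_that("the detection rule requires I, then D, then T, in order", {
  expect_false(ecodetect:::gunshot_path_rule(rep("S", 10)))
  expect_true(ecodetect:::gunshot_path_rule(c("N", "I", "I", "D", "D", "T")))
  expect_false(ecodetect:::gunshot_path_rule(c("T", "T", "I", "D", "D", "N")))
  expect_false(ecodetect:::gunshot_path_rule(c("I", "D", "N", "N")))
  expect_true(ecodetect:::gunshot_path_rule(c("T", "I", "N", "D", "S", "T")))
})

test_that("a synthetic gunshot span is decoded through I, D and T", {
  cfg <- gunshot_config(model = shared_model())
  fx <- gunshot_span_fixture(101)
  ev <- detect_gunshot_span(fx$buffer, cfg)
  expect_false(is.null(ev))
  path <- attr(ev, "path")
  expect_true(all(c("I", "D", "T") %in% path))
  # event time points at the first impulse window, near the true onset
  expect_lt(abs(ev$time_s - 0.8), 0.1)
  # an all-silence span produces no event
  silence <- audio_buffer(numeric(2 * 16384), 8000)
  expect_null(detect_gunshot_span(silence, cfg))
})

test_that("stream scanning finds shots straddling partition boundaries", {
  cfg <- gunshot_config(model = shared_model())
  # partition boundary at 2.048 s; shot centred on it
  fx <- generate_fixture(fixture_spec("gunshot", duration_s = 8,
                                      snr_db = 20, seed = 55,
                                      shot_times_s = 1.9))
  ev <- scan_stream(fx$buffer, cfg)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time_s - 1.9), 0.2)
})

test_that("k shots separated by more than 8 s give k merged events", {
  cfg <- gunshot_config(model = shared_model())
  fx <- generate_fixture(fixture_spec("gunshot", duration_s = 22,
                                      snr_db = 20, seed = 56,
                                      shot_times_s = c(1, 10.5, 20)))
  ev <- scan_stream(fx$buffer, cfg)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$time_s, c(1, 10.5, 20), tolerance = 0.1)
  # empty stream
  expect_equal(nrow(scan_stream(audio_buffer(numeric(0), 8000), cfg)), 0)
})

test_that("detection is insensitive to stream offset modulo the partition", {
  cfg <- gunshot_config(model = shared_model())
  base <- generate_fixture(fixture_spec("gunshot", duration_s = 10,
                                        snr_db = 20, seed = 57,
                                        shot_times_s = 3.0))
  for (offset_s in c(0, 0.7, 1.4)) {
    shifted <- audio_buffer(
      base$buffer$samples[(round(offset_s * 8000) + 1):length(base$buffer$samples)],
      8000
    )
    ev <- scan_stream(shifted, cfg)
    expect_equal(nrow(ev), 1)
  }
})

test_that("detection rate degrades monotonically as SNR falls", {
  cfg <- gunshot_config(model = shared_model())
  rate_at <- function(snr) {
    mean(sapply(1:8, function(s) {
      fx <- gunshot_span_fixture(700 + s, snr_db = snr)
      !is.null(detect_gunshot_span(fx$buffer, cfg))
    }))
  }
  r <- c(rate_at(25), rate_at(5), rate_at(-15))
  expect_true(all(diff(r) <= 0))
  expect_equal(r[1], 1)
})

test_that("model validation enforces stochasticity and positive spreads", {
  topo <- gunshot_topology()
  trans <- topo / rowSums(topo)
  mu <- matrix(0, 5, 3)
  expect_error(gunshot_hmm(trans * 2, mu, matrix(1, 5, 3)), "sum to 1")
  expect_error(gunshot_hmm(trans, mu, matrix(0, 5, 3)), "positive")
  expect_error(gunshot_hmm(trans, mu, matrix(1, 5, 3), cap_factor = 1),
               "exceed 1")
  m <- gunshot_hmm(trans, mu, matrix(1, 5, 3))
  expect_equal(rowSums(m$transition), rep(1, 5), ignore_attr = TRUE)
})
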