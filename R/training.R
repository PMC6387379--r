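#' Fit log-normal emission parameters from labelled windows
#'
#' Moment-matches a log-normal distribution per state and band on the log
#' scale: `mu` is the mean and `sigma` the standard deviation of the log
#' band magnitudes of the windows labelled with that state. Magnitudes are
#' floored at a tiny positive constant before the log. Every state needs at
#' least two windows, and a state whose magnitudes are all identical is
#' rejected (its variance is degenerate); small but positive standard
#' deviations are floored at `sigma_floor` to avoid near-degenerate spikes.
#'
#' @param states Character vector of window state labels
#'   (`"S", "N", "I", "D", "T"`).
#' @param features Matrix of band magnitudes, one row per window, three
#'   columns.
#' @param sigma_floor Lower bound applied to each fitted `sigma`.
#' @return A list with 5x3 matrices `mu` and `sigma`.
#' @export
fit_emissions <- function(states, features, sigma_floor = 1e-3) {
  features <- as.matrix(features)
  if (ncol(features) != 3) stop("`features` must have 3 columns", call. = FALSE)
  if (length(states) != nrow(features)) {
    stop("`states` and `features` must have matching lengths", call. = FALSE)
  }
  mu <- matrix(NA_real_, 5, 3, dimnames = list(GUNSHOT_STATES, NULL))
  sigma <- mu
  for (s in GUNSHOT_STATES) {
    idx <- which(states == s)
    if (length(idx) < 2) {
      stop(sprintf("state '%s' has fewer than 2 labelled windows", s),
           call. = FALSE)
    }
    lx <- log(pmax(features[idx, , drop = FALSE], MAGNITUDE_FLOOR))
    for (b in 1:3) {
      sdev <- stats::sd(lx[, b])
      if (sdev == 0) {
        stop(sprintf(
          "state '%s', band %d: all magnitudes identical (degenerate variance)",
          s, b
        ), call. = FALSE)
      }
      mu[s, b] <- mean(lx[, b])
      sigma[s, b] <- max(sdev, sigma_floor)
    }
  }
  list(mu = mu, sigma = sigma)
}

#' Fit transition probabilities from labelled dwell segments
#'
#' Uses the mean time spent in each state: under the memoryless (geometric)
#' dwell implied by a Markov chain, a mean dwell of `d` windows corresponds
#' to a self-transition probability of `1 - 1/d`. The exit mass `1/d` is
#' distributed over the state's allowed successors in the detector topology,
#' proportionally to the successor counts observed between consecutive
#' segments (uniformly when a state's exits were never observed).
#'
#' @param segments A data frame with columns `state` and `duration`
#'   (dwell length in windows, >= 1), in temporal order, plus an optional
#'   `recording` column separating independent recordings (successors are
#'   only counted within a recording).
#' @param topology Logical 5x5 matrix of allowed transitions; defaults to
#'   [gunshot_topology()].
#' @return A 5x5 row-stochastic transition matrix.
#' @export
fit_transitions <- function(segments, topology = gunshot_topology()) {
  stopifnot(is.data.frame(segments),
            all(c("state", "duration") %in% names(segments)))
  if (any(segments$duration < 1)) {
    stop("segment durations must be at least one window", call. = FALSE)
  }
  missing <- setdiff(GUNSHOT_STATES, unique(segments$state))
  if (length(missing)) {
    stop(sprintf("no dwell segments observed for state(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rec <- if ("recording" %in% names(segments)) segments$recording
         else rep(1L, nrow(segments))
  # Observed successor counts between consecutive segments of one recording.
  succ <- matrix(0, 5, 5, dimnames = list(GUNSHOT_STATES, GUNSHOT_STATES))
  for (r in unique(rec)) {
    st <- segments$state[rec == r]
    if (length(st) > 1) {
      for (k in seq_len(length(st) - 1L)) {
        succ[st[k], st[k + 1L]] <- succ[st[k], st[k + 1L]] + 1
      }
    }
  }
  trans <- matrix(0, 5, 5, dimnames = list(GUNSHOT_STATES, GUNSHOT_STATES))
  for (s in GUNSHOT_STATES) {
    dwell <- mean(segments$duration[segments$state == s])
    if (dwell < 1) stop("mean dwell below one window", call. = FALSE)
    p_stay <- 1 - 1 / dwell
    trans[s, s] <- p_stay
    successors <- setdiff(GUNSHOT_STATES[topology[s, ]], s)
    if (!length(successors)) {
      trans[s, s] <- 1
      next
    }
    w <- succ[s, successors]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(successors),
                                             length(successors))
    trans[s, successors] <- (1 - p_stay) * w
  }
  trans
}

#' Simulate a state sequence from the model's Markov chain
#'
#' Draws a random path from the initial distribution and transition matrix,
#' ignoring emissions. Used to validate fitted transition probabilities by
#' checking that simulated sequences have the same structure as labelled
#' gunshots (every excursion entering `I` runs through `D` and `T`).
#'
#' @param model A [gunshot_hmm()].
#' @param n_steps Number of windows to simulate (>= 1).
#' @param seed Integer seed (simulations are reproducible by construction).
#' @return Character vector of `n_steps` states.
#' @export
simulate_states <- function(model, n_steps, seed) {
  stopifnot(inherits(model, "gunshot_hmm"), n_steps >= 1)
  local_seed(seed, {
    path <- character(n_steps)
    cur <- sample(model$states, 1, prob = model$initial)
    path[1] <- cur
    if (n_steps > 1) {
      for (t in 2:n_steps) {
        cur <- sample(model$states, 1, prob = model$transition[cur, ])
        path[t] <- cur
      }
    }
    path
  })
}

#' Fit a gunshot HMM from labelled recordings
#'
#' High-level supervised estimation: takes one state-label sequence and one
#' feature matrix per recording, fits emissions from the pooled labelled
#' windows with [fit_emissions()] and transitions from the per-recording
#' dwell segments with [fit_transitions()].
#'
#' @param state_seqs List of character vectors, one per recording, each
#'   labelling every analysis window of that recording.
#' @param feature_list List of `N x 3` feature matrices matching
#'   `state_seqs` (see [extract_features()]).
#' @param cap_factor Emission likelihood cap passed to [gunshot_hmm()].
#' @param topology Allowed-transition matrix for [fit_transitions()].
#' @return A fitted [gunshot_hmm()].
#' @export
fit_gunshot_model <- function(state_seqs, feature_list, cap_factor = 100,
                              topology = gunshot_topology()) {
  stopifnot(is.list(state_seqs), is.list(feature_list),
            length(state_seqs) == length(feature_list))
  states <- unlist(state_seqs, use.names = FALSE)
  features <- do.call(rbind, feature_list)
  em <- fit_emissions(states, features)
  segs <- do.call(rbind, lapply(seq_along(state_seqs), function(i) {
    r <- rle(state_seqs[[i]])
    data.frame(state = r$values, duration = r$lengths, recording = i,
               stringsAsFactors = FALSE)
  }))
  trans <- fit_transitions(segs, topology)
  gunshot_hmm(trans, em$mu, em$sigma, cap_factor = cap_factor)
}

#' Label analysis windows from time-interval annotations
#'
#' Maps interval annotations (`start_s`, `end_s`, `state`) onto the
#' detector's analysis windows: a window takes the state of the interval
#' covering its midpoint. Windows covered by no interval are labelled `NA`.
#'
#' @param n_windows Number of analysis windows.
#' @param labels Data frame with columns `start_s`, `end_s`, `state`.
#' @param window_s Window duration in seconds (`window_len / sample_rate`).
#' @return Character vector of `n_windows` states (possibly `NA`).
#' @export
label_windows <- function(n_windows, labels, window_s) {
  mid <- (seq_len(n_windows) - 0.5) * window_s
  out <- rep(NA_character_, n_windows)
  for (k in seq_len(nrow(labels))) {
    hit <- mid >= labels$start_s[k] & mid < labels$end_s[k]
    out[hit] <- labels$state[k]
  }
  out
}

# Cache for the packaged default model so repeated calls are cheap.
.ecodetect_cache <- new.env(parent = emptyenv())

#' Default gunshot model fitted on packaged synthetic fixtures
#'
#' Builds the shipped gunshot HMM by running the full supervised training
#' pipeline on a fixed, seeded set of synthetic gunshot, noise and silence
#' fixtures from [generate_fixture()]. The model is deterministic and cached
#' after the first call. It is a reasonable starting point for the synthetic
#' acoustics the generator produces; real deployments should train on real
#' labelled recordings with [fit_gunshot_model()].
#'
#' @return A [gunshot_hmm()].
#' @export
default_gunshot_model <- function() {
  if (!is.null(.ecodetect_cache$default_gunshot_model)) {
    return(.ecodetect_cache$default_gunshot_model)
  }
  model <- train_gunshot_on_fixtures(n_shots = 12, seed = 20060)
  .ecodetect_cache$default_gunshot_model <- model
  model
}

# Shared synthetic-training routine: generates `n_shots` gunshot fixtures
# (plus matched noise and near-silent spans), labels windows from the
# generator's ground-truth segments, and fits the HMM.
train_gunshot_on_fixtures <- function(n_shots, seed, snr_db = 20) {
  cfg <- gunshot_config(model = placeholder_gunshot_model())
  window_s <- cfg$window_len / cfg$sample_rate_hz
  n_win <- 2L * cfg$partition_samples %/% cfg$window_len
  state_seqs <- list()
  feature_list <- list()
  span_s <- 2 * cfg$partition_samples / cfg$sample_rate_hz
  for (k in seq_len(n_shots)) {
    fx <- generate_fixture(fixture_spec(
      "gunshot", duration_s = span_s, snr_db = snr_db, seed = seed + k,
      onset_s = 0.8
    ))
    feats <- extract_features(fx$buffer, cfg)
    st <- label_windows(nrow(feats), fx$segments, window_s)
    keep <- !is.na(st)
    state_seqs[[length(state_seqs) + 1L]] <- st[keep]
    feature_list[[length(feature_list) + 1L]] <- feats[keep, , drop = FALSE]
  }
  # Near-silent spans supply the silence state's emission statistics.
  for (k in seq_len(max(2L, n_shots %/% 4L))) {
    fx <- generate_fixture(fixture_spec(
      "background", duration_s = span_s, seed = seed + 1000L + k,
      sample_rate_hz = cfg$sample_rate_hz, noise_rms = 1e-4
    ))
    feats <- extract_features(fx$buffer, cfg)
    state_seqs[[length(state_seqs) + 1L]] <- rep("S", nrow(feats))
    feature_list[[length(feature_list) + 1L]] <- feats
  }
  fit_gunshot_model(state_seqs, feature_list)
}

# Minimal structurally-valid model used only so gunshot_config() can be
# constructed before a fitted model exists (feature extraction does not
# consult the model).
placeholder_gunshot_model <- function() {
  topo <- gunshot_topology()
  trans <- topo / rowSums(topo)
  mu <- matrix(rep(c(-14, -4, 4, 1, -2), 3), 5, 3)
  sigma <- matrix(1, 5, 3)
  gunshot_hmm(trans, mu, sigma)
}
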