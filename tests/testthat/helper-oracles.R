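# Independent reference implementations used to check the package's
# algorithms on small inputs. These deliberately avoid the code paths they
# verify.

# Squared modulus of the Hamming-windowed DFT-style sum at frequency f.
dft_band_mag2 <- function(x, f, fs, h) {
  j <- seq_along(x)
  Mod(sum(h * x * exp(-2i * pi * f * j / fs)))^2
}

# Brute-force sliding median via direct enumeration.
brute_sliding_median <- function(v, width, step) {
  last <- length(v) - width + 1L
  starts <- unique(c(seq.int(1L, last, by = step), last))
  sapply(starts, function(s) median(v[s:(s + width - 1L)]))
}

# Exhaustive maximum-probability path: enumerate all 5^N state paths.
brute_viterbi <- function(emissions, model) {
  n <- nrow(emissions)
  paths <- as.matrix(expand.grid(rep(list(1:5), n)))
  logp <- model$log_initial[paths[, 1]] + emissions[cbind(1L, paths[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      logp <- logp + model$log_transition[cbind(paths[, t - 1], paths[, t])] +
        emissions[cbind(t, paths[, t])]
    }
  }
  model$states[paths[which.max(logp), ]]
}

# Random valid gunshot HMM (arbitrary dense transitions, random emissions).
random_hmm <- function() {
  trans <- matrix(rexp(25), 5, 5)
  trans <- trans / rowSums(trans)
  init <- rexp(5)
  gunshot_hmm(trans,
              mu = matrix(rnorm(15, 0, 2), 5, 3),
              sigma = matrix(runif(15, 0.2, 1.5), 5, 3),
              initial = init / sum(init))
}

# Mann-Whitney concordance probability (ties counted half).
concordance_auc <- function(statistics, truths) {
  pos <- statistics[truths]
  neg <- statistics[!truths]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Shared fixture-heavy objects, built once per test run.
cached <- local({
  env <- new.env(parent = emptyenv())
  function(name, builder) {
    if (is.null(env[[name]])) env[[name]] <- builder()
    env[[name]]
  }
})
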