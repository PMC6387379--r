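test_that("emission fitting recovers log-normal parameters", {
  set.seed(41)
  n <- 2000
  feats <- matrix(rlnorm(3 * 5 * n, meanlog = -2, sdlog = 0.5), ncol = 3)
  states <- rep(GUNSHOT_STATES <- c("S", "N", "I", "D", "T"), each = n)
  em <- fit_emissions(states, feats)
  expect_true(all(abs(em$mu - (-2)) < 0.05))
  expect_true(all(abs(em$sigma - 0.5) < 0.05))
})

test_that("degenerate and missing training inputs are rejected by name", {
  feats <- matrix(1, 10, 3)
  states <- rep(c("S", "N", "I", "D", "T"), each = 2)
  expect_error(fit_emissions(states, feats), "degenerate variance")
  expect_error(
    fit_emissions(rep(c("S", "N", "I", "D"), each = 3),
                  matrix(rlnorm(36), 12, 3)),
    "'T'"
  )
})

test_that("fitted densities rank each state highest on its own data", {
  set.seed(42)
  n <- 500
  lo <- matrix(rlnorm(3 * n, -6, 0.4), ncol = 3)
  hi <- matrix(rlnorm(3 * n, 2, 0.4), ncol = 3)
  mid <- matrix(rlnorm(3 * n, -2, 0.4), ncol = 3)
  feats <- rbind(lo, hi, mid, mid * 2, lo * 3)
  states <- rep(c("S", "I", "N", "D", "T"), each = n)
  em <- fit_emissions(states, feats)
  model <- gunshot_hmm(gunshot_topology() / rowSums(gunshot_topology()),
                       em$mu, em$sigma)
  ll_lo <- emission_loglik(colMeans(lo), model)
  expect_equal(names(which.max(ll_lo)), "S")
  ll_hi <- emission_loglik(colMeans(hi), model)
  expect_equal(names(which.max(ll_hi)), "I")
})

test_that("transition fitting implements the geometric dwell model", {
  segs <- data.frame(
    state = c("N", "I", "D", "T", "N", "S", "N", "I", "D", "T", "S"),
    duration = c(10, 1, 4, 8, 12, 20, 8, 1, 4, 8, 20)
  )
  trans <- fit_transitions(segs)
  expect_equal(trans["I", "I"], 0)       # mean dwell 1 -> immediate exit
  expect_equal(trans["D", "D"], 0.75)    # mean dwell 4 -> 1 - 1/4
  expect_equal(rowSums(trans), rep(1, 5), ignore_attr = TRUE)
  # exit mass follows observed successors within the topology
  expect_equal(trans["I", "D"], 1)       # only observed successor
  expect_true(all(trans[!gunshot_topology()] == 0))
  expect_error(fit_transitions(segs[segs$state != "T", ]), "T")
  expect_error(fit_transitions(data.frame(state = "S", duration = 0.5)),
               "at least one window")
})

test_that("simulated state sequences honour the transition structure", {
  topo <- gunshot_topology()
  # identity-like chain stays in its initial state
  frozen <- gunshot_hmm(diag(5), matrix(0, 5, 3), matrix(1, 5, 3))
  expect_equal(unique(simulate_states(frozen, 50, seed = 1)), "S")

  trans <- matrix(0, 5, 5, dimnames = list(colnames(topo), colnames(topo)))
  trans["S", ] <- c(0.90, 0.05, 0.05, 0, 0)
  trans["N", ] <- c(0.10, 0.85, 0.05, 0, 0)
  trans["I", ] <- c(0, 0, 0.60, 0.40, 0)
  trans["D", ] <- c(0, 0, 0, 0.70, 0.30)
  trans["T", ] <- c(0.10, 0.10, 0, 0, 0.80)
  model <- gunshot_hmm(trans, matrix(0, 5, 3), matrix(1, 5, 3))
  path <- simulate_states(model, 10000, seed = 99)
  # empirical mean dwell within 10% of the geometric expectation 1/(1-p)
  r <- rle(path)
  for (s in c("S", "N", "D", "T")) {
    expect_equal(mean(r$lengths[r$values == s]), 1 / (1 - trans[s, s]),
                 tolerance = 0.1)
  }
  # every excursion entering I reaches T before returning to S or N
  runs <- r$values
  complete <- which(runs == "I" & seq_along(runs) + 2 <= length(runs))
  expect_gt(length(complete), 10)
  for (k in complete) {
    expect_true(runs[k + 1] == "D" && runs[k + 2] == "T")
  }
  # determinism under the seed
  expect_identical(path, simulate_states(model, 10000, seed = 99))
})

test_that("window labelling maps interval annotations by midpoint", {
  labels <- data.frame(start_s = c(0, 0.5), end_s = c(0.5, 0.8),
                       state = c("N", "I"))
  st <- label_windows(10, labels, window_s = 0.1)
  expect_equal(st, c(rep("N", 5), rep("I", 3), NA, NA))
})

test_that("fitting on simulated data recovers the generating model", {
  set.seed(43)
  topo <- gunshot_topology()
  trans <- matrix(0, 5, 5, dimnames = list(colnames(topo), colnames(topo)))
  trans["S", ] <- c(0.85, 0.08, 0.07, 0, 0)
  trans["N", ] <- c(0.10, 0.82, 0.08, 0, 0)
  trans["I", ] <- c(0, 0, 0.50, 0.50, 0)
  trans["D", ] <- c(0, 0, 0, 0.75, 0.25)
  trans["T", ] <- c(0.08, 0.07, 0, 0, 0.85)
  mu <- matrix(c(-12, -4, 3, 1, -1), 5, 3) + matrix(rnorm(15, 0, 0.3), 5, 3)
  sigma <- matrix(runif(15, 0.4, 0.7), 5, 3)
  truth <- gunshot_hmm(trans, mu, sigma)

  n <- 5000
  path <- simulate_states(truth, n, seed = 7)
  idx <- match(path, truth$states)
  feats <- matrix(rlnorm(3 * n, meanlog = mu[idx, ], sdlog = sigma[idx, ]),
                  n, 3)
  fitted <- fit_gunshot_model(list(path), list(feats))
  expect_true(all(abs(fitted$transition - trans) < 0.05))
  expect_true(all(abs(fitted$mu - mu) < 0.1))
  expect_true(all(abs(fitted$sigma - sigma) < 0.1))
})

test_that("the default model is deterministic and structurally valid", {
  model <- cached("gunshot_model", default_gunshot_model)
  expect_s3_class(model, "gunshot_hmm")
  expect_equal(rowSums(model$transition), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(model$transition[!gunshot_topology()] == 0))
  # impulse emissions sit far above silence emissions in every band
  expect_true(all(model$mu["I", ] > model$mu["S", ] + 5))
})
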