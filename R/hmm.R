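#' @name gunshot_hmm
#' @title Five-state gunshot hidden Markov model
#'
#' @description
#' The gunshot detector classifies each 16 ms analysis window into one of
#' five states — silence (`S`), noise (`N`), initial impulse (`I`), decaying
#' impulse (`D`) and tail (`T`) — from its three-band Goertzel magnitudes.
#' Emissions are modelled as independent log-normal distributions per state
#' and band (log-densities summed over bands), with long right tails that
#' absorb extreme close-range magnitudes. To stop extreme observations from
#' locking the decoder into a single state, per-window state log-likelihoods
#' are capped so that no state is favoured by more than `cap_factor`
#' (default 100) times over any other.
#'
#' The default transition topology follows the strictly ordered gunshot
#' stages: `S -> {S, N, I}`, `N -> {N, S, I}`, `I -> {I, D}`, `D -> {D, T}`,
#' `T -> {T, S, N}`; all other transitions have probability zero. The
#' topology is configurable through the transition matrix itself.
#'
#' @param transition 5x5 row-stochastic transition matrix over the states
#'   `S, N, I, D, T` (rows = from, columns = to).
#' @param mu,sigma 5x3 matrices of log-normal log-means and log-sds, one row
#'   per state, one column per frequency band.
#' @param cap_factor Maximum allowed per-window likelihood ratio between
#'   states (default 100).
#' @param initial Initial state distribution; defaults to uniform over
#'   `{S, N}`, since an analysis span almost never begins mid-gunshot.
#' @return An object of class `gunshot_hmm`.
NULL

GUNSHOT_STATES <- c("S", "N", "I", "D", "T")

#' Allowed transition topology of the gunshot model
#'
#' @return A 5x5 logical matrix; `TRUE` where a transition is allowed.
#' @export
gunshot_topology <- function() {
  allowed <- matrix(FALSE, 5, 5,
                    dimnames = list(GUNSHOT_STATES, GUNSHOT_STATES))
  allowed["S", c("S", "N", "I")] <- TRUE
  allowed["N", c("N", "S", "I")] <- TRUE
  allowed["I", c("I", "D")] <- TRUE
  allowed["D", c("D", "T")] <- TRUE
  allowed["T", c("T", "S", "N")] <- TRUE
  allowed
}

#' @rdname gunshot_hmm
#' @export
gunshot_hmm <- function(transition, mu, sigma, cap_factor = 100,
                        initial = c(S = 0.5, N = 0.5, I = 0, D = 0, T = 0)) {
  transition <- as.matrix(transition)
  mu <- as.matrix(mu)
  sigma <- as.matrix(sigma)
  if (!all(dim(transition) == c(5, 5))) {
    stop("`transition` must be a 5x5 matrix", call. = FALSE)
  }
  if (!all(dim(mu) == c(5, 3)) || !all(dim(sigma) == c(5, 3))) {
    stop("`mu` and `sigma` must be 5x3 (state x band) matrices",
         call. = FALSE)
  }
  if (any(sigma <= 0)) {
    stop("every emission `sigma` must be positive", call. = FALSE)
  }
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("each transition row must sum to 1", call. = FALSE)
  }
  if (any(transition < 0)) {
    stop("transition probabilities must be non-negative", call. = FALSE)
  }
  if (cap_factor <= 1) stop("`cap_factor` must exceed 1", call. = FALSE)
  initial <- rep_len(as.numeric(initial), 5)
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    stop("`initial` must be a probability distribution over the 5 states",
         call. = FALSE)
  }
  dimnames(transition) <- list(GUNSHOT_STATES, GUNSHOT_STATES)
  rownames(mu) <- rownames(sigma) <- GUNSHOT_STATES
  structure(
    list(
      states = GUNSHOT_STATES,
      transition = transition,
      log_transition = log(transition),
      mu = mu,
      sigma = sigma,
      cap_factor = cap_factor,
      initial = initial,
      log_initial = log(initial)
    ),
    class = "gunshot_hmm"
  )
}

#' @export
print.gunshot_hmm <- function(x, ...) {
  cat("<gunshot_hmm> states S, N, I, D, T; cap factor", x$cap_factor, "\n")
  cat("Transition matrix:\n")
  print(round(x$transition, 4))
  invisible(x)
}

# Floor for magnitudes before taking logs (log-normal support is positive).
MAGNITUDE_FLOOR <- 1e-30

#' Capped per-state emission log-likelihoods
#'
#' For each observation window, sums the log-normal log-densities of the
#' three band magnitudes under each state (bands treated as independent) and
#' then caps the five values so that their spread never exceeds
#' `log(cap_factor)`: values below `max - log(cap_factor)` are raised to
#' exactly that floor. Magnitudes at or below zero are floored at a tiny
#' positive constant before the log.
#'
#' @param triples A length-3 numeric vector (one window) or an `N x 3`
#'   matrix of band magnitudes.
#' @param model A [gunshot_hmm()].
#' @return A length-5 named vector for a single window, or an `N x 5` matrix.
#' @export
emission_loglik <- function(triples, model) {
  stopifnot(inherits(model, "gunshot_hmm"))
  single <- is.null(dim(triples))
  m <- if (single) matrix(triples, nrow = 1) else as.matrix(triples)
  if (ncol(m) != 3) stop("each observation must have 3 band magnitudes",
                         call. = FALSE)
  mf <- pmax(m, MAGNITUDE_FLOOR)
  n <- nrow(m)
  ll <- matrix(0, n, 5, dimnames = list(NULL, model$states))
  for (s in 1:5) {
    for (b in 1:3) {
      ll[, s] <- ll[, s] +
        stats::dlnorm(mf[, b], model$mu[s, b], model$sigma[s, b], log = TRUE)
    }
  }
  floor_ll <- apply(ll, 1, max) - log(model$cap_factor)
  ll <- pmax(ll, floor_ll)
  if (single) ll[1, ] else ll
}

#' Most likely state path by Viterbi decoding
#'
#' Computes, in log space, the single state path with the highest joint
#' probability of the initial distribution, the transitions and the capped
#' emissions — the standard O(S^2 N) dynamic programme. Ties resolve to the
#' first state in the order `S, N, I, D, T`.
#'
#' @param triples An `N x 3` matrix of band magnitudes (or length-3 vector).
#' @param model A [gunshot_hmm()].
#' @return Character vector of `N` decoded states.
#' @export
viterbi <- function(triples, model) {
  stopifnot(inherits(model, "gunshot_hmm"))
  e <- emission_loglik(triples, model)
  if (is.null(dim(e))) e <- matrix(e, nrow = 1)
  n <- nrow(e)
  logA <- model$log_transition
  delta <- model$log_initial + e[1, ]
  back <- matrix(0L, n, 5)
  if (n > 1) {
    for (t in 2:n) {
      cand <- delta + logA # column s: delta[from] + logA[from, s]
      back[t, ] <- apply(cand, 2, which.max)
      delta <- cand[cbind(back[t, ], 1:5)] + e[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  model$states[path]
}
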