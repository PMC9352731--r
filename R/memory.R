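#' Learning parameters of the associative memory
#'
#' Learning stabilises absent connections: during a learning episode a
#' fraction `p[1,2] * mu` of the state-1 (zero-strength) connections onto
#' each output neuron moves to state 2, and higher states are untouched.
#' `alpha` scales the state weights `w(i) = alpha * (i - 1) / (S - 1)`.
#'
#' @param mu Learning rate in `[0, 1]` per learning time unit.
#' @param alpha Positive weight scale constant (default 1, so the top state
#'   has weight 1).
#' @param inhibition Feedforward-inhibition policy: `"half_delta"` sets the
#'   threshold midway through the expected learning increment (the default
#'   circuit), `"two_sigma"` sets it two weighted asymptotic standard
#'   deviations above the equilibrium net input.
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(mu = 1, alpha = 1,
                            inhibition = c("half_delta", "two_sigma")) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(mu = mu, alpha = alpha, inhibition = match.arg(inhibition)),
            class = "learning_params")
}

#' Weight of a connection state
#'
#' Connection strength is proportional to the state number:
#' `w(i) = alpha * (i - 1) / (S - 1)`, so state 1 (absent) has weight 0 and
#' state `S` has weight `alpha`.
#'
#' @param i State index (vectorised), in `1..S`.
#' @param S Number of states.
#' @param alpha Weight scale.
#' @return Numeric weights.
#' @export
state_weight <- function(i, S, alpha = 1) {
  if (any(i < 1 | i > S)) stop("state index out of range 1..S")
  alpha * (i - 1) / (S - 1)
}

# up-move probability out of state 1
p12 <- function(spec) spec$x[2] * spec$y[1]

#' Distribution-level learning
#'
#' Applies the stabilisation learning rule to a state distribution: per
#' learning unit, mass `v[1] * p[1,2] * mu` moves from state 1 to state 2;
#' no other state is touched, so total mass is conserved. Iterating `units`
#' times depletes state 1 geometrically, which is the origin of the
#' exponentially decelerating learning curve (see [learning_curve()]).
#'
#' @param v State distribution.
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @param units Number of learning time units (>= 1).
#' @return The post-learning state distribution.
#' @export
learn_distribution <- function(v, spec, params, units = 1L) {
  check_distribution(v, spec$S)
  if (units < 1) stop("units must be >= 1")
  rate <- p12(spec) * params$mu
  for (k in seq_len(units)) {
    moved <- v[1] * rate
    v[1] <- v[1] - moved
    v[2] <- v[2] + moved
  }
  v
}

#' Create a connection ensemble for one input-output mapping
#'
#' An explicit `A x B` matrix of integer connection states, one connection
#' per (input neuron, output neuron) pair, for Monte-Carlo simulation of a
#' single learned association.
#'
#' @param spec A [chain_spec()].
#' @param A,B Input and output neuron counts.
#' @param init `"equilibrium"` draws initial states from `x`; `"empty"`
#'   starts every connection in state 1 (the 'empty brain').
#' @param seed Integer seed.
#' @return Object of class `memory_ensemble`: list with `states`
#'   (`A x B` integer matrix), `A`, `B`, `S`.
#' @export
new_ensemble <- function(spec, A, B, init = c("equilibrium", "empty"),
                         seed = 1L) {
  init <- match.arg(init)
  stopifnot(A >= 1, B >= 1)
  states <- if (init == "empty") {
    matrix(1L, A, B)
  } else {
    withr::with_seed(seed,
      matrix(sample.int(spec$S, A * B, replace = TRUE, prob = spec$x), A, B))
  }
  structure(list(states = states, A = A, B = B, S = spec$S),
            class = "memory_ensemble")
}

#' Stochastic learning on an explicit ensemble
#'
#' Stochastic counterpart of [learn_distribution()]: per learning unit,
#' every state-1 connection is independently promoted to state 2 with
#' probability `p[1,2] * mu`. The mean number of promotions per output
#' neuron is `A * p[1,2] * mu` on the empty brain and
#' `x[1] * A * p[1,2] * mu` at equilibrium.
#'
#' @param ens A [new_ensemble()].
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @param units Learning units.
#' @param seed Integer seed.
#' @return The updated `memory_ensemble`.
#' @export
learn_ensemble <- function(ens, spec, params, units = 1L, seed = 1L) {
  if (units < 1) stop("units must be >= 1")
  rate <- p12(spec) * params$mu
  st <- ens$states
  withr::with_seed(seed, {
    for (k in seq_len(units)) {
      idx <- which(st == 1L)
      if (length(idx) && rate > 0) {
        promote <- idx[stats::runif(length(idx)) < rate]
        st[promote] <- 2L
      }
    }
  })
  ens$states <- st
  ens
}

#' Expected net input to an output neuron
#'
#' When all `A` input neurons fire, the expected net input to each output
#' neuron under state distribution `v` is `A * sum(w(i) * v[i])`.
#'
#' @param v State distribution.
#' @param A Number of activated input neurons.
#' @param S State count.
#' @param alpha Weight scale.
#' @return Scalar expected net input (weight units).
#' @export
expected_net_input <- function(v, A, S, alpha = 1) {
  check_distribution(v, S)
  A * sum(state_weight(seq_len(S), S, alpha) * v)
}

#' Feedforward inhibition threshold
#'
#' The inhibition `F` scales linearly with the number of activated input
#' neurons and filters out the background net input that every output
#' neuron receives from equilibrium connections. Under the default
#' `half_delta` policy,
#' `F = alpha * A_active / (S - 1) * (x[1] * p[1,2] * mu / 2 + sum((i - 1) * x[i]))`:
#' the equilibrium net input plus half the expected learning increment, so
#' a learned pattern sits half an increment above threshold and an
#' unlearned one half an increment below. The `two_sigma` policy instead
#' adds two weighted asymptotic standard deviations of the occupancy
#' fluctuations to the equilibrium net input.
#'
#' @param A_active Number of activated input neurons.
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @return Scalar threshold (weight units).
#' @export
feedforward_inhibition <- function(A_active, spec, params) {
  if (A_active < 0) stop("A_active must be nonnegative")
  S <- spec$S; x <- spec$x
  if (params$inhibition == "half_delta") {
    params$alpha * A_active / (S - 1) *
      (x[1] * p12(spec) * params$mu / 2 + sum((seq_len(S) - 1) * x))
  } else {
    w <- state_weight(seq_len(S), S, params$alpha)
    sigma2 <- passage_summary(spec)$sigma2
    expected_net_input(x, A_active, S, params$alpha) +
      2 * sqrt(A_active * sum(w^2 * sigma2))
  }
}

#' Threshold retrieval from a connection ensemble
#'
#' Presents a cue consisting of a random subset of the input neurons and
#' applies the binary activation rule: output neuron `b` fires iff its net
#' input from the active inputs exceeds the feedforward inhibition scaled
#' to the active-input count.
#'
#' @param ens A [new_ensemble()] (possibly after [learn_ensemble()]).
#' @param cue_fraction Fraction of input neurons in the cue, in `(0, 1]`.
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @param seed Seed for the cue draw.
#' @return Object of class `retrieval_result`: `net` (length-`B` net
#'   inputs), `F` (threshold), `act` (binary activations),
#'   `fraction_active`.
#' @export
retrieve <- function(ens, cue_fraction, spec, params, seed = 1L) {
  if (cue_fraction <= 0 || cue_fraction > 1)
    stop("cue_fraction must lie in (0, 1]")
  n_cue <- max(1L, round(cue_fraction * ens$A))
  cue <- withr::with_seed(seed, sample.int(ens$A, n_cue))
  w <- state_weight(seq_len(ens$S), ens$S, params$alpha)
  W <- matrix(w[ens$states], ens$A, ens$B)
  net <- colSums(W[cue, , drop = FALSE])
  Fb <- feedforward_inhibition(n_cue, spec, params)
  act <- as.integer(net - Fb > 0)
  structure(list(net = net, F = Fb, act = act,
                 fraction_active = mean(act)),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("Retrieval: %d/%d output neurons active (threshold F = %.4g)\n",
              sum(x$act), length(x$act), x$F))
  invisible(x)
}

#' Closed-form exponential learning curve
#'
#' Under massed learning at equilibrium, a constant fraction
#' `f = mu * x[2] * y[1]` of the state-1 connections is stabilised per
#' learning unit, so the expected state-1 count after `t` units is
#' `x[1] * A * (1 - f)^t` and the state-2 count is
#' `A * x[2] + A * x[1] - x[1] * A * (1 - f)^t` — an exponentially
#' decelerating learning curve with asymptote `A * (x[1] + x[2])`.
#'
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @param A Number of input connections per output neuron.
#' @param t Vector of learning times (units).
#' @return Data frame with columns `t`, `state1`, `state2`.
#' @export
learning_curve <- function(spec, params, A, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  f <- params$mu * spec$x[2] * spec$y[1]
  n1 <- spec$x[1] * A * (1 - f)^t
  data.frame(t = t, state1 = n1,
             state2 = A * spec$x[2] + A * spec$x[1] - n1)
}
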