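#' Monte-Carlo simulation of a connection population
#'
#' Simulates `n` independent connections, each following the transition
#' matrix of `spec`, for `t_max` steps, and returns state-occupancy counts
#' over time. This is the stochastic counterpart of
#' [evolve_distribution()] and serves as an oracle for all closed-form
#' results of the chain analysis.
#'
#' @param spec A [chain_spec()].
#' @param n Number of connections (>= 1).
#' @param t_max Number of steps (>= 0).
#' @param v0 Initial state distribution; defaults to the equilibrium `x`.
#' @param seed Integer seed; the simulation is bit-for-bit reproducible.
#' @return A `(t_max + 1) x S` integer matrix of counts with rownames
#'   `t0 ... t<t_max>`; each row sums to `n`. Attribute `"states"` carries
#'   the final state vector.
#' @export
#' @examples
#' spec <- chain_spec(c(0.5, 0.3, 0.2), c(0.2, 0.1))
#' occ <- simulate_connections(spec, n = 500, t_max = 10, seed = 1)
#' occ[1, ]
simulate_connections <- function(spec, n, t_max, v0 = NULL, seed = 1L) {
  stopifnot(n >= 1, t_max >= 0)
  P <- build_transition_matrix(spec)
  S <- spec$S
  if (is.null(v0)) v0 <- spec$x
  check_distribution(v0, S)
  p_up <- c(spec$x[-1] * spec$y, 0)
  p_down <- c(0, spec$x[-S] * spec$y)
  counts <- matrix(0L, t_max + 1, S,
                   dimnames = list(paste0("t", 0:t_max), paste0("state_", 1:S)))
  states <- withr::with_seed(seed, {
    st <- sample.int(S, n, replace = TRUE, prob = v0)
    counts[1, ] <- tabulate(st, nbins = S)
    if (t_max > 0) {
      for (step in seq_len(t_max)) {
        u <- stats::runif(n)
        up <- p_up[st]
        down <- p_down[st]
        st <- st + (u < up) - (u >= up & u < up + down)
        counts[step + 1, ] <- tabulate(st, nbins = S)
      }
    }
    st
  })
  attr(counts, "states") <- states
  counts
}

#' Simulated dwell times in one state
#'
#' Draws `n` complete dwell episodes in `state` (geometric waiting times
#' with success probability `1 - P[state, state]`), the Monte-Carlo oracle
#' for [state_lifetimes()].
#'
#' @param spec A [chain_spec()].
#' @param state State index.
#' @param n Number of dwell episodes.
#' @param seed Integer seed.
#' @return Integer vector of `n` dwell durations (steps).
#' @export
simulate_dwell_times <- function(spec, state, n, seed = 1L) {
  P <- build_transition_matrix(spec)
  p_exit <- 1 - P[state, state]
  if (p_exit <= 0) stop("state is absorbing; dwell time infinite")
  withr::with_seed(seed, stats::rgeom(n, p_exit) + 1L)
}

#' Simulated first-passage (hitting) times
#'
#' Runs `n` independent walkers from state `from` until each first reaches
#' state `to`, the Monte-Carlo oracle for [first_passage_times()].
#'
#' @param spec A [chain_spec()].
#' @param from,to State indices.
#' @param n Number of walkers.
#' @param seed Integer seed.
#' @param t_cap Safety cap on steps; walkers still running at the cap are an
#'   error (raise the cap for slow chains).
#' @return Integer vector of `n` hitting times (steps).
#' @export
simulate_hitting_times <- function(spec, from, to, n, seed = 1L,
                                   t_cap = 1e6) {
  stopifnot(from != to)
  S <- spec$S
  p_up <- c(spec$x[-1] * spec$y, 0)
  p_down <- c(0, spec$x[-S] * spec$y)
  withr::with_seed(seed, {
    st <- rep.int(from, n)
    hit_at <- rep.int(NA_integer_, n)
    alive <- seq_len(n)
    step <- 0L
    while (length(alive) && step < t_cap) {
      step <- step + 1L
      u <- stats::runif(length(alive))
      up <- p_up[st[alive]]
      down <- p_down[st[alive]]
      st[alive] <- st[alive] + (u < up) - (u >= up & u < up + down)
      done <- st[alive] == to
      if (any(done)) {
        hit_at[alive[done]] <- step
        alive <- alive[!done]
      }
    }
    if (length(alive))
      stop(sprintf("%d walkers did not hit state %d within %g steps",
                   length(alive), to, t_cap))
    hit_at
  })
}

#' Write an occupancy trajectory as CSV
#'
#' Writes counts (or fractions) from [simulate_connections()] with header
#' `t,state_1,...,state_S`.
#'
#' @param occ Matrix returned by [simulate_connections()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(occ, path) {
  df <- data.frame(t = 0:(nrow(occ) - 1), occ, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
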