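#' Fundamental matrix of the connection chain
#'
#' Computes the Kemeny–Snell fundamental matrix `Z = (I - P + X)^{-1}` of an
#' ergodic chain, where `X` is the matrix whose every row is the equilibrium
#' vector `x`. `Z` is the generating object for first-passage times and
#' asymptotic occupancy variances. Rows of `Z` sum to 1 (the row sums of
#' `I - P + X` are 1 and inversion preserves them).
#'
#' @param spec A [chain_spec()].
#' @param P Transition matrix; built from `spec` when omitted.
#' @return `S x S` fundamental matrix.
#' @export
fundamental_matrix <- function(spec, P = NULL) {
  if (is.null(P)) P <- build_transition_matrix(spec)
  S <- spec$S
  X <- matrix(spec$x, S, S, byrow = TRUE)
  A <- diag(S) - P + X
  kap <- kappa(A, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stop(sprintf("fundamental matrix system is ill-conditioned (condition number %.3g)", kap))
  Z <- solve(A)
  dimnames(Z) <- dimnames(P)
  Z
}

#' First-passage times between connection states
#'
#' Expected number of steps to first reach state `j` starting from state
#' `i`: `t[i, j] = (Z[j, j] - Z[i, j]) / x[j]`, with zero diagonal by
#' convention. The entry `t[2, S]` is the model's consolidation timescale:
#' the mean time for a freshly stabilised connection (state 2) to first
#' reach the strongest state.
#'
#' @param Z Fundamental matrix from [fundamental_matrix()].
#' @param x Equilibrium vector.
#' @return `S x S` matrix of expected hitting times (time steps).
#' @export
first_passage_times <- function(Z, x) {
  S <- length(x)
  if (!is.matrix(Z) || nrow(Z) != S || ncol(Z) != S)
    stop("Z and x have inconsistent dimensions")
  tt <- (matrix(diag(Z), S, S, byrow = TRUE) - Z) / matrix(x, S, S, byrow = TRUE)
  diag(tt) <- 0
  dimnames(tt) <- dimnames(Z)
  tt
}

#' Asymptotic occupancy variances
#'
#' Long-run variance of the fraction of time a connection spends in each
#' state: `sigma2[j] = 2 * x[j] * Z[j, j] - x[j] - x[j]^2`. For the fully
#' mixing chain (`P` with identical rows `x`, so `Z = I`) this reduces to
#' the i.i.d. Bernoulli variance `x[j] * (1 - x[j])`.
#'
#' @inheritParams first_passage_times
#' @return Numeric vector of `S` variances (per-step occupancy scale).
#' @export
asymptotic_variance <- function(Z, x) {
  S <- length(x)
  if (!is.matrix(Z) || nrow(Z) != S) stop("Z and x have inconsistent dimensions")
  2 * x * diag(Z) - x - x^2
}

#' Combined passage analysis of a chain
#'
#' Convenience wrapper returning the fundamental matrix, the full
#' first-passage-time matrix and the asymptotic occupancy variances in one
#' `passage_summary` object.
#'
#' @inheritParams fundamental_matrix
#' @return A list of class `passage_summary` with elements `Z`, `t`,
#'   `sigma2`.
#' @export
passage_summary <- function(spec, P = NULL) {
  if (is.null(P)) P <- build_transition_matrix(spec)
  Z <- fundamental_matrix(spec, P)
  structure(
    list(Z = Z, t = first_passage_times(Z, spec$x),
         sigma2 = asymptotic_variance(Z, spec$x)),
    class = "passage_summary"
  )
}

#' @export
print.passage_summary <- function(x, ...) {
  S <- nrow(x$Z)
  cat(sprintf("Passage analysis of a %d-state chain\n", S))
  cat(sprintf("  consolidation time t[2,%d]: %.4g steps\n", S, x$t[2, S]))
  cat("  asymptotic occupancy variances:", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}
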