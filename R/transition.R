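#' Build the tridiagonal transition matrix of the connection random walk
#'
#' Constructs the per-step transition matrix `P` of the reflecting random
#' walk over `S` connection states. Up-moves are `P[i, i+1] = x[i+1] * y[i]`,
#' down-moves are `P[i+1, i] = x[i] * y[i]`, and the diagonal takes the
#' remainder so each row sums to 1. Detailed balance
#' `x[i] * P[i, i+1] == x[i+1] * P[i+1, i]` holds by construction, which
#' makes `x` the stationary distribution regardless of the choice of `y`.
#'
#' @param spec A [chain_spec()].
#' @return An `S x S` stochastic matrix with `dimnames`
#'   `state_1 ... state_S`.
#' @export
#' @examples
#' P <- build_transition_matrix(chain_spec(c(0.5, 0.3, 0.2), c(0.2, 0.1)))
#' rowSums(P)
build_transition_matrix <- function(spec) {
  validate_chain_spec(spec)
  S <- spec$S; x <- spec$x; y <- spec$y
  P <- matrix(0, S, S)
  for (i in seq_len(S - 1)) {
    P[i, i + 1] <- x[i + 1] * y[i]
    P[i + 1, i] <- x[i] * y[i]
  }
  diag(P) <- 1 - rowSums(P)
  if (any(diag(P) < -1e-12)) {
    bad <- which.min(diag(P))
    stop(sprintf("negative diagonal in row %d; spec is invalid", bad))
  }
  diag(P) <- pmax(diag(P), 0)
  dimnames(P) <- list(paste0("state_", seq_len(S)), paste0("state_", seq_len(S)))
  P
}

#' Stationarity residual of the equilibrium distribution
#'
#' Returns `max_i |(xP)_i - x_i|`, the largest componentwise violation of
#' stationarity. For any matrix built by [build_transition_matrix()] this is
#' at floating-point level (below 1e-12): detailed balance forces `x` to be
#' the equilibrium distribution.
#'
#' @param spec A [chain_spec()].
#' @param P Transition matrix consistent with `spec`.
#' @return Scalar maximum absolute residual.
#' @export
verify_equilibrium <- function(spec, P) {
  if (!is.matrix(P) || nrow(P) != spec$S || ncol(P) != spec$S)
    stop("P must be an S x S matrix matching spec")
  max(abs(drop(spec$x %*% P) - spec$x))
}

#' Expected dwell times of the connection states
#'
#' The expected number of consecutive steps a connection spends in state `i`
#' before leaving it is `1 / (1 - P[i, i])` (a geometric waiting time). For
#' the highest state the only exit probability is `y[S-1] * x[S-1]`, so e.g.
#' `x[S-1] = 0.02`, `y[S-1] = 0.005` gives a 1/10,000 per-step reversion
#' probability and a 10,000-step expected lifetime — with one step per day,
#' over 25 years. An absorbing state (diagonal exactly 1) is reported as an
#' explicit `Inf`, never an overflow.
#'
#' @param P Transition matrix.
#' @return Numeric vector of `S` expected dwell times, in time steps.
#' @export
state_lifetimes <- function(P) {
  d <- diag(P)
  ifelse(d >= 1, Inf, 1 / (1 - d))
}

#' Evolve a state distribution forward in time
#'
#' Computes `v %*% P^t`. The matrix power is taken by repeated squaring
#' (`method = "power"`, exact to machine precision in O(log t) matrix
#' products) or through the symmetrized eigendecomposition of the reversible
#' chain (`method = "eigen"`); the two agree to 1e-10 and `"auto"` picks the
#' power method.
#'
#' @param v Probability vector over the `S` states.
#' @param P Transition matrix.
#' @param t Nonnegative integer number of steps.
#' @param method `"auto"`, `"power"` or `"eigen"`.
#' @param x Equilibrium vector; required for `method = "eigen"`.
#' @return Probability vector after `t` steps.
#' @export
evolve_distribution <- function(v, P, t, method = c("auto", "power", "eigen"),
                                x = NULL) {
  method <- match.arg(method)
  if (t < 0) stop("t must be nonnegative")
  t <- as.numeric(t)
  if (t != floor(t)) stop("t must be an integer number of steps")
  check_distribution(v, nrow(P))
  if (method == "eigen") {
    if (is.null(x)) stop("method = 'eigen' requires the equilibrium vector x")
    ed <- reversible_eigen(P, x)
    return(drop(propagate_modes(rbind(v), ed, t)))
  }
  drop(v %*% mat_power(P, t))
}

# Matrix power by repeated squaring.
mat_power <- function(P, t) {
  S <- nrow(P)
  out <- diag(S)
  base <- P
  while (t > 0) {
    if (t %% 2 == 1) out <- out %*% base
    t <- t %/% 2
    if (t > 0) base <- base %*% base
  }
  out
}

check_distribution <- function(v, S, tol = 1e-9) {
  if (length(v) != S) stop("distribution has wrong length")
  if (any(v < -tol)) stop("distribution has negative entries")
  if (abs(sum(v) - 1) > tol) stop("distribution does not sum to 1")
  invisible(v)
}

# Symmetrized eigendecomposition of a reversible chain: with D = diag(x),
# M = D^{1/2} P D^{-1/2} is symmetric, so P = D^{-1/2} U L U' D^{1/2} with
# real spectrum. Returns pieces needed to propagate any row vector.
reversible_eigen <- function(P, x) {
  s <- sqrt(x)
  M <- sweep(sweep(P, 1, s, `*`), 2, s, `/`)
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  list(values = ee$values, U = ee$vectors, s = s)
}

# rows of V evolved t steps: V P^t = (V D^{-1/2} U) L^t (U' D^{1/2})
propagate_modes <- function(V, ed, t) {
  left <- sweep(V, 2, ed$s, `/`) %*% ed$U
  lam_t <- ifelse(ed$values == 0 & t == 0, 1, ed$values^t)
  out <- sweep(left, 2, lam_t, `*`) %*% t(ed$U)
  sweep(out, 2, ed$s, `*`)
}
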