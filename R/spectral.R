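#' Spectral analysis of the forgetting rate
#'
#' A reversible chain has a real spectrum; after a memory is learned, the
#' distance of the connection-state distribution from equilibrium decays for
#' large `t` like `a2 * lambda2^t`, where `lambda2` is the second-largest
#' eigenvalue of `P`. `-log(lambda2)` is therefore the asymptotic forgetting
#' rate per time step, and it is dominated by the (low) plasticity of the
#' top states: chains with a near-absorbing strongest state have `lambda2`
#' close to 1 and multi-year forgetting tails.
#'
#' The eigendecomposition is taken on the symmetrization
#' `D^{1/2} P D^{-1/2}` (`D = diag(x)`), which guarantees real eigenvalues.
#' The tail coefficient `a2` is estimated by regressing the log Euclidean
#' distance from equilibrium against `t` over a late-time window where the
#' third mode has decayed to relative amplitude below `cutoff`.
#'
#' @param P Transition matrix.
#' @param x Equilibrium vector of `P`.
#' @param v0 Initial distribution used for the tail-coefficient regression;
#'   default is a point mass on state 1.
#' @param cutoff Relative amplitude of mode 3 vs mode 2 defining the start
#'   of the late-time window.
#' @return An object of class `spectral_summary`: `eigenvalues` (sorted
#'   descending, leading value 1), `lambda2`, `tail_rate = -log(lambda2)`,
#'   `tail_coefficient`.
#' @export
spectral_summary <- function(P, x, v0 = NULL, cutoff = 1e-8) {
  S <- nrow(P)
  ed <- reversible_eigen(P, x)
  vals <- sort(ed$values, decreasing = TRUE)
  if (abs(vals[1] - 1) > 1e-10)
    stop("leading eigenvalue differs from 1; matrix is not a proper stochastic matrix")
  if (any(vals < -1 - 1e-10) || any(vals > 1 + 1e-10))
    stop("eigenvalues outside [-1, 1]; reversibility violated upstream")
  lambda2 <- vals[2]
  if (is.null(v0)) v0 <- c(1, rep(0, S - 1))
  tail_coefficient <- estimate_tail_coefficient(v0, ed, x, vals, cutoff)
  structure(
    list(eigenvalues = vals, lambda2 = lambda2,
         tail_rate = -log(lambda2), tail_coefficient = tail_coefficient),
    class = "spectral_summary"
  )
}

# Fit log ||v P^t - x|| ~ t on a window where only the lambda2 mode remains.
estimate_tail_coefficient <- function(v0, ed, x, vals, cutoff) {
  lambda2 <- vals[2]
  if (lambda2 <= 0) return(NA_real_)
  lam3 <- if (length(vals) >= 3) abs(vals[3]) else 0
  t_start <- if (lam3 > 0 && lam3 < lambda2) {
    ceiling(log(cutoff) / (log(lam3) - log(lambda2)))
  } else 1
  t_start <- max(t_start, 1)
  steps <- unique(round(seq(t_start, t_start + 50 / (1 - lambda2 + 1e-12),
                            length.out = 25)))
  d <- vapply(steps, function(t) {
    vt <- drop(propagate_modes(rbind(v0), ed, t))
    sqrt(sum((vt - x)^2))
  }, numeric(1))
  keep <- d > 1e-300
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log(d[keep]) ~ steps[keep])
  exp(unname(stats::coef(fit)[1]))
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("Spectrum:", format(x$eigenvalues, digits = 6), "\n")
  cat(sprintf("  lambda2 = %.8g, tail forgetting rate = %.4g per step\n",
              x$lambda2, x$tail_rate))
  if (!is.na(x$tail_coefficient))
    cat(sprintf("  tail coefficient a2 = %.4g\n", x$tail_coefficient))
  invisible(x)
}
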