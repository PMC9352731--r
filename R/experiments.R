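#' Trace strength: excess expected net input over the equilibrium baseline
#'
#' The default retention metric. A memory trace with connection-state
#' distribution `v` contributes expected net input `A * sum(w(i) * v[i])`
#' to each output neuron; subtracting the equilibrium baseline
#' `A * sum(w(i) * x[i])` leaves the learned signal
#' `Delta net = A * sum(w(i) * (v[i] - x[i]))`. Immediately after one
#' learning unit at equilibrium this equals
#' `x[1] * p[1,2] * mu * A / (S - 1)`, and it decays to 0 as the chain
#' relaxes back to `x`.
#'
#' @param v State distribution of the trace.
#' @param spec A [chain_spec()].
#' @param A Input-neuron count.
#' @param alpha Weight scale.
#' @return Scalar strength (weight units).
#' @export
trace_strength <- function(v, spec, A, alpha = 1) {
  w <- state_weight(seq_len(spec$S), spec$S, alpha)
  A * sum(w * (v - spec$x))
}

# strength of a (possibly signed) deviation vector d = v - x
deviation_strength <- function(d, spec, A, alpha = 1) {
  A * sum(state_weight(seq_len(spec$S), spec$S, alpha) * d)
}

# deviation d evolved over several times at once (eigendecomposition)
evolve_deviation <- function(d, spec, P, times) {
  ed <- reversible_eigen(P, spec$x)
  t(vapply(times, function(t) drop(propagate_modes(rbind(d), ed, t)),
           numeric(spec$S)))
}

#' Forgetting curve of a single learned trace
#'
#' Learns one pattern at equilibrium and tracks retention over time. With
#' `metric = "net"` the curve is the exact excess net input
#' `Delta net(t)` of the evolving distribution (deterministic, via the
#' chain's eigendecomposition); with `metric = "simulated"` an explicit
#' `A x B` ensemble is drifted stochastically and retention is the fraction
#' of output neurons active under a full cue.
#'
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @param A Input-neuron count.
#' @param t_max Largest probe time; ignored when `times` is given.
#' @param times Optional vector of probe times; default is about 60
#'   log-spaced times from 0 to `t_max`.
#' @param metric `"net"` or `"simulated"`.
#' @param units Learning units in the single episode.
#' @param B Output-neuron count (simulated metric).
#' @param seed Seed (simulated metric).
#' @return Object of class `forgetting_curve`: data frame with columns
#'   `t`, `strength`.
#' @export
forgetting_experiment <- function(spec, params, A = 1000, t_max = 10000,
                                  times = NULL,
                                  metric = c("net", "simulated"),
                                  units = 1L, B = 200, seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(times)) {
    stopifnot(t_max >= 1)
    times <- unique(c(0, round(exp(seq(0, log(t_max), length.out = 60)))))
  }
  times <- sort(unique(times))
  P <- build_transition_matrix(spec)
  if (metric == "net") {
    v1 <- learn_distribution(spec$x, spec, params, units)
    dmat <- evolve_deviation(v1 - spec$x, spec, P, times)
    strength <- apply(dmat, 1, deviation_strength, spec = spec, A = A,
                      alpha = params$alpha)
  } else {
    strength <- simulated_forgetting(spec, params, A, B, times, units, seed)
  }
  structure(data.frame(t = times, strength = strength),
            class = c("forgetting_curve", "data.frame"))
}

# drift an explicit ensemble and probe recall at the requested times
simulated_forgetting <- function(spec, params, A, B, times, units, seed) {
  ens <- new_ensemble(spec, A, B, init = "equilibrium", seed = seed)
  ens <- learn_ensemble(ens, spec, params, units = units, seed = seed + 1L)
  S <- spec$S
  p_up <- c(spec$x[-1] * spec$y, 0)
  p_down <- c(0, spec$x[-S] * spec$y)
  withr::with_seed(seed + 2L, {
    st <- ens$states
    now <- 0L
    vapply(times, function(tt) {
      while (now < tt) {
        u <- stats::runif(length(st))
        up <- p_up[st]
        down <- p_down[st]
        st <<- st + (u < up) - (u >= up & u < up + down)
        now <<- now + 1L
      }
      ens$states <- st
      retrieve(ens, 1, spec, params, seed = seed + 3L)$fraction_active
    }, numeric(1))
  })
}

#' Classify the shape of a forgetting curve
#'
#' Fits a power law (`log strength ~ log t`) and an exponential
#' (`log strength ~ t`) on an early-time and a late-time window and reports
#' the R-squared of each fit, plus a plateau estimate (mean strength over
#' the final window). For chains with low top-state plasticity the early
#' portion — a mixture of many exponentials with spread rates — is closer
#' to a power curve, while the tail, dominated by the second eigenvalue,
#' is closer to a single exponential.
#'
#' @param curve A [forgetting_experiment()] result (or any data frame with
#'   `t`, `strength`; at least 20 points spanning both regimes).
#' @param early_window,late_window Length-2 time ranges. Defaults: the
#'   lower half of the positive probe times on a log scale (the regime
#'   where several eigenmodes are still mixed — the power-law region) and
#'   the top quarter (where only the slowest mode survives).
#' @return List of class `curve_shape`: `early_power_r2`, `early_exp_r2`,
#'   `late_power_r2`, `late_exp_r2`, `power_exponent`, `exp_rate`
#'   (late-window log-slope per step), `plateau`.
#' @export
classify_curve_shape <- function(curve, early_window = NULL,
                                 late_window = NULL) {
  ok <- curve$t > 0 & curve$strength > 0
  if (sum(ok) < 20)
    stop("curve must have at least 20 positive points spanning early and late times")
  tt <- curve$t[ok]; ss <- curve$strength[ok]
  if (diff(range(ss)) / max(ss) < 1e-12)
    stop("degenerate (constant) curve; shape is undefined")
  lr <- range(log(tt))
  if (is.null(early_window))
    early_window <- exp(c(lr[1], lr[1] + diff(lr) / 2))
  if (is.null(late_window))
    late_window <- exp(c(lr[2] - diff(lr) / 4, lr[2]))
  fit_r2 <- function(xx, yy) {
    if (length(xx) < 3) return(list(r2 = NA_real_, slope = NA_real_))
    f <- stats::lm(yy ~ xx)
    ss_tot <- sum((yy - mean(yy))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(f)^2) / ss_tot else NA_real_
    list(r2 = r2, slope = unname(stats::coef(f)[2]))
  }
  in_early <- tt >= early_window[1] & tt <= early_window[2]
  in_late <- tt >= late_window[1] & tt <= late_window[2]
  ep <- fit_r2(log(tt[in_early]), log(ss[in_early]))
  ee <- fit_r2(tt[in_early], log(ss[in_early]))
  lp <- fit_r2(log(tt[in_late]), log(ss[in_late]))
  le <- fit_r2(tt[in_late], log(ss[in_late]))
  structure(list(early_power_r2 = ep$r2, early_exp_r2 = ee$r2,
                 late_power_r2 = lp$r2, late_exp_r2 = le$r2,
                 power_exponent = ep$slope, exp_rate = le$slope,
                 plateau = mean(curve$strength[curve$t >= late_window[1]])),
            class = "curve_shape")
}

#' @export
print.curve_shape <- function(x, ...) {
  cat(sprintf("Early window:  power R2 = %.5f | exponential R2 = %.5f\n",
              x$early_power_r2, x$early_exp_r2))
  cat(sprintf("Late window:   power R2 = %.5f | exponential R2 = %.5f\n",
              x$late_power_r2, x$late_exp_r2))
  cat(sprintf("Late log-slope %.4g per step; plateau estimate %.4g\n",
              x$exp_rate, x$plateau))
  invisible(x)
}

# Bisection for the learning rate that gives a target trace strength.
# strength_fn(mu) must be continuous and nondecreasing on [0, 1].
calibrate_mu <- function(strength_fn, target, rel_tol = 1e-10) {
  f1 <- strength_fn(1)
  if (f1 < target * (1 - 1e-12))
    return(list(mu = NA_real_, feasible = FALSE,
                message = sprintf("required mu > 1 (strength at mu = 1 is %.6g < target %.6g)",
                                  f1, target)))
  lo <- 0; hi <- 1
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (strength_fn(mid) < target) lo <- mid else hi <- mid
    if ((hi - lo) <= rel_tol * max(hi, 1e-30)) break
  }
  mu <- (lo + hi) / 2
  list(mu = mu, feasible = TRUE, achieved = strength_fn(mu))
}

#' Jost's law of forgetting: the older of two equal-strength traces decays
#' slower
#'
#' Builds an *old* trace (learned with rate `params$mu`, then drifted
#' `age_old` steps) and a *young* trace whose learning rate is calibrated
#' by bisection so both have exactly equal strength at probe time 0. Both
#' are then drifted and probed: the old trace, having moved mass into
#' higher, less plastic states, retains more strength at every later probe.
#'
#' @param spec A [chain_spec()].
#' @param params [learning_params()] for the old trace.
#' @param age_old Age (steps) of the old trace at matching time.
#' @param t_probe Vector of probe delays (steps) after matching.
#' @param A Input-neuron count.
#' @return List of class `jost_report`: `mu_young`, `feasible`, and a data
#'   frame `probes` with `t_probe`, `strength_old`, `strength_young`.
#' @export
jost_decay_experiment <- function(spec, params, age_old, t_probe,
                                  A = 1000) {
  P <- build_transition_matrix(spec)
  d_old <- trace_deviation_at_age(spec, P, params$mu, age_old)
  target <- deviation_strength(d_old, spec, A, params$alpha)
  fresh_strength <- function(mu)
    deviation_strength(trace_deviation_at_age(spec, P, mu, 0), spec, A,
                       params$alpha)
  cal <- calibrate_mu(fresh_strength, target)
  if (!cal$feasible)
    return(structure(list(mu_young = NA_real_, feasible = FALSE,
                          message = cal$message, probes = NULL),
                     class = "jost_report"))
  d_young <- trace_deviation_at_age(spec, P, cal$mu, 0)
  probes <- data.frame(
    t_probe = t_probe,
    strength_old = strengths_at(d_old, spec, P, t_probe, A, params$alpha),
    strength_young = strengths_at(d_young, spec, P, t_probe, A, params$alpha))
  structure(list(mu_young = cal$mu, feasible = TRUE, age_old = age_old,
                 matched_strength = target, probes = probes),
            class = "jost_report")
}

# deviation (v - x) of a trace learned at equilibrium with rate mu, aged t
trace_deviation_at_age <- function(spec, P, mu, age) {
  v1 <- learn_distribution(spec$x, spec, learning_params(mu = mu), 1L)
  d <- v1 - spec$x
  if (age > 0) d <- drop(evolve_deviation(d, spec, P, age))
  d
}

strengths_at <- function(d, spec, P, times, A, alpha) {
  dmat <- evolve_deviation(d, spec, P, times)
  apply(dmat, 1, deviation_strength, spec = spec, A = A, alpha = alpha)
}

#' Jost's law of learning: the older of two equal-strength traces benefits
#' more from relearning
#'
#' Equal-strength old and young traces are built as in
#' [jost_decay_experiment()]; identical additional learning is then applied
#' to both. The strength increment of a trace with current state-1 mass
#' `v1` is `v1 * p[1,2] * mu * A / (S - 1)`; the old trace, whose state-1
#' pool has been replenished by drift, gains more.
#'
#' @inheritParams jost_decay_experiment
#' @param relearn_units Units of additional learning applied to both.
#' @param relearn_mu Learning rate of the additional episode (defaults to
#'   `params$mu`).
#' @return List of class `jost_report`: calibration details plus
#'   `increment_old`, `increment_young`, `state1_old`, `state1_young`.
#' @export
jost_learning_experiment <- function(spec, params, age_old,
                                     relearn_units = 1L, relearn_mu = NULL,
                                     A = 1000) {
  if (is.null(relearn_mu)) relearn_mu <- params$mu
  P <- build_transition_matrix(spec)
  d_old <- trace_deviation_at_age(spec, P, params$mu, age_old)
  target <- deviation_strength(d_old, spec, A, params$alpha)
  fresh_strength <- function(mu)
    deviation_strength(trace_deviation_at_age(spec, P, mu, 0), spec, A,
                       params$alpha)
  cal <- calibrate_mu(fresh_strength, target)
  if (!cal$feasible)
    return(structure(list(feasible = FALSE, message = cal$message),
                     class = "jost_report"))
  d_young <- trace_deviation_at_age(spec, P, cal$mu, 0)
  rp <- learning_params(mu = relearn_mu, alpha = params$alpha)
  inc <- function(d) {
    v <- spec$x + d
    v2 <- learn_distribution(v, spec, rp, relearn_units)
    deviation_strength(v2 - spec$x, spec, A, params$alpha) -
      deviation_strength(d, spec, A, params$alpha)
  }
  structure(list(feasible = TRUE, mu_young = cal$mu, age_old = age_old,
                 matched_strength = target,
                 increment_old = inc(d_old), increment_young = inc(d_young),
                 state1_old = spec$x[1] + d_old[1],
                 state1_young = spec$x[1] + d_young[1]),
            class = "jost_report")
}

#' Spacing effect: spaced learning outlasts strength-matched massed
#' learning
#'
#' A spaced trace receives `k_episodes` learning episodes separated by
#' `gap` drift steps; a massed trace receives `k_episodes` back-to-back
#' episodes whose learning rate is calibrated by bisection so both traces
#' have equal strength immediately after their final episode. At every
#' later probe the spaced trace is at least as strong: the drift intervals
#' let part of its increment climb into slower, higher states.
#'
#' @param spec A [chain_spec()].
#' @param params [learning_params()] for the spaced trace.
#' @param k_episodes Number of learning episodes.
#' @param gap Drift steps between spaced episodes.
#' @param t_probe Vector of probe delays after the matching point.
#' @param A Input-neuron count.
#' @return List of class `spacing_report`: `mu_massed`, `feasible`,
#'   deviations at match time, and a data frame `probes` with columns
#'   `t_probe`, `strength_spaced`, `strength_massed`.
#' @export
spacing_experiment <- function(spec, params, k_episodes, gap, t_probe,
                               A = 1000) {
  stopifnot(k_episodes >= 1, gap >= 0)
  P <- build_transition_matrix(spec)
  spaced_v <- function(mu) {
    v <- spec$x
    lp <- learning_params(mu = mu, alpha = params$alpha)
    for (k in seq_len(k_episodes)) {
      v <- learn_distribution(v, spec, lp, 1L)
      if (k < k_episodes && gap > 0)
        v <- spec$x + drop(evolve_deviation(v - spec$x, spec, P, gap))
    }
    v
  }
  massed_v <- function(mu)
    learn_distribution(spec$x, spec, learning_params(mu = mu,
                                                     alpha = params$alpha),
                       k_episodes)
  v_sp <- spaced_v(params$mu)
  target <- trace_strength(v_sp, spec, A, params$alpha)
  cal <- calibrate_mu(function(mu) trace_strength(massed_v(mu), spec, A,
                                                  params$alpha), target)
  if (!cal$feasible)
    return(structure(list(feasible = FALSE, message = cal$message),
                     class = "spacing_report"))
  v_ms <- massed_v(cal$mu)
  probes <- data.frame(
    t_probe = t_probe,
    strength_spaced = strengths_at(v_sp - spec$x, spec, P, t_probe, A,
                                   params$alpha),
    strength_massed = strengths_at(v_ms - spec$x, spec, P, t_probe, A,
                                   params$alpha))
  structure(list(feasible = TRUE, mu_massed = cal$mu,
                 matched_strength = target,
                 deviation_spaced = v_sp - spec$x,
                 deviation_massed = v_ms - spec$x, probes = probes),
            class = "spacing_report")
}

#' Diffuse lesion model
#'
#' A lesion deletes each connection in state `i >= 2` with probability
#' `q[i]`, sending it to state 1. Vulnerability decreases with connection
#' strength, so `q` must be non-increasing over states `2..S`; `q[1] = 0`
#' by convention (absent connections cannot be deleted).
#'
#' @param q Vector of `S` per-state deletion probabilities.
#' @return Object of class `lesion_model`.
#' @seealso [lesion_model_power()] for the standard one-parameter family.
#' @export
lesion_model <- function(q) {
  if (any(q < 0 | q > 1)) stop("deletion probabilities must lie in [0, 1]")
  if (q[1] != 0) stop("q[1] must be 0: state-1 connections are absent")
  if (length(q) >= 3 && any(diff(q[-1]) > 1e-12))
    stop("q must be non-increasing over states 2..S (vulnerability decreases with strength)")
  structure(list(q = q), class = "lesion_model")
}

#' One-parameter diffuse lesion family
#'
#' `q[i] = q_base * (1 - w(i))^gamma` for `i >= 2` (`q[1] = 0`), where
#' `w(i)` is the state weight. `gamma = 0` gives uniform lesioning of all
#' present connections (a control); larger `gamma` concentrates damage on
#' weak connections. The strongest state (`w = 1`) is never deleted when
#' `gamma > 0`.
#'
#' @param S Number of states.
#' @param q_base Deletion probability scale in `[0, 1]`.
#' @param gamma Nonnegative strength-protection exponent.
#' @return A [lesion_model()].
#' @export
lesion_model_power <- function(S, q_base = 0.8, gamma = 1) {
  if (q_base < 0 || q_base > 1) stop("q_base must lie in [0, 1]")
  if (gamma < 0) stop("gamma must be nonnegative")
  w <- state_weight(seq_len(S), S, 1)
  q <- q_base * (1 - w)^gamma
  q[1] <- 0
  lesion_model(q)
}

#' Apply a lesion to a state distribution
#'
#' Distribution-level lesioning: mass `q[i] * v[i]` moves from each state
#' `i >= 2` to state 1. Linear in `v`, so it commutes with expectation over
#' ensembles.
#'
#' @param v State distribution (or signed deviation vector).
#' @param lesion A [lesion_model()].
#' @return The lesioned vector.
#' @export
apply_lesion <- function(v, lesion) {
  q <- lesion$q
  if (length(v) != length(q)) stop("dimension mismatch between v and lesion")
  out <- (1 - q) * v
  out[1] <- out[1] + sum(q * v)
  out
}

#' Apply a lesion to an explicit ensemble
#'
#' Each connection in state `i >= 2` is independently reset to state 1 with
#' probability `q[i]`.
#'
#' @param ens A [new_ensemble()].
#' @param lesion A [lesion_model()].
#' @param seed Integer seed.
#' @return The lesioned `memory_ensemble`.
#' @export
apply_lesion_ensemble <- function(ens, lesion, seed = 1L) {
  q <- lesion$q
  if (length(q) != ens$S) stop("lesion and ensemble have different S")
  st <- ens$states
  withr::with_seed(seed, {
    hit <- stats::runif(length(st)) < q[st]
    st[hit] <- 1L
  })
  ens$states <- st
  ens
}

#' Logistic strength-to-recall link
#'
#' Maps trace strength to a recall probability,
#' `p = plogis(beta0 + beta1 * strength)`. The defaults place a freshly
#' learned default-spec trace (`A = 1000`, `mu = 1`) at recall around 0.9
#' and a fully forgotten trace at around 0.05.
#'
#' @param beta0 Intercept (log-odds of recall at zero strength).
#' @param beta1 Positive slope per weight unit of strength.
#' @return Object of class `retrieval_link`.
#' @export
retrieval_link <- function(beta0 = -3, beta1 = 0.8) {
  if (beta1 <= 0) stop("beta1 must be positive")
  structure(list(beta0 = beta0, beta1 = beta1), class = "retrieval_link")
}

link_prob <- function(link, strength)
  stats::plogis(link$beta0 + link$beta1 * strength)

#' Ribot gradient under diffuse lesioning
#'
#' For each memory age, learns a trace at equilibrium, drifts it `age`
#' steps, and computes recall probability before (control) and after
#' (patient) a diffuse lesion. Post-lesion strength is measured against the
#' equally lesioned background (the lesion hits trace and background
#' connections alike and inhibition tracks the background), so
#' `strength_post = A * sum_{i>=2} w(i) * (1 - q[i]) * (v[i] - x[i])`.
#' The relative retrograde gradient is the ratio of log-transformed recall
#' probabilities, `log(p_patient) / log(p_control)`. Because old traces
#' hold their excess strength in high, lesion-resistant states, the
#' retained-strength ratio grows with age: recent memories are hit hardest
#' (Ribot's law).
#'
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @param lesion A [lesion_model()].
#' @param ages Vector of memory ages (steps) at lesion time.
#' @param A Input-neuron count.
#' @param link A [retrieval_link()].
#' @param eps Floor applied to probabilities before taking logs.
#' @return Object of class `ribot_gradient`: data frame with columns
#'   `age`, `strength_pre`, `strength_post`, `control_p`, `patient_p`,
#'   `relative`.
#' @export
lesion_experiment <- function(spec, params, lesion, ages, A = 1000,
                              link = retrieval_link(), eps = 1e-6) {
  if (length(lesion$q) != spec$S) stop("lesion and spec have different S")
  P <- build_transition_matrix(spec)
  d0 <- trace_deviation_at_age(spec, P, params$mu, 0)
  dmat <- evolve_deviation(d0, spec, P, ages)
  w <- state_weight(seq_len(spec$S), spec$S, params$alpha)
  s_pre <- as.numeric(dmat %*% w) * A
  s_post <- as.numeric(dmat %*% (w * (1 - lesion$q))) * A
  control_p <- link_prob(link, s_pre)
  patient_p <- link_prob(link, s_post)
  floored <- control_p < eps | patient_p < eps
  if (any(floored))
    warning(sprintf("%d recall probabilities below eps = %g floored before log transform",
                    sum(floored), eps))
  control_p <- pmax(control_p, eps)
  patient_p <- pmax(patient_p, eps)
  if (any(control_p >= 1))
    warning("control recall probability of 1: relative gradient undefined at that age")
  structure(data.frame(age = ages, strength_pre = s_pre,
                       strength_post = s_post, control_p = control_p,
                       patient_p = patient_p,
                       relative = log(patient_p) / log(control_p)),
            class = c("ribot_gradient", "data.frame"))
}
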