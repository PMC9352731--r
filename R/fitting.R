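#' Retention dataset of two-group recall proportions
#'
#' Observed recall proportions by memory age for a control and a patient
#' (lesioned) group, the input to [relative_gradient()] and [fit_model()].
#'
#' @param age Memory ages (positive, in time steps/units of the study).
#' @param p_recall Recall proportions in `(0, 1]`.
#' @param group `"control"` or `"patient"` per record.
#' @param n_items Optional item counts behind each proportion.
#' @return Object of class `retention_dataset` (a data frame with columns
#'   `age`, `p_recall`, `n_items`, `group`).
#' @export
retention_dataset <- function(age, p_recall, group, n_items = NA_integer_) {
  df <- data.frame(age = age, p_recall = p_recall,
                   n_items = n_items, group = as.character(group))
  if (any(df$age <= 0)) stop("ages must be positive")
  if (any(df$p_recall <= 0 | df$p_recall > 1))
    stop("recall proportions must lie in (0, 1]")
  if (!all(df$group %in% c("control", "patient")))
    stop("group must be 'control' or 'patient'")
  for (g in unique(df$group))
    if (length(unique(df$age[df$group == g])) < 3)
      stop(sprintf("group '%s' needs at least 3 distinct ages", g))
  structure(df, class = c("retention_dataset", "data.frame"))
}

#' Read and write retention datasets as CSV
#'
#' Plain CSV with header `age,p_recall,n_items,group`.
#'
#' @param dataset A [retention_dataset()].
#' @param path File path.
#' @return `read_retention_csv()` returns a `retention_dataset`;
#'   `write_retention_csv()` returns `path` invisibly.
#' @export
write_retention_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_retention_csv
#' @export
read_retention_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  retention_dataset(df$age, df$p_recall, df$group,
                    if ("n_items" %in% names(df)) df$n_items else NA_integer_)
}

#' Relative retrograde gradient of a retention dataset
#'
#' For each age with a matched control/patient pair, the ratio of the
#' log-transformed recall probabilities,
#' `rg(age) = log(p_patient) / log(p_control)`. Identical groups give a
#' flat gradient of 1; a value above 1 means the patient group is
#' disproportionately impaired at that age. Ages where `p_control = 1`
#' (zero log) are excluded with a warning; proportions are floored at
#' `eps` before the log transform.
#'
#' @param dataset A [retention_dataset()].
#' @param eps Probability floor for the log transform.
#' @return Data frame with columns `age`, `p_control`, `p_patient`, `rg`.
#' @export
relative_gradient <- function(dataset, eps = 1e-6) {
  ctrl <- dataset[dataset$group == "control", ]
  pat <- dataset[dataset$group == "patient", ]
  ages <- intersect(ctrl$age, pat$age)
  if (!length(ages)) stop("no matched ages between control and patient groups")
  unmatched <- setdiff(union(ctrl$age, pat$age), ages)
  if (length(unmatched))
    warning(sprintf("%d unmatched ages dropped", length(unmatched)))
  pc <- ctrl$p_recall[match(ages, ctrl$age)]
  pp <- pat$p_recall[match(ages, pat$age)]
  if (any(pc < eps | pp < eps)) {
    warning(sprintf("proportions below eps = %g floored before log transform", eps))
    pc <- pmax(pc, eps); pp <- pmax(pp, eps)
  }
  keep <- pc < 1
  if (any(!keep))
    warning(sprintf("%d ages with p_control = 1 excluded (log of 1 is 0)",
                    sum(!keep)))
  ord <- order(ages[keep])
  data.frame(age = ages[keep][ord], p_control = pc[keep][ord],
             p_patient = pp[keep][ord],
             rg = (log(pp[keep]) / log(pc[keep]))[ord])
}

# Model-predicted recall probabilities for both groups at given ages.
# Strength is linear in mu (single learning unit at equilibrium), so the
# age profile is precomputed once per spec and reused across optimizer
# evaluations.
retention_profile <- function(spec, ages) {
  P <- build_transition_matrix(spec)
  d0 <- trace_deviation_at_age(spec, P, 1, 0)   # deviation per unit mu
  evolve_deviation(d0, spec, P, ages)           # length(ages) x S
}

predict_retention <- function(profile, spec, mu, lesion, link, A) {
  w <- state_weight(seq_len(spec$S), spec$S, 1)
  s_pre <- as.numeric(profile %*% w) * A * mu
  s_post <- as.numeric(profile %*% (w * (1 - lesion$q))) * A * mu
  list(control_p = link_prob(link, s_pre),
       patient_p = link_prob(link, s_post),
       strength_pre = s_pre, strength_post = s_post)
}

#' Generate a synthetic two-group retention dataset from the model
#'
#' Stand-in for external retention studies: for each age, the control
#' recall probability is the link applied to the trace strength at that
#' age, and the patient probability is the link applied to the post-lesion
#' strength. Observed proportions are binomial draws with `n_items` trials
#' per point (or the exact probabilities when `noise = FALSE`).
#'
#' @param spec A [chain_spec()].
#' @param params [learning_params()].
#' @param lesion A [lesion_model()].
#' @param link A [retrieval_link()].
#' @param ages Vector of memory ages.
#' @param n_items Items per (age, group) cell.
#' @param seed Integer seed.
#' @param A Input-neuron count.
#' @param noise Draw binomial noise? `FALSE` returns exact probabilities.
#' @return A [retention_dataset()].
#' @export
generate_retention_dataset <- function(spec, params, lesion,
                                       link = retrieval_link(), ages,
                                       n_items = 50, seed = 1L, A = 1000,
                                       noise = TRUE) {
  stopifnot(length(ages) >= 1, n_items >= 1)
  profile <- retention_profile(spec, ages)
  pr <- predict_retention(profile, spec, params$mu, lesion, link, A)
  pc <- pr$control_p; pp <- pr$patient_p
  if (noise) {
    obs <- withr::with_seed(seed, c(
      stats::rbinom(length(ages), n_items, pc) / n_items,
      stats::rbinom(length(ages), n_items, pp) / n_items))
    pc <- obs[seq_along(ages)]
    pp <- obs[-seq_along(ages)]
  }
  floor_p <- 1 / (2 * n_items)
  retention_dataset(rep(ages, 2), pmax(c(pc, pp), floor_p),
                    rep(c("control", "patient"), each = length(ages)),
                    n_items = n_items)
}

#' Fit the spine-drift model to a retention dataset
#'
#' Least-squares fit of model-predicted retention to observed data. Free
#' parameters are a declared subset of `mu` (learning rate), `q_base` and
#' `gamma` (lesion severity and strength-protection exponent), and `beta0`,
#' `beta1` (link coefficients); the rest are held at `fixed` values. The
#' objective is the sum of squared errors on the relative retrograde
#' gradient (default, the quantity retrograde-amnesia studies plot) or on
#' the raw retention proportions of both groups. Minimisation uses the
#' derivative-free Nelder-Mead simplex on logit-rescaled coordinates
#' (respecting `bounds`) with seeded multi-starts.
#'
#' @param dataset A [retention_dataset()].
#' @param spec A [chain_spec()] (held fixed during the fit).
#' @param free Character vector of free parameter names.
#' @param fixed Named list of values for the non-free parameters; defaults
#'   `mu = 1`, `q_base = 0.8`, `gamma = 1`, `beta0 = -3`, `beta1 = 0.8`.
#' @param bounds Named list of `c(lo, hi)` per free parameter; defaults
#'   `mu`, `q_base` in `[0, 1]`, `gamma` in `[0, 4]`, `beta0` in
#'   `[-10, 2]`, `beta1` in `[0.01, 5]`.
#' @param objective `"relative_gradient"` or `"retention"`.
#' @param A Input-neuron count the strengths are scaled by.
#' @param n_starts Number of seeded multi-starts.
#' @param seed Integer seed (start points only; the objective is
#'   deterministic).
#' @param eps Probability floor for log transforms.
#' @return Object of class `fit_result`: `par` (named fitted values),
#'   `sse`, `n_evals`, `converged`, `objective`, plus the per-start
#'   results in `starts`.
#' @export
fit_model <- function(dataset, spec, free = c("mu", "q_base"),
                      fixed = list(), bounds = list(),
                      objective = c("relative_gradient", "retention"),
                      A = 1000, n_starts = 10, seed = 1L, eps = 1e-6) {
  objective <- match.arg(objective)
  defaults <- list(mu = 1, q_base = 0.8, gamma = 1, beta0 = -3, beta1 = 0.8)
  default_bounds <- list(mu = c(0, 1), q_base = c(0, 1), gamma = c(0, 4),
                         beta0 = c(-10, 2), beta1 = c(0.01, 5))
  if (!all(free %in% names(defaults)))
    stop("free parameters must be among: ", paste(names(defaults), collapse = ", "))
  fixed <- utils::modifyList(defaults, fixed)
  bounds <- utils::modifyList(default_bounds, bounds)

  ctrl <- dataset[dataset$group == "control", ]
  pat <- dataset[dataset$group == "patient", ]
  ages <- sort(intersect(ctrl$age, pat$age))
  profile <- retention_profile(spec, ages)
  obs_rg <- if (objective == "relative_gradient") {
    suppressWarnings(relative_gradient(dataset, eps))
  } else NULL
  obs_pc <- pmax(ctrl$p_recall[match(ages, ctrl$age)], eps)
  obs_pp <- pmax(pat$p_recall[match(ages, pat$age)], eps)

  n_evals <- 0L
  sse_fn <- function(theta) {
    n_evals <<- n_evals + 1L
    p <- fixed
    p[free] <- from_unit(stats::plogis(theta), bounds[free])
    lesion <- lesion_model_power(spec$S, p$q_base, p$gamma)
    link <- retrieval_link(p$beta0, p$beta1)
    pr <- predict_retention(profile, spec, p$mu, lesion, link, A)
    if (objective == "relative_gradient") {
      pc <- pmax(pmin(pr$control_p, 1 - eps), eps)
      pp <- pmax(pr$patient_p, eps)
      pred <- log(pp) / log(pc)
      idx <- match(obs_rg$age, ages)
      sum((pred[idx] - obs_rg$rg)^2)
    } else {
      sum((pr$control_p - obs_pc)^2) + sum((pr$patient_p - obs_pp)^2)
    }
  }

  starts <- withr::with_seed(seed, lapply(seq_len(n_starts), function(k) {
    if (k == 1) rep(0, length(free))   # centre of the bounds
    else stats::qlogis(stats::runif(length(free), 0.05, 0.95))
  }))
  runs <- lapply(starts, function(th0) {
    if (length(free) == 1) {
      # Nelder-Mead is unreliable in 1-D; Brent on the rescaled coordinate
      stats::optim(th0, sse_fn, method = "Brent", lower = -15, upper = 15,
                   control = list(maxit = 2000))
    } else {
      stats::optim(th0, sse_fn, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
    }
  })
  sses <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(sses)]]
  par <- from_unit(stats::plogis(best$par), bounds[free])
  names(par) <- free
  structure(list(par = par, sse = best$value, n_evals = n_evals,
                 converged = best$convergence == 0, objective = objective,
                 fixed = fixed[setdiff(names(fixed), free)],
                 starts = data.frame(start = seq_len(n_starts), sse = sses)),
            class = "fit_result")
}

from_unit <- function(u, bounds)
  mapply(function(ui, b) b[1] + ui * (b[2] - b[1]), u, bounds)

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit (%s objective): SSE = %.6g after %d evaluations%s\n",
              x$objective, x$sse, x$n_evals,
              if (x$converged) "" else " [NOT converged]"))
  cat("  fitted:", paste(sprintf("%s = %.6g", names(x$par), x$par),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write a fit result as JSON
#'
#' @param fit A [fit_model()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(par = as.list(fit$par), sse = fit$sse, n_evals = fit$n_evals,
         converged = fit$converged, objective = fit$objective),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
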