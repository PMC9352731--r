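#' Recipe for a biologically-motivated chain specification
#'
#' Empirical spine-volume distributions are strongly skewed toward small
#' spines, resembling (stretched) exponential, gamma or lognormal shapes;
#' a recipe discretises one of these families over the `S` strength states
#' and pairs it with a plasticity profile (constant or geometrically
#' decreasing in state index, matching the observation that large spines
#' fluctuate less).
#'
#' @param S Number of states.
#' @param equilibrium_family `"exponential"`, `"gamma"`, `"lognormal"` or
#'   `"custom"`.
#' @param family_params Named list: `rate` (exponential), `shape`/`scale`
#'   (gamma), `meanlog`/`sdlog` (lognormal), `x` (custom).
#' @param y_profile `"constant"`, `"geometric"` or `"custom"`.
#' @param y_params Named list: `y0` (level), `ratio` (geometric decay per
#'   state, in `(0, 1)`), `y` (custom).
#' @param pin_x,pin_y Optional named numeric vectors pinning individual
#'   entries, e.g. `pin_x = c("4" = 0.02)` forces `x[4] = 0.02` (the rest
#'   of `x` is renormalised to the remaining mass).
#' @return Object of class `fixture_recipe`.
#' @export
fixture_recipe <- function(S = 5,
                           equilibrium_family = c("exponential", "gamma",
                                                  "lognormal", "custom"),
                           family_params = list(),
                           y_profile = c("geometric", "constant", "custom"),
                           y_params = list(),
                           pin_x = NULL, pin_y = NULL) {
  structure(list(S = S, equilibrium_family = match.arg(equilibrium_family),
                 family_params = family_params,
                 y_profile = match.arg(y_profile), y_params = y_params,
                 pin_x = pin_x, pin_y = pin_y),
            class = "fixture_recipe")
}

#' Build a validated chain spec from a recipe
#'
#' Normalises the family's mass over `S` bins into `x`, builds `y` from the
#' profile, applies any pinned entries, and enforces validity: if any
#' induced diagonal would go negative, all unpinned `y` are rescaled down
#' and a message reports the factor.
#'
#' @param recipe A [fixture_recipe()].
#' @return A valid [chain_spec()].
#' @export
make_spec <- function(recipe) {
  S <- recipe$S
  fp <- recipe$family_params
  x <- switch(recipe$equilibrium_family,
    exponential = {
      rate <- if (is.null(fp$rate)) 1 else fp$rate
      exp(-rate * (seq_len(S) - 1))
    },
    gamma = {
      shape <- if (is.null(fp$shape)) 0.7 else fp$shape
      scale <- if (is.null(fp$scale)) 1 else fp$scale
      edges <- seq(0, stats::qgamma(0.995, shape, scale = scale),
                   length.out = S + 1)
      diff(stats::pgamma(edges, shape, scale = scale))
    },
    lognormal = {
      meanlog <- if (is.null(fp$meanlog)) -1 else fp$meanlog
      sdlog <- if (is.null(fp$sdlog)) 1 else fp$sdlog
      edges <- seq(0, stats::qlnorm(0.995, meanlog, sdlog), length.out = S + 1)
      diff(stats::plnorm(edges, meanlog, sdlog))
    },
    custom = {
      if (is.null(fp$x)) stop("custom family requires family_params$x")
      fp$x
    })
  if (any(x <= 0)) x <- pmax(x, 1e-6)
  x <- x / sum(x)
  if (!is.null(recipe$pin_x)) {
    idx <- as.integer(names(recipe$pin_x))
    if (sum(recipe$pin_x) >= 1) stop("pinned x entries must sum below 1")
    free <- setdiff(seq_len(S), idx)
    x[free] <- x[free] / sum(x[free]) * (1 - sum(recipe$pin_x))
    x[idx] <- recipe$pin_x
  }

  yp <- recipe$y_params
  y0 <- if (is.null(yp$y0)) 0.2 else yp$y0
  y <- switch(recipe$y_profile,
    constant = rep(y0, S - 1),
    geometric = {
      ratio <- if (is.null(yp$ratio)) 0.4 else yp$ratio
      if (ratio <= 0 || ratio >= 1) stop("geometric ratio must lie in (0, 1)")
      y0 * ratio^(seq_len(S - 1) - 1)
    },
    custom = {
      if (is.null(yp$y)) stop("custom y profile requires y_params$y")
      yp$y
    })
  pinned_y <- integer(0)
  if (!is.null(recipe$pin_y)) {
    pinned_y <- as.integer(names(recipe$pin_y))
    y[pinned_y] <- recipe$pin_y
  }

  # enforce nonnegative diagonals by rescaling unpinned y
  spec_try <- structure(list(S = S, x = x, y = y, time_unit = "day"),
                        class = "chain_spec")
  load <- max(diagonal_load(spec_try))
  if (load > 0.99) {
    free_y <- setdiff(seq_len(S - 1), pinned_y)
    if (!length(free_y))
      stop("infeasible recipe: diagonal negative and all y entries pinned")
    fac <- 0.99 / load
    y[free_y] <- y[free_y] * fac
    spec_try$y <- y
    if (max(diagonal_load(spec_try)) > 1)
      stop("infeasible recipe: cannot rescale to validity with pinned y")
    message(sprintf("rescaled unpinned y by %.4g to keep diagonals nonnegative", fac))
  }
  chain_spec(x, y)
}

#' Canonical five-state chain specification
#'
#' The documented default used throughout examples and tests: five states,
#' most equilibrium mass in the absent/weak states (`x[1] = 0.60`), 6% of
#' connections in the large, low-plasticity top state, and
#' `x[4] = 0.02`, `y[4] = 0.005` so the top state's only exit probability
#' is 1/10,000 per day — an expected lifetime of 10,000 days, comfortably
#' over 25 years.
#'
#' @return A [chain_spec()] with `S = 5`,
#'   `x = (0.60, 0.22, 0.10, 0.02, 0.06)`,
#'   `y = (0.2, 0.05, 0.02, 0.005)`.
#' @export
default_spec <- function() {
  chain_spec(x = c(0.60, 0.22, 0.10, 0.02, 0.06),
             y = c(0.2, 0.05, 0.02, 0.005))
}

#' Deterministic grid of diverse valid chain specs
#'
#' Generates `n` seeded specs cycling over state counts
#' `S in {4, 5, 7}` and the three equilibrium families, with geometrically
#' decreasing plasticity profiles of varying level and decay (plasticity
#' decreasing with strength is a core model assumption and the regime in
#' which the memory laws are claimed). Used as the property-test corpus.
#'
#' @param n Number of specs (>= 1).
#' @param seed Integer seed.
#' @return List of `n` valid [chain_spec()] objects; attribute `"recipes"`
#'   carries the generating recipes.
#' @export
fixture_grid <- function(n = 10, seed = 1L) {
  stopifnot(n >= 1)
  S_cycle <- c(4, 5, 7)
  fam_cycle <- c("exponential", "gamma", "lognormal")
  draws <- withr::with_seed(seed,
    data.frame(y0 = stats::runif(n, 0.05, 0.3),
               ratio = stats::runif(n, 0.2, 0.6),
               rate = stats::runif(n, 0.6, 1.4),
               shape = stats::runif(n, 0.5, 1.2),
               meanlog = stats::runif(n, -1.5, -0.5)))
  recipes <- lapply(seq_len(n), function(k) {
    fam <- fam_cycle[((k - 1) %/% 3) %% 3 + 1]
    fixture_recipe(
      S = S_cycle[(k - 1) %% 3 + 1],
      equilibrium_family = fam,
      family_params = switch(fam,
        exponential = list(rate = draws$rate[k]),
        gamma = list(shape = draws$shape[k]),
        lognormal = list(meanlog = draws$meanlog[k])),
      y_profile = "geometric",
      y_params = list(y0 = draws$y0[k], ratio = draws$ratio[k]))
  })
  specs <- lapply(recipes, function(r) suppressMessages(make_spec(r)))
  attr(specs, "recipes") <- recipes
  specs
}
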