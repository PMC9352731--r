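#' Chain specification for the connection-strength random walk
#'
#' A `chain_spec` bundles the three ingredients of the reflecting random-walk
#' model of neural connection strength: the number of discrete strength states
#' `S` (state 1 = absent/zero-strength connection, state `S` = strongest,
#' least plastic connection), the target equilibrium distribution `x` over
#' those states, and the `S - 1` plasticity scale factors `y` that set how
#' fast adjacent states exchange probability mass. The transition matrix
#' built from a spec (see [build_transition_matrix()]) satisfies detailed
#' balance with respect to `x` by construction, so the equilibrium shape and
#' the time course of the dynamics can be chosen independently.
#'
#' @param x Numeric vector of `S` equilibrium probabilities; all positive,
#'   summing to 1.
#' @param y Numeric vector of `S - 1` positive plasticity factors; `y[j]`
#'   scales the exchange rate between states `j` and `j + 1`. Small values at
#'   high indices make strong connections stable.
#' @param time_unit Label for one time step (default `"day"`).
#'
#' @return An object of class `chain_spec` with elements `S`, `x`, `y`,
#'   `time_unit`.
#'
#' @details The spec must be *valid*: every diagonal entry of the induced
#'   transition matrix must be nonnegative, i.e. for interior states
#'   `x[i-1]*y[i-1] + x[i+1]*y[i] <= 1` (boundary rows analogous).
#'   [validate_chain_spec()] enforces this and names the offending row.
#'
#' @seealso [build_transition_matrix()], [default_spec()], [make_spec()]
#' @export
#' @examples
#' spec <- chain_spec(x = c(0.5, 0.3, 0.2), y = c(0.2, 0.1))
#' spec$S
chain_spec <- function(x, y, time_unit = "day") {
  spec <- structure(
    list(S = length(x), x = as.numeric(x), y = as.numeric(y),
         time_unit = time_unit),
    class = "chain_spec"
  )
  validate_chain_spec(spec)
  spec
}

#' Validate a chain specification
#'
#' Checks the structural invariants of a [chain_spec()]: `S >= 2`, positive
#' `x` summing to 1, positive `y` of length `S - 1`, and nonnegative induced
#' diagonal for every row of the transition matrix.
#'
#' @param spec A `chain_spec`.
#' @param tol Tolerance on `sum(x) == 1`.
#' @return `spec`, invisibly; errors describe the first violated invariant,
#'   naming the offending row where relevant.
#' @export
validate_chain_spec <- function(spec, tol = 1e-10) {
  if (!inherits(spec, "chain_spec"))
    stop("not a chain_spec object")
  S <- spec$S; x <- spec$x; y <- spec$y
  if (S < 2) stop("chain must have at least 2 states")
  if (length(x) != S) stop("x must have length S")
  if (length(y) != S - 1) stop("y must have length S - 1")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all equilibrium probabilities x must be positive and finite")
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("x must sum to 1 (got %.15g)", sum(x)))
  if (any(!is.finite(y)) || any(y <= 0))
    stop("all plasticity factors y must be positive and finite")
  d <- diagonal_load(spec)
  bad <- which(d > 1 + 1e-12)
  if (length(bad))
    stop(sprintf(paste0(
      "invalid spec: diagonal of transition matrix would be negative in row %d ",
      "(off-diagonal mass %.6g > 1); reduce y"), bad[1], d[bad[1]]))
  invisible(spec)
}

# Total off-diagonal probability mass per row of the induced matrix.
diagonal_load <- function(spec) {
  S <- spec$S; x <- spec$x; y <- spec$y
  up <- c(x[-1] * y, 0)          # P[i, i+1] = x[i+1] * y[i]
  down <- c(0, x[-S] * y)        # P[i+1, i] = x[i] * y[i]
  up + down
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("Connection-state random walk: S = %d states (time unit: %s)\n",
              x$S, x$time_unit))
  cat("  equilibrium x:", format(x$x, digits = 4), "\n")
  cat("  plasticity  y:", format(x$y, digits = 4), "\n")
  invisible(x)
}

#' Read and write chain specifications
#'
#' Specs round-trip through a plain JSON/YAML schema
#' `{"S": int, "x": [...], "y": [...], "time_unit": "day"}`. The format is
#' inferred from the file extension (`.json`, `.yaml`/`.yml`) or forced with
#' `format`.
#'
#' @param spec A `chain_spec`.
#' @param path File path.
#' @param format `"json"`, `"yaml"` or `"auto"` (by extension).
#' @return `read_chain_spec()` returns a validated `chain_spec`;
#'   `write_chain_spec()` returns `path` invisibly.
#' @export
write_chain_spec <- function(spec, path, format = c("auto", "json", "yaml")) {
  format <- resolve_format(match.arg(format), path)
  obj <- list(S = spec$S, x = spec$x, y = spec$y, time_unit = spec$time_unit)
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_chain_spec
#' @export
read_chain_spec <- function(path, format = c("auto", "json", "yaml")) {
  format <- resolve_format(match.arg(format), path)
  obj <- if (format == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  spec <- chain_spec(x = unlist(obj$x), y = unlist(obj$y),
                     time_unit = if (is.null(obj$time_unit)) "day" else obj$time_unit)
  if (!is.null(obj$S) && obj$S != spec$S)
    stop("declared S does not match length(x)")
  spec
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml" else "json"
}
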