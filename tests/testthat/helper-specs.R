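# Shared fixture chains, built in code.

# two-state symmetric chain: P = [[0.9, 0.1], [0.1, 0.9]]
spec2 <- function() chain_spec(x = c(0.5, 0.5), y = 0.2)

# three-state reference chain used for most hand-computed values
spec3 <- function() chain_spec(x = c(0.5, 0.3, 0.2), y = c(0.2, 0.1))

# moderately plastic four-state chain: hitting times reachable by simulation
spec4 <- function() chain_spec(x = c(0.4, 0.3, 0.2, 0.1), y = c(0.5, 0.4, 0.3))

# detailed-balance residual of a constructed matrix
db_residual <- function(spec, P) {
  S <- spec$S
  i <- seq_len(S - 1)
  max(abs(spec$x[i] * P[cbind(i, i + 1)] - spec$x[i + 1] * P[cbind(i + 1, i)]))
}
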