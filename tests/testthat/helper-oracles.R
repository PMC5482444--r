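# Brute-force quadrature oracle for the exponential-memory integrals.
# Independent of the recursive implementation: composite Simpson integration
# of the defining integrals M1 = int e^(-s/tau) c(t-s) ds and
# M2 = int s e^(-s/tau) c(t-s) ds over a piecewise-constant history
# (concentration zero before the history starts).

quad_memory <- function(cs, dts, tau, n_sub = 2000) {
  stopifnot(length(cs) == length(dts))
  t_end <- sum(dts)
  bounds <- cumsum(c(0, dts))
  M1 <- 0
  M2 <- 0
  for (i in seq_along(cs)) {
    a <- t_end - bounds[i + 1] # youngest age of segment i
    b <- t_end - bounds[i]
    h <- (b - a) / n_sub
    s <- seq(a, b, length.out = n_sub + 1)
    w <- c(1, rep(c(4, 2), length.out = n_sub - 1), 1) * h / 3
    M1 <- M1 + cs[i] * sum(w * exp(-s / tau))
    M2 <- M2 + cs[i] * sum(w * s * exp(-s / tau))
  }
  list(M1 = M1, M2 = M2)
}

# recursive counterpart over the same history, starting from empty memory
recursive_memory <- function(cs, dts, tau) {
  st <- structure(list(M1 = 0, M2 = 0), class = "kernel_state")
  for (i in seq_along(cs)) st <- update_memory(st, cs[i], dts[i], tau)
  st
}
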