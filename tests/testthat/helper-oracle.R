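# Independent oracle: plain long-horizon integration of micrm_dynamics with
# deSolve, no pruning and no Newton refinement.
integrate_oracle <- function(system, R0, t_end = 5000) {
  n <- nrow(system$c)
  rhs <- function(t, x, parms) {
    d <- micrm_dynamics(pmax(x[seq_len(n)], 0),
                        pmax(x[n + seq_len(system$params$M)], 0),
                        system, R0)
    list(c(d$dN, d$dR))
  }
  x0 <- c(rep(system$params$initial_abundance, n), R0)
  out <- deSolve::lsoda(x0, c(0, t_end), rhs, rtol = 1e-10, atol = 1e-12)
  x <- out[nrow(out), -1]
  list(N = pmax(x[seq_len(n)], 0),
       R = pmax(x[n + seq_len(system$params$M)], 0))
}
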