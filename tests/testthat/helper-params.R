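# Shared fixtures: the simulation parameter set and quantities derived from
# it that several test files reuse. Everything is computed, never loaded.

sim_params <- kw_params()                       # P = 16.9867 set
hc_ref <- critical_handling_time(sim_params)    # ~ 17.4172

# short full-model run used by several checks (h below threshold)
run_short <- function(h = hc_ref - 1, t_end = 300, A0 = 50, R0 = 500, ...) {
  p <- set_handling_time(sim_params, h)
  simulate_stand(p, make_history(p, A0 = A0, R0 = R0), t_end = t_end, ...)
}

# random strictly positive parameter draws around the defaults (log-normal
# jitter), used by property tests
random_params <- function(n, sd = 0.5) {
  lapply(seq_len(n), function(i) {
    j <- function(x) x * exp(stats::rnorm(1, 0, sd))
    kw_params(
      h = 1, tau_s = j(150), mu_s = j(0.01), mu_r = j(0.01),
      k_s = j(0.1), k_r = j(0.1), tau_p = j(32.2), mu_a = j(0.0806)
    )
  })
}
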