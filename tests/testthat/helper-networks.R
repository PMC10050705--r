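# Shared fixtures and a cache for expensive converged runs (several test
# files interrogate the same converged synthetic cerebral network; run each
# configuration once per session).
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .sim_cache)) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

fast_settings <- function() solver_settings(init_pc = mmhg_to_pa(75))

# converged baseline synthetic cerebral network (tight threshold: periodic
# state for mass-balance checks)
cow_baseline_sim <- function() cached("cow_base", {
  run_to_convergence(toy_cow_network(), threshold = 0.3, max_cycles = 50,
                     settings = fast_settings())
})

# BGC + aspiration scenario runs, keyed by configuration and rate
cow_scenario_sim <- function(config_id, rate, threshold = 1) {
  key <- paste0("cow_", config_id, "_", rate, "_", threshold)
  cached(key, {
    cfg <- enumerate_configurations()
    cfg <- cfg[cfg$config == config_id, ]
    net <- scenario_network(toy_cow_network(), cfg, rate)
    suppressWarnings(run_to_convergence(net, threshold = threshold,
                                        max_cycles = 50,
                                        settings = fast_settings()))
  })
}

# a right-moving simple-wave pulse state on a vessel: area bump of relative
# amplitude `amp` centred at `x0`, with the flow of a forward characteristic
pulse_state <- function(vessel, fluid, amp = 0.01, x0 = NULL, sigma = 0.05) {
  x <- (seq_len(vessel$M) - 0.5) * vessel$dx
  if (is.null(x0)) x0 <- vessel$L / 4
  A <- vessel$A0 * (1 + amp * exp(-((x - x0) / sigma)^2))
  c0 <- wave_speed(vessel$A0, vessel, fluid)
  u <- 4 * (wave_speed(A, vessel, fluid) - c0)
  list(A = A, Q = A * u, x = x)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
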