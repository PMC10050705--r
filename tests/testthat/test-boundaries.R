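test_that("windkessel outlet reaches the closed-form steady pressure", {
  net <- single_vessel_network(inlet = "flow", q = 1e-5,
                               outlet = "windkessel", Pout = 400)
  sim <- run_to_convergence(net, threshold = 0.01, max_cycles = 60)
  wk <- net$boundaries[[2]]$params
  tr <- vessel_trace(sim, "tube", units = "SI")
  pred <- wk$Pout + 1e-5 * (wk$R1 + wk$R2)
  expect_rel_error(mean(tr$P_dist), pred, 0.005)
})

test_that("windkessel with zero inflow settles at the outflow pressure", {
  net <- single_vessel_network(inlet = "flow", q = 0, outlet = "windkessel",
                               Pout = mmhg_to_pa(10))
  # start the capacitor away from Pout so the relaxation is real
  net$boundaries[[2]]$params$Pc <- mmhg_to_pa(40)
  sim <- run_to_convergence(net, threshold = 0.005, max_cycles = 60,
                            settings = solver_settings())
  tr <- vessel_trace(sim, "tube", units = "SI")
  expect_rel_error(mean(tr$P_dist), mmhg_to_pa(10), 0.01)
  expect_lt(max(abs(tr$Q_dist)), 1e-9)
})

test_that("capacitor relaxes with time constant R2*C after a flow step", {
  fl <- fluid_properties()
  v <- vessel_segment("v", L = 0.2, radius = 5e-3, h0 = 1e-3, E = 4e5)
  # R2 far below the vessel's characteristic impedance so the boundary
  # behaves as an imposed flow step and the lumped ODE dominates
  wk <- windkessel3(R1 = 0, R2 = 1e6, C = 1e-6, Pout = 0, Pc = 0)
  q <- 1e-5
  A_int <- v$A0; Q_int <- q
  dt <- 1e-3
  n <- 5000
  pc <- numeric(n)
  for (i in seq_len(n)) {
    up <- windkessel_update(wk, A_int, Q_int, v, fl, dt)
    wk <- up$outlet
    pc[i] <- wk$Pc
  }
  pc_inf <- pc[n]
  t <- dt * seq_len(n)
  sel <- which(pc_inf - pc > 0.02 * pc_inf & t < 2.5)
  fit <- stats::lm(log(pc_inf - pc[sel]) ~ t[sel])
  tau <- -1 / stats::coef(fit)[[2]]
  expect_rel_error(tau, wk$R2 * wk$C, 0.05)
})

test_that("an impedance-matched outlet barely reflects an incident pulse", {
  fl <- fluid_properties()
  net <- single_vessel_network(L = 1.5, M = 300, inlet = "reflect",
                               outlet = "windkessel", R_total = 1e10,
                               C_wk = 3e-8)
  v <- net$vessels$tube
  ps <- pulse_state(v, fl, amp = 0.01, x0 = 0.5)
  cppnet <- mtflow:::build_solver_net(net)
  state <- mtflow:::initial_state(cppnet)
  state$A[[1]] <- ps$A; state$Q[[1]] <- ps$Q
  a_inc <- max(ps$A - v$A0)
  # run long enough for the pulse to hit the outlet and any reflection to
  # travel back into the vessel interior
  res <- mtflow:::cpp_run_cycle(cppnet, state, 0, 0.28, 0.9, 1e-3)
  a_res <- max(abs(unlist(res$state$A[[1]]) - v$A0))
  expect_lt(a_res / a_inc, 0.02)
})

test_that("junction solves conserve flow to near machine precision", {
  fl <- fluid_properties()
  p <- vessel_segment("p", L = 0.1, radius = 5e-3, h0 = 1e-3, E = 4e5)
  d1 <- vessel_segment("d1", L = 0.1, radius = 3.5e-3, h0 = 7e-4, E = 4e5)
  d2 <- vessel_segment("d2", L = 0.1, radius = 3e-3, h0 = 6e-4, E = 5e5)
  out <- junction_solve("bifurcation", c("distal", "proximal", "proximal"),
                        A = c(p$A0 * 1.05, d1$A0, d2$A0),
                        Q = c(2e-5, 0, 0), vessels = list(p, d1, d2),
                        fluid = fl)
  imbalance <- abs(out$Q[1] - out$Q[2] - out$Q[3])
  expect_lt(imbalance, 1e-10 * abs(out$Q[1]) + 1e-18)
  # static pressure continuity at a bifurcation
  P <- mapply(pressure_from_area, out$A, list(p, d1, d2))
  expect_lt(max(abs(P - P[1])), 1e-6 * max(1, abs(P[1])))
})

test_that("junction solve honours total-pressure coupling at conjunctions", {
  fl <- fluid_properties()
  a <- vessel_segment("a", L = 0.1, radius = 5e-3, h0 = 1e-3, E = 4e5)
  b <- vessel_segment("b", L = 0.1, radius = 4e-3, h0 = 8e-4, E = 4e5)
  out <- junction_solve("conjunction", c("distal", "proximal"),
                        A = c(a$A0 * 1.03, b$A0), Q = c(3e-5, 1e-5),
                        vessels = list(a, b), fluid = fl)
  u <- out$Q / out$A
  Ptot <- mapply(pressure_from_area, out$A, list(a, b)) +
    0.5 * fl$density * u^2
  expect_lt(abs(Ptot[1] - Ptot[2]), 1e-6 * max(1, abs(Ptot[1])))
  expect_lt(abs(out$Q[1] - out$Q[2]), 1e-10 * abs(out$Q[1]) + 1e-18)
})

test_that("matched conjunction transmits; rigid continuation reflects", {
  fl <- fluid_properties()
  # amplitude of the same pulse after the same travel time in a uniform
  # junction-free tube: the diffusion reference for the reflected pulse
  reference_amplitude <- function() {
    v <- vessel_segment("v", L = 2.0, radius = 5e-3, h0 = 1e-3, E = 4e5,
                        M = 400)
    net <- arterial_network(list(v), boundaries = list(
      list(vessel = "v", end = "proximal", type = "reflect", params = NULL),
      list(vessel = "v", end = "distal", type = "reflect", params = NULL)),
      fluid = fl)
    ps <- pulse_state(v, fl, amp = 0.01, x0 = 0.6)
    cn <- mtflow:::build_solver_net(net)
    st <- mtflow:::initial_state(cn)
    st$A[[1]] <- ps$A; st$Q[[1]] <- ps$Q
    res <- mtflow:::cpp_run_cycle(cn, st, 0, 0.1, 0.9, 1e-3)
    max(abs(unlist(res$state$A[[1]]) - v$A0))
  }
  reflection_ratio <- function(stiffen) {
    v1 <- vessel_segment("v1", L = 1.0, radius = 5e-3, h0 = 1e-3, E = 4e5,
                         M = 200)
    v2 <- vessel_segment("v2", L = 1.0, radius = 5e-3, h0 = 1e-3,
                         E = 4e5 * stiffen, M = 200)
    net <- arterial_network(
      list(v1, v2),
      junctions = list(list(kind = "conjunction", ends = list(
        list(vessel = "v1", end = "distal"),
        list(vessel = "v2", end = "proximal")))),
      boundaries = list(
        list(vessel = "v1", end = "proximal", type = "reflect",
             params = NULL),
        list(vessel = "v2", end = "distal", type = "reflect",
             params = NULL)),
      fluid = fl)
    ps <- pulse_state(v1, fl, amp = 0.01, x0 = 0.6)
    cppnet <- mtflow:::build_solver_net(net)
    state <- mtflow:::initial_state(cppnet)
    state$A[[1]] <- ps$A; state$Q[[1]] <- ps$Q
    a_inc <- max(ps$A - v1$A0)
    # after ~0.1 s the pulse (c0 ~ 7 m/s) has crossed the junction; any
    # reflection is back inside v1
    res <- mtflow:::cpp_run_cycle(cppnet, state, 0, 0.1, 0.9, 1e-3)
    max(abs(unlist(res$state$A[[1]]) - v1$A0)) / a_inc
  }
  a_inc <- 1  # ratios below are relative to the initial amplitude
  expect_lt(reflection_ratio(1), 0.01)   # impedance matched
  # 1000x stiffer continuation: linear reflection coefficient
  # (Z2 - Z1)/(Z2 + Z1) with Z ~ sqrt(beta) gives ~0.94 of the incident
  # pulse; compare against the diffusion reference at equal travel time
  v_ref <- vessel_segment("v", L = 2, radius = 5e-3, h0 = 1e-3, E = 4e5,
                          M = 400)
  ps_ref <- pulse_state(v_ref, fl, amp = 0.01, x0 = 0.6)
  a0_inc <- max(ps_ref$A - v_ref$A0)
  a_ref <- reference_amplitude() / a0_inc
  expect_gt(reflection_ratio(1e3) / a_ref, 0.85)
})
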