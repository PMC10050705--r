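test_that("packaged scaling and reference tables carry the printed values", {
  tab <- ageing_scaling_table()
  expect_equal(dim(tab), c(36L, 4L))
  g <- function(a, f) tab[tab$age == a & tab$factor == f, c("mean", "sd")]
  expect_equal(unlist(g(65, "radius"), use.names = FALSE), c(1.13, 0.07))
  expect_equal(unlist(g(65, "cardiac_output"), use.names = FALSE),
               c(0.80, 0.20))
  expect_equal(unlist(g(25, "compliance"), use.names = FALSE), c(1.00, 0.27))
  expect_equal(unlist(g(75, "stiffness"), use.names = FALSE), c(2.00, 0.45))
  ref <- brachial_pressure_reference()
  r65 <- ref[ref$age == 65, ]
  expect_equal(c(r65$sbp_mean, r65$sbp_sd, r65$dbp_mean, r65$dbp_sd),
               c(126, 9, 78, 6))
  expect_equal(ref$sbp_mean[ref$age == 25], 124)
  expect_equal(ref$dbp_mean[ref$age == 25], 75)
})

test_that("scaling samples recover the table moments", {
  n <- 1e5
  s <- sample_scalings(65, n, seed = 42)
  tab <- ageing_scaling_table()
  for (f in c("radius", "compliance", "cardiac_output")) {
    row <- tab[tab$age == 65 & tab$factor == f, ]
    se <- row$sd / sqrt(n)
    expect_lt(abs(mean(s[[f]]) - row$mean), 3 * se)
    expect_lt(abs(sd(s[[f]]) - row$sd), 3 * row$sd / sqrt(2 * n))
  }
  expect_true(all(as.matrix(s) > 0))
  expect_error(sample_scalings(30, 10), "not in the scaling table")
})

test_that("sampling is deterministic under a seed and degenerate at sd 0", {
  s1 <- sample_scalings(65, 50, seed = 7)
  s2 <- sample_scalings(65, 50, seed = 7)
  expect_identical(s1, s2)
  tab <- ageing_scaling_table()
  tab$sd <- 0
  s0 <- sample_scalings(45, 20, table = tab, seed = 1)
  for (f in names(s0))
    expect_true(all(s0[[f]] == tab$mean[tab$age == 45 & tab$factor == f]))
})

test_that("scalings act on area, wall, outlets and inlet as specified", {
  net <- bifurcation_network()
  id <- list(radius = 1, thickness = 1, stiffness = 1, resistance = 1,
             compliance = 1, cardiac_output = 1)
  expect_equal(apply_scalings(net, id), net)
  s <- list(radius = 1.13, thickness = 1.2, stiffness = 1.5,
            resistance = 1.23, compliance = 0.54, cardiac_output = 0.8)
  net2 <- apply_scalings(net, s)
  v0 <- net$vessels$parent; v2 <- net2$vessels$parent
  expect_equal(v2$A0 / v0$A0, 1.13^2)  # radius scaling squares into area
  expect_equal(v2$A0 / v0$A0, 1.2769)
  expect_equal(v2$h0 / v0$h0, 1.2)
  expect_equal(v2$E / v0$E, 1.5)
  expect_equal(v2$beta, compute_beta(v2$E, v2$h0, v2$nu, v2$A0))
  wk0 <- net$boundaries[[2]]$params; wk2 <- net2$boundaries[[2]]$params
  expect_equal(wk2$R1 / wk0$R1, 1.23)
  expect_equal(wk2$R2 / wk0$R2, 1.23)
  expect_equal(wk2$C / wk0$C, 0.54)
  expect_equal(net2$boundaries[[1]]$params$scale, 0.8)
  # an 0.80 cardiac-output factor turns a 350 ml/s peak into 280 ml/s
  w <- net2$boundaries[[1]]$params
  w$peak_flow <- 3.5e-4
  expect_equal(inlet_flow(w, w$systole / 2) * 1e6, 280)
  # left/right homologues stay identical
  expect_equal(net2$vessels$left$A0, net2$vessels$right$A0)
  expect_error(apply_scalings(net, list(radius = 1)), "lacks")
})

test_that("scaling application is homogeneous (componentwise product)", {
  net <- bifurcation_network()
  s1 <- list(radius = 1.1, thickness = 1.2, stiffness = 1.3,
             resistance = 1.4, compliance = 0.8, cardiac_output = 0.9)
  s2 <- list(radius = 0.95, thickness = 1.05, stiffness = 1.1,
             resistance = 0.9, compliance = 1.2, cardiac_output = 1.05)
  s12 <- Map(`*`, s1, s2)
  a <- apply_scalings(apply_scalings(net, s1), s2)
  b <- apply_scalings(net, s12)
  expect_equal(a, b)
})

test_that("the plausibility filter is a closed rectangle at 2.575 sd", {
  # age 65: 126 +/- 9 and 78 +/- 6 -> bounds 149.175 / 102.825, 93.45 / 62.55
  expect_true(physiological_filter(126, 78, 65))
  expect_false(physiological_filter(150, 78, 65))   # 150 > 149.175
  expect_true(physiological_filter(149.175, 78, 65))  # boundary accepts
  expect_false(physiological_filter(126, 62, 65))   # 62 < 62.55
  expect_true(physiological_filter(126, 62.55, 65))
  expect_false(physiological_filter(102.8, 78, 65))
  expect_error(physiological_filter(120, 80, 30), "not in the pressure")
})

test_that("baseline calibration picks the best match deterministically", {
  subj <- data.frame(sbp = c(130, 124, 118), dbp = c(80, 75, 72))
  sel <- calibrate_baseline(subj, target = c(124, 75))
  expect_equal(sel$index, 2L)
  expect_equal(sel$distance, 0)
  # ties break to the lowest index
  subj2 <- data.frame(sbp = c(123, 125), dbp = c(75, 75))
  expect_equal(calibrate_baseline(subj2, target = c(124, 75))$index, 1L)
  # a population of one returns that subject
  expect_equal(calibrate_baseline(data.frame(sbp = 140, dbp = 90),
                                  target = c(124, 75))$index, 1L)
  expect_error(calibrate_baseline(data.frame(sbp = numeric(),
                                             dbp = numeric())),
               "empty population")
})

test_that("identity scaling reproduces baseline haemodynamics bit-for-bit", {
  net <- bifurcation_network()
  id <- list(radius = 1, thickness = 1, stiffness = 1, resistance = 1,
             compliance = 1, cardiac_output = 1)
  sim1 <- run_to_convergence(net, threshold = 1, max_cycles = 20)
  sim2 <- run_to_convergence(apply_scalings(net, id), threshold = 1,
                             max_cycles = 20)
  expect_identical(sim1$vessels, sim2$vessels)
  expect_identical(sim1$errors, sim2$errors)
})

test_that("small populations build, filter and summarise", {
  net <- toy_cow_network()
  pop <- cached("pop65_n6",
                build_population(net, 65, 6, seed = 11, threshold = 3,
                                 max_cycles = 30))
  expect_s3_class(pop, "mt_population")
  expect_equal(nrow(pop$subjects), 6L)
  expect_true(all(c("sbp", "dbp", "accepted") %in% names(pop$subjects)))
  conv <- pop$subjects$converged
  expect_true(any(conv))
  # acceptance flag is consistent with the filter applied to the pressures
  expect_equal(pop$subjects$accepted[conv],
               physiological_filter(pop$subjects$sbp[conv],
                                    pop$subjects$dbp[conv], 65) %in% TRUE)
  expect_equal(pop$summary$n_total, 6)
  # empty population
  pop0 <- build_population(net, 65, 0)
  expect_equal(nrow(pop0$subjects), 0L)
  expect_equal(pop0$summary$n_accepted, 0)
  # subject networks are rebuilt deterministically from scalings
  nets <- subject_networks(pop)
  if (length(nets)) {
    i <- as.integer(names(nets)[1])
    expect_equal(nets[[1]],
                 apply_scalings(net,
                                pop$subjects[i, mtflow:::scaling_factor_names]))
  }
})
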