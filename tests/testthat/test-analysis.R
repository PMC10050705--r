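test_that("cycle-mean flow integrates traces to ml/min", {
  t <- seq(0, 1, by = 1e-3)
  expect_equal(mean_flow(rep(2e-6, length(t)), t), 120)
  expect_equal(mean_flow(1e-6 * sin(2 * pi * t), t), 0, tolerance = 1e-9)
  # the baseline cardiac inlet: half sine, 350 ml/s peak, 0.3 s systole,
  # 1 s period -> 350 * 2 * 0.3 / pi ml/s = 4010.7 ml/min
  w <- inlet_waveform()
  q <- inlet_flow(w, t)
  expect_equal(mean_flow(q, t), 3.5e-4 * 2 * 0.3 / pi * 6e7,
               tolerance = 1e-5)
  expect_error(mean_flow(1, 1), "shorter than a cycle")
  expect_error(mean_flow(t, t[-1]), "same length")
  # linearity in the trace
  q2 <- 1e-6 * (0.3 + 0.5 * sin(2 * pi * t))
  expect_equal(mean_flow(2 * q2 + q, t),
               2 * mean_flow(q2, t) + mean_flow(q, t))
})

test_that("pulsatility index follows its closed form", {
  t <- seq(0, 1, by = 1e-3)
  expect_equal(pulsatility_index(0.6 + 0.2 * sin(2 * pi * t)), 0.4 / 0.6,
               tolerance = 1e-3)
  expect_equal(pulsatility_index(rep(0.5, 100)), 0)
  v <- c(0, 1, 2, 1)
  expect_equal(pulsatility_index(v), 2)
  expect_error(pulsatility_index(sin(2 * pi * t[-length(t)])), "zero-mean")
  # invariant to positive scaling of velocity
  v2 <- 0.6 + 0.2 * sin(2 * pi * t)
  expect_equal(pulsatility_index(3 * v2), pulsatility_index(v2))
})

test_that("direction classification is a sign test with a zero flag", {
  expect_identical(as.character(classify_direction(10)), "antegrade")
  expect_identical(as.character(classify_direction(-130)), "retrograde")
  d0 <- classify_direction(0)
  expect_identical(as.character(d0), "antegrade")
  expect_true(attr(d0, "zero_flow"))
  expect_false(attr(classify_direction(5), "zero_flow"))
})

test_that("population summaries give median (min, max) per group", {
  d <- data.frame(v = c(1, 2, 3), g = "a")
  s <- population_summary(d, "v", by = "g")
  expect_equal(s[c("median", "min", "max")],
               data.frame(median = 2, min = 1, max = 3))
  s1 <- population_summary(data.frame(v = 5), "v")
  expect_equal(unlist(s1), c(n = 1, median = 5, min = 5, max = 5))
  # permutation invariance
  d2 <- data.frame(v = rnorm(50), g = rep(c("a", "b"), 25))
  p <- sample(nrow(d2))
  s_a <- population_summary(d2, "v", "g")
  s_b <- population_summary(d2[p, ], "v", "g")
  s_b <- s_b[match(s_a$g, s_b$g), ]  # group discovery order may differ
  rownames(s_a) <- rownames(s_b) <- NULL
  expect_equal(s_a, s_b)
  # order-statistics oracle: sample median near the distribution median
  set.seed(1)
  n <- 1e4
  x <- data.frame(v = runif(n))
  se <- 1 / (2 * sqrt(n))  # asymptotic se of the median of U(0,1)
  expect_lt(abs(population_summary(x, "v")$median - 0.5), 3 * se)
  # empty groups are omitted with a warning
  d3 <- data.frame(v = c(1, NA), g = c("a", "b"))
  expect_warning(s3 <- population_summary(d3, "v", "g"), "empty group")
  expect_equal(nrow(s3), 1L)
})

test_that("flow summaries and site metrics agree across trace locations", {
  sim <- cached("bif_tight",
                run_to_convergence(bifurcation_network(), threshold = 0.1,
                                   max_cycles = 40))
  fs <- flow_summary(sim)
  expect_setequal(fs$vessel, c("parent", "left", "right"))
  expect_true(all(fs$direction == "antegrade"))
  expect_true(all(fs$min_flow <= fs$mean_flow & fs$mean_flow <= fs$max_flow))
  # distal-face and mid-vessel means agree for a converged run
  for (v in fs$vessel) {
    qm <- vessel_mean_flow(sim, v, "mid")
    qd <- vessel_mean_flow(sim, v, "dist")
    expect_rel_error(qd, qm, 0.01)
  }
  p <- site_pressures(sim, "parent")
  expect_true(p[["SBP"]] > p[["DBP"]])
})
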