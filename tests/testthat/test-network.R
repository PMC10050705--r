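test_that("network files round-trip through write and load", {
  net <- bifurcation_network()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, f)
  net2 <- load_network(f)
  expect_identical(names(net2$vessels), names(net$vessels))
  expect_equal(network_volume(net2), network_volume(net))
  expect_equal(vapply(net2$vessels, `[[`, numeric(1), "beta"),
               vapply(net$vessels, `[[`, numeric(1), "beta"))
  expect_equal(length(net2$junctions), length(net$junctions))
  expect_equal(net2$boundaries[[2]]$params$R1, net$boundaries[[2]]$params$R1)
  expect_identical(net2$symmetry, net$symmetry)
})

test_that("the packaged cerebral topology has 13 windkessel outlets", {
  f <- system.file("extdata", "cow_network_synthetic.yaml",
                   package = "mtflow")
  net <- load_network(f)
  expect_equal(n_outlets(net), 13L)
  expect_equal(length(net$vessels), 34L)
  # ICApp and ICApd are separated by the Ophthalmic branch point
  oph <- net$sites$Ophthalmic$vessel
  jn <- net$junctions[[mtflow:::find_attachment(net, oph,
                                                "proximal")$index]]
  attached <- vapply(jn$ends, function(e) e$vessel, character(1))
  expect_true(all(c(net$sites$ICApp$vessel, net$sites$ICApd$vessel)
                  %in% attached))
  # one heart inlet
  expect_equal(sum(vapply(net$boundaries, function(b) b$type == "inlet",
                          logical(1))), 1L)
})

test_that("structural violations are rejected with named records", {
  v <- vessel_segment("a", L = 0.1, radius = 5e-3, h0 = 1e-3, E = 4e5)
  # dangling end
  expect_error(
    arterial_network(list(v), boundaries = list(
      list(vessel = "a", end = "proximal", type = "reflect",
           params = NULL))),
    "dangling.*a:distal")
  # an end attached twice
  expect_error(
    arterial_network(list(v), boundaries = list(
      list(vessel = "a", end = "proximal", type = "reflect", params = NULL),
      list(vessel = "a", end = "distal", type = "reflect", params = NULL),
      list(vessel = "a", end = "distal", type = "flow",
           params = list(q = 0)))),
    "attached 2 times")
  # duplicate names
  expect_error(
    arterial_network(list(v, v), boundaries = list()),
    "duplicate vessel names")
})

test_that("splitting a vessel preserves volume and haemodynamics", {
  net <- single_vessel_network(M = 20)
  net2 <- split_vessel_at(net, "tube", 0.5)
  expect_equal(length(net2$vessels), length(net$vessels) + 1L)
  expect_equal(network_volume(net2), network_volume(net))
  expect_equal(net2$vessels$tube_seg1$L + net2$vessels$tube_seg2$L,
               net$vessels$tube$L)
  sim1 <- run_to_convergence(net, threshold = 0.05, max_cycles = 40)
  sim2 <- run_to_convergence(net2, threshold = 0.05, max_cycles = 40)
  # distal pressures of the split network match the unsplit one within
  # solver tolerance
  d <- max(abs(vessel_trace(sim1, "tube")$P_dist -
                 vessel_trace(sim2, "tube_seg2")$P_dist))
  expect_lt(d, 0.5)  # well inside the 3 mmHg solver tolerance
  q1 <- vessel_mean_flow(sim1, "tube", where = "dist")
  q2 <- vessel_mean_flow(sim2, "tube_seg2", where = "dist")
  expect_rel_error(q2, q1, 0.01)
})

test_that("splits below the discretisation floor are rejected", {
  net <- single_vessel_network(M = 20)
  expect_error(split_vessel_at(net, "tube", 0.999), "5-cell floor")
  expect_error(split_vessel_at(net, "tube", 1.2), "strictly between")
  net5 <- single_vessel_network(M = 8)
  expect_error(split_vessel_at(net5, "tube", 0.5), "5-cell floor")
})

test_that("detaching a junction edge lowers the degree and is reversible", {
  net <- toy_cow_network()
  at <- mtflow:::find_attachment(net, "l_icapp", "proximal")
  expect_identical(at$kind, "junction")
  j <- at$index
  net2 <- detach_junction_edge(net, "l_icapp", "proximal",
                               replacement = list(type = "reflect",
                                                  params = NULL))
  expect_identical(net2$junctions[[j]]$kind, "conjunction")
  rest <- vapply(net2$junctions[[j]]$ends, function(e) e$vessel,
                 character(1))
  expect_setequal(rest, c("l_cca", "l_eca"))
  expect_identical(mtflow:::find_attachment(net2, "l_icapp",
                                            "proximal")$kind, "reflect")
  expect_equal(network_volume(net2), network_volume(net))
  # reattach: restore the original junction record and drop the boundary
  net3 <- net2
  net3$junctions[[j]] <- net$junctions[[j]]
  keep <- !vapply(net3$boundaries, function(b)
    b$vessel == "l_icapp" && b$end == "proximal", logical(1))
  net3$boundaries <- net3$boundaries[keep]
  validate_network(net3)
  expect_equal(length(net3$junctions), length(net$junctions))
  # detaching from a conjunction needs a boundary for the orphaned end
  expect_error(detach_junction_edge(net2, "l_cca", "distal",
                                    replacement = list(type = "reflect",
                                                       params = NULL)),
               "orphaned")
})

test_that("the symmetry map is an involution onto homologues", {
  net <- toy_cow_network()
  sy <- net$symmetry
  expect_true(length(sy) > 0)
  for (nm in names(sy)) expect_identical(sy[[sy[[nm]]]], nm)
  # retrieval-path vessels map left to right
  for (s in c("ICApp", "ICApd", "ICAd", "MCA")) {
    v <- net$sites[[s]]$vessel
    expect_identical(sy[[v]], sub("^l_", "r_", v))
  }
})
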