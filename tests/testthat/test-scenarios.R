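config_layout <- data.frame(
  config = paste0("C", 1:12),
  aspiration_site = c(rep("ICApp", 5), rep("ICApd", 4), rep("ICAd", 3)),
  clot = c("MCA", "ICAd", "ICApd", "ICApp", "removed",
           "MCA", "ICAd", "ICApd", "removed",
           "MCA", "ICAd", "removed"),
  mca_outlet = c("full_occlusion", rep("pre_intervention", 4),
                 "full_occlusion", rep("pre_intervention", 3),
                 "full_occlusion", rep("pre_intervention", 2)),
  phase = c(1L, 2L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 1L, 2L, 3L),
  stringsAsFactors = FALSE)

test_that("configuration enumeration matches the published table row for row", {
  cfg <- enumerate_configurations()
  expect_equal(nrow(cfg), 12L)
  expect_equal(cfg[names(config_layout)], config_layout)
  expect_true(all(cfg$bgc_site == "ICApp"))
  # per-site subsets
  expect_equal(sum(cfg$aspiration_site == "ICApp"), 5L)
  expect_equal(sum(cfg$aspiration_site == "ICApd"), 4L)
  expect_equal(sum(cfg$aspiration_site == "ICAd"), 3L)
  expect_equal(cfg$config[cfg$aspiration_site == "ICAd"],
               c("C10", "C11", "C12"))
  # phase/outlet consistency
  expect_true(all((cfg$phase == 1) == (cfg$mca_outlet == "full_occlusion")))
  expect_true(all((cfg$phase == 3) == (cfg$clot == "removed")))
  expect_error(enumerate_configurations("ACA"), "off the retrieval path")
})

test_that("campaign job enumeration multiplies subjects, configs, rates", {
  expect_equal(nrow(enumerate_campaign_jobs(211, c(0.5, 5, 10))), 7596L)
  expect_equal(nrow(enumerate_campaign_jobs(1, 5)), 12L)
  expect_equal(nrow(enumerate_campaign_jobs(character(0))), 0L)
  expect_equal(nrow(enumerate_campaign_jobs(3, 5)), 36L)
  jobs <- enumerate_campaign_jobs(2, c(0.5, 5))
  expect_equal(sum(jobs$subject == 1), 24L)
})

test_that("the BGC arrests proximal ICA flow and is idempotent", {
  net <- toy_cow_network()
  nb <- apply_bgc(net)
  expect_identical(apply_bgc(nb), nb)  # idempotent
  expect_identical(mtflow:::find_attachment(nb, "l_icapp",
                                            "proximal")$kind, "reflect")
  # CCA and ECA remain joined; contralateral untouched
  at <- mtflow:::find_attachment(nb, "l_cca", "distal")
  expect_identical(nb$junctions[[at$index]]$kind, "conjunction")
  expect_identical(mtflow:::find_attachment(nb, "r_icapp", "proximal")$kind,
                   "junction")
  # degree-3 requirement
  chain <- conjunction_chain_network(3)
  chain$sites$ICApp <- list(vessel = "seg2", end = "distal")
  expect_error(apply_bgc(chain), "degree-3")
})

test_that("aspiration inserts a constant sink with the requested rate", {
  net <- toy_cow_network()
  na <- insert_aspiration(net, "ICApd", rate = 5)
  stub <- "l_icapd_asp"
  expect_true(stub %in% names(na$vessels))
  b <- Filter(function(b) b$vessel == stub, na$boundaries)[[1]]
  expect_equal(b$type, "flow")
  expect_equal(b$params$q, 5e-6)             # 5 ml/s in SI
  expect_equal(b$params$q * 6e7 / 1e0, 300)  # = 300 ml/min
  # host split into two segments + stub
  expect_equal(length(na$vessels), length(net$vessels) + 2L)
  expect_error(insert_aspiration(net, "ICApd", rate = -1), ">= 0")
})

test_that("the moving clot narrows the lumen; severity 1 is rejected", {
  net <- toy_cow_network()
  a0 <- net$vessels$l_icad$A0
  ns <- apply_clot(net, "ICAd", severity = 0.7)
  expect_equal(ns$vessels$l_icad$A0, 0.3 * a0)
  expect_equal(ns$vessels$l_icad$beta,
               compute_beta(ns$vessels$l_icad$E, ns$vessels$l_icad$h0,
                            ns$vessels$l_icad$nu, 0.3 * a0))
  # 0.10 cm^2 lumen -> 0.03 cm^2 at severity 0.7
  v <- vessel_segment("x", L = 0.05, A0 = 0.10e-4, h0 = 3e-4, E = 8e5)
  net2 <- single_vessel_network()
  net2$vessels$tube$A0 <- 0.10e-4
  n2 <- apply_clot(net2, "tube", severity = 0.7)
  expect_equal(n2$vessels$tube$A0, 0.03e-4)
  # diameter basis squares the reduction
  nd <- apply_clot(net, "ICAd", severity = 0.5, basis = "diameter")
  expect_equal(nd$vessels$l_icad$A0, 0.25 * a0)
  # keep-beta option
  nk <- apply_clot(net, "ICAd", severity = 0.7, recompute_beta = FALSE)
  expect_equal(nk$vessels$l_icad$beta, net$vessels$l_icad$beta)
  expect_identical(apply_clot(net, "ICAd", severity = 0), net)
  expect_error(apply_clot(net, "ICAd", severity = 1), "full_occlusion")
  # full occlusion swaps the outlet windkessel for a reflector
  no <- apply_clot(net, "MCA", full_occlusion = TRUE)
  expect_identical(mtflow:::find_attachment(no, "l_mca", "distal")$kind,
                   "reflect")
})

test_that("scenario edits commute to the same final network", {
  net <- toy_cow_network()
  cfg <- enumerate_configurations()
  c8 <- cfg[cfg$config == "C8", ]  # aspiration ICApd, clot ICApd
  a <- scenario_network(net, c8, rate = 5)  # BGC -> aspiration -> clot
  # clot first, then BGC, then aspiration
  b <- apply_clot(net, "ICApd", severity = 0.7)
  b <- apply_bgc(b)
  b <- insert_aspiration(b, "ICApd", 5)
  expect_setequal(names(a$vessels), names(b$vessels))
  for (v in names(a$vessels)) expect_equal(a$vessels[[v]], b$vessels[[v]])
  key <- function(net) sort(vapply(net$boundaries, function(x)
    paste(x$vessel, x$end, x$type), character(1)))
  expect_identical(key(a), key(b))
})

test_that("a zero-subject campaign yields an empty result store", {
  camp <- run_campaign(list(), rates = 5)
  expect_equal(nrow(camp$results), 0L)
  expect_equal(nrow(camp$jobs), 0L)
})
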