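#' Toy fixture networks
#'
#' Small networks with analytically predictable behaviour, used for solver
#' verification and in the test suite: a single uniform tube, a symmetric
#' bifurcation, and a chain of identical segments joined by conjunctions.
#'
#' @param L,radius,h0,E,nu vessel geometry and wall mechanics (SI).
#' @param M cells per vessel (`NULL` = automatic).
#' @param inlet `"waveform"` (half-sine cardiac inflow), `"flow"` (constant
#'   prescribed inflow `q`), or `"reflect"` (closed end).
#' @param q constant inflow for `inlet = "flow"`, m^3/s.
#' @param peak_flow,systole,period half-sine inlet parameters.
#' @param outlet `"windkessel"` or `"reflect"`.
#' @param R_total,C_wk,Pout windkessel total resistance (R1+R2), compliance
#'   and outflow pressure; R1 is set to the characteristic impedance of the
#'   terminated vessel (impedance matching) and R2 to the remainder.
#' @return an `arterial_network`.
#' @name fixtures
NULL

wk_matched <- function(vessel, fluid, R_total, C_wk, Pout = 0) {
  zc <- characteristic_impedance(vessel, fluid)
  if (R_total <= zc)
    stop("R_total must exceed the characteristic impedance ", signif(zc, 4))
  windkessel3(R1 = zc, R2 = R_total - zc, C = C_wk, Pout = Pout, Pc = Pout)
}

#' @rdname fixtures
#' @export
single_vessel_network <- function(L = 0.2, radius = 5e-3, h0 = 1e-3, E = 4e5,
                                  nu = 0.5, M = NULL,
                                  inlet = c("waveform", "flow", "reflect"),
                                  q = 1e-5, peak_flow = 1e-4, systole = 0.3,
                                  period = 1.0,
                                  outlet = c("windkessel", "reflect"),
                                  R_total = 1.1e9, C_wk = 1e-9, Pout = 0) {
  inlet <- match.arg(inlet)
  outlet <- match.arg(outlet)
  fluid <- fluid_properties()
  v <- vessel_segment("tube", L = L, radius = radius, h0 = h0, E = E,
                      nu = nu, M = M)
  bin <- switch(inlet,
    waveform = list(vessel = "tube", end = "proximal", type = "inlet",
                    params = inlet_waveform(peak_flow, systole, period)),
    flow = list(vessel = "tube", end = "proximal", type = "flow",
                params = list(q = q)),
    reflect = list(vessel = "tube", end = "proximal", type = "reflect",
                   params = NULL))
  bout <- switch(outlet,
    windkessel = list(vessel = "tube", end = "distal", type = "windkessel",
                      params = wk_matched(v, fluid, R_total, C_wk, Pout)),
    reflect = list(vessel = "tube", end = "distal", type = "reflect",
                   params = NULL))
  arterial_network(list(v), boundaries = list(bin, bout), fluid = fluid)
}

#' @rdname fixtures
#' @export
bifurcation_network <- function(peak_flow = 1e-4, systole = 0.3,
                                period = 1.0) {
  fluid <- fluid_properties()
  parent <- vessel_segment("parent", L = 0.1, radius = 5e-3, h0 = 1e-3,
                           E = 4e5)
  d1 <- vessel_segment("left", L = 0.1, radius = 3.5e-3, h0 = 7e-4, E = 4e5)
  d2 <- vessel_segment("right", L = 0.1, radius = 3.5e-3, h0 = 7e-4, E = 4e5)
  arterial_network(
    list(parent, d1, d2),
    junctions = list(list(kind = "bifurcation", ends = list(
      list(vessel = "parent", end = "distal"),
      list(vessel = "left", end = "proximal"),
      list(vessel = "right", end = "proximal")))),
    boundaries = list(
      list(vessel = "parent", end = "proximal", type = "inlet",
           params = inlet_waveform(peak_flow, systole, period)),
      list(vessel = "left", end = "distal", type = "windkessel",
           params = wk_matched(d1, fluid, 2.2e9, 6e-10)),
      list(vessel = "right", end = "distal", type = "windkessel",
           params = wk_matched(d2, fluid, 2.2e9, 6e-10))),
    symmetry = c(left = "right", right = "left"),
    fluid = fluid)
}

#' @rdname fixtures
#' @param n number of chained segments (>= 2).
#' @export
conjunction_chain_network <- function(n = 3, peak_flow = 1e-4, systole = 0.3,
                                      period = 1.0) {
  stopifnot(n >= 2)
  fluid <- fluid_properties()
  vs <- lapply(seq_len(n), function(i)
    vessel_segment(paste0("seg", i), L = 0.1, radius = 5e-3, h0 = 1e-3,
                   E = 4e5))
  jn <- lapply(seq_len(n - 1L), function(i)
    list(kind = "conjunction", ends = list(
      list(vessel = paste0("seg", i), end = "distal"),
      list(vessel = paste0("seg", i + 1L), end = "proximal"))))
  arterial_network(
    vs, junctions = jn,
    boundaries = list(
      list(vessel = "seg1", end = "proximal", type = "inlet",
           params = inlet_waveform(peak_flow, systole, period)),
      list(vessel = paste0("seg", n), end = "distal", type = "windkessel",
           params = wk_matched(vs[[n]], fluid, 1.1e9, 1e-9))),
    fluid = fluid)
}

# parameter table of the synthetic cerebral network: name, length [m],
# radius [m], wall thickness [m], Young's modulus [Pa], outlet total
# resistance [Pa s/m^3] (NA = not an outlet), outlet compliance [m^3/Pa].
# Outlets discharge at a common outflow pressure (venous plus
# critical-closing, ~35 mmHg); resistances are sized for a mean arterial
# pressure near 91 mmHg at the 4 l/min mean inflow, and compliances for a
# diastolic decay slow enough that compliance-reduced (aged) subjects keep
# physiological diastolic pressures.
toy_cow_table <- function() {
  tab <- rbind(
    c("aorta_asc",      0.040, 0.0120, 1.6e-3, 4e5, NA,      NA),
    c("brachiocephalic",0.035, 0.0095, 1.4e-3, 4e5, NA,      NA),
    c("aortic_arch1",   0.020, 0.0112, 1.6e-3, 4e5, NA,      NA),
    c("aortic_arch2",   0.039, 0.0107, 1.6e-3, 4e5, NA,      NA),
    c("aortic_arch3",   0.020, 0.0105, 1.6e-3, 4e5, NA,      NA),
    c("thoracic_aorta", 0.150, 0.0100, 1.2e-3, 4e5, 1.83e8,  8.2e-9),
    c("basilar",        0.230, 0.0020, 4.0e-4, 8e5, NA,      NA),
    c("r_brachial",     0.250, 0.0040, 8.0e-4, 9e5, 3.17e9,  4.7e-10),
    c("l_brachial",     0.250, 0.0040, 8.0e-4, 9e5, 3.17e9,  4.7e-10),
    c("l_cca",          0.120, 0.0030, 6.0e-4, 7e5, NA,      NA),
    c("r_cca",          0.120, 0.0030, 6.0e-4, 7e5, NA,      NA),
    c("l_eca",          0.100, 0.0022, 4.5e-4, 8e5, 2.82e9,  5.3e-10),
    c("r_eca",          0.100, 0.0022, 4.5e-4, 8e5, 2.82e9,  5.3e-10),
    c("l_icapp",        0.100, 0.0020, 4.0e-4, 8e5, NA,      NA),
    c("r_icapp",        0.100, 0.0020, 4.0e-4, 8e5, NA,      NA),
    c("l_ophth",        0.020, 0.0007, 2.0e-4, 8e5, 4.13e10, 3.6e-11),
    c("r_ophth",        0.020, 0.0007, 2.0e-4, 8e5, 4.13e10, 3.6e-11),
    c("l_icapd",        0.040, 0.0020, 4.0e-4, 8e5, NA,      NA),
    c("r_icapd",        0.040, 0.0020, 4.0e-4, 8e5, NA,      NA),
    c("l_pcoa",         0.015, 0.0010, 2.5e-4, 8e5, NA,      NA),
    c("r_pcoa",         0.015, 0.0010, 2.5e-4, 8e5, NA,      NA),
    c("l_icad",         0.035, 0.0020, 4.0e-4, 8e5, NA,      NA),
    c("r_icad",         0.035, 0.0020, 4.0e-4, 8e5, NA,      NA),
    c("l_mca",          0.060, 0.0014, 3.0e-4, 8e5, 3.58e9,  4.2e-10),
    c("r_mca",          0.060, 0.0014, 3.0e-4, 8e5, 3.58e9,  4.2e-10),
    c("l_aca1",         0.012, 0.0012, 2.5e-4, 8e5, NA,      NA),
    c("r_aca1",         0.012, 0.0012, 2.5e-4, 8e5, NA,      NA),
    c("l_aca2",         0.025, 0.0012, 2.5e-4, 8e5, 6.89e9,  2.2e-10),
    c("r_aca2",         0.025, 0.0012, 2.5e-4, 8e5, 6.89e9,  2.2e-10),
    c("acoa",           0.012, 0.0010, 2.5e-4, 8e5, NA,      NA),
    c("l_pca1",         0.010, 0.0012, 2.5e-4, 8e5, NA,      NA),
    c("r_pca1",         0.010, 0.0012, 2.5e-4, 8e5, NA,      NA),
    c("l_pca2",         0.035, 0.0012, 2.5e-4, 8e5, 6.89e9,  2.2e-10),
    c("r_pca2",         0.035, 0.0012, 2.5e-4, 8e5, 6.89e9,  2.2e-10))
  data.frame(name = tab[, 1],
             L = as.numeric(tab[, 2]), radius = as.numeric(tab[, 3]),
             h0 = as.numeric(tab[, 4]), E = as.numeric(tab[, 5]),
             R_total = as.numeric(tab[, 6]), C_wk = as.numeric(tab[, 7]),
             stringsAsFactors = FALSE)
}

# common outlet outflow pressure of the synthetic network [Pa]
toy_cow_pout <- function() mmhg_to_pa(35)

toy_cow_junctions <- function() {
  bif <- function(p, d1, d2)
    list(kind = "bifurcation", ends = list(
      list(vessel = p, end = "distal"),
      list(vessel = d1, end = "proximal"),
      list(vessel = d2, end = "proximal")))
  anast <- function(p1, p2, d)
    list(kind = "anastomosis", ends = list(
      list(vessel = p1, end = "distal"),
      list(vessel = p2, end = "distal"),
      list(vessel = d, end = "proximal")))
  list(
    bif("aorta_asc", "brachiocephalic", "aortic_arch1"),
    bif("brachiocephalic", "r_cca", "r_brachial"),
    bif("aortic_arch1", "l_cca", "aortic_arch2"),
    bif("aortic_arch2", "l_brachial", "aortic_arch3"),
    bif("aortic_arch3", "basilar", "thoracic_aorta"),
    bif("l_cca", "l_eca", "l_icapp"),
    bif("r_cca", "r_eca", "r_icapp"),
    bif("l_icapp", "l_ophth", "l_icapd"),
    bif("r_icapp", "r_ophth", "r_icapd"),
    bif("l_icapd", "l_pcoa", "l_icad"),
    bif("r_icapd", "r_pcoa", "r_icad"),
    bif("l_icad", "l_mca", "l_aca1"),
    bif("r_icad", "r_mca", "r_aca1"),
    bif("l_aca1", "l_aca2", "acoa"),
    anast("r_aca1", "acoa", "r_aca2"),
    bif("basilar", "l_pca1", "r_pca1"),
    anast("l_pca1", "l_pcoa", "l_pca2"),
    anast("r_pca1", "r_pcoa", "r_pca2"))
}

#' Synthetic cerebral arterial network (upper body + circle of Willis)
#'
#' A 34-vessel network with the topology used for thrombectomy simulation:
#' ascending aorta inlet, brachial and thoracic outlets, left/right carotid
#' trees with the ICA split into ICApp / ICApd / ICAd by the Ophthalmic and
#' posterior-communicating branch points, MCA / ACA / PCA territories, and
#' the communicating arteries closing the circle of Willis. Thirteen
#' windkessel outlets terminate the network, with R1 impedance-matched.
#'
#' All parameter values are synthetic: physiologically plausible numbers
#' chosen for this package (no published baseline is reproduced). Treat them
#' as a template to be replaced with literature values for quantitative
#' work; the shipped file `inst/extdata/cow_network_synthetic.yaml` is the
#' editable equivalent.
#'
#' @param peak_flow,systole,period cardiac inlet half-sine parameters
#'   (defaults: 350 ml/s, 0.3 s, 1.0 s).
#' @param co_scale dimensionless cardiac-output scale of the inlet.
#' @return an `arterial_network` with sites `MCA`, `ICApp`, `ICApd`,
#'   `ICAd`, `ACA`, `PCoA`, `Ophthalmic`, `CCA`, `ECA`, `brachial` mapped to
#'   the left-side vessels, and a left/right symmetry map.
#' @export
toy_cow_network <- function(peak_flow = 3.5e-4, systole = 0.3, period = 1.0,
                            co_scale = 1.0) {
  fluid <- fluid_properties()
  tab <- toy_cow_table()
  vessels <- lapply(seq_len(nrow(tab)), function(i) {
    M <- max(5L, as.integer(ceiling(tab$L[i] / 6e-3)))
    # retrieval-path segments host the aspiration catheter tip and must
    # stay splittable (>= 5 cells per daughter)
    if (grepl("ica(pp|pd|d)$", tab$name[i])) M <- max(M, 10L)
    vessel_segment(tab$name[i], L = tab$L[i], radius = tab$radius[i],
                   h0 = tab$h0[i], E = tab$E[i], M = M)
  })
  names(vessels) <- tab$name
  boundaries <- list(list(
    vessel = "aorta_asc", end = "proximal", type = "inlet",
    params = inlet_waveform(peak_flow, systole, period, scale = co_scale)))
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$R_total[i])) next
    boundaries <- c(boundaries, list(list(
      vessel = tab$name[i], end = "distal", type = "windkessel",
      params = wk_matched(vessels[[tab$name[i]]], fluid, tab$R_total[i],
                          tab$C_wk[i], Pout = toy_cow_pout()))))
  }
  lr <- grep("^l_", tab$name, value = TRUE)
  sym <- c(stats::setNames(sub("^l_", "r_", lr), lr),
           stats::setNames(lr, sub("^l_", "r_", lr)))
  sites <- list(
    MCA = list(vessel = "l_mca", end = "distal"),
    ICApp = list(vessel = "l_icapp", end = "distal"),
    ICApd = list(vessel = "l_icapd", end = "distal"),
    ICAd = list(vessel = "l_icad", end = "distal"),
    ACA = list(vessel = "l_aca1", end = "distal"),
    PCoA = list(vessel = "l_pcoa", end = "distal"),
    Ophthalmic = list(vessel = "l_ophth", end = "distal"),
    CCA = list(vessel = "l_cca", end = "distal"),
    ECA = list(vessel = "l_eca", end = "distal"),
    brachial = list(vessel = "l_brachial", end = "distal"))
  arterial_network(vessels, junctions = toy_cow_junctions(),
                   boundaries = boundaries, sites = sites, symmetry = sym,
                   fluid = fluid)
}
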