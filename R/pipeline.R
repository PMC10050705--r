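#' End-to-end ageing + filtering + thrombectomy pipeline
#'
#' Runs the full study pipeline on a baseline network: (1) optional
#' calibration of the baseline against the youngest reference pressures
#' using a preliminary population; (2) virtual population generation and
#' physiological filtering per age; (3) stroke induction (complete MCA
#' occlusion) and the thrombectomy campaign over all configurations and
#' aspiration rates for the accepted subjects of `treat_age`; (4) summary
#' tables. All randomness derives from `seed`; per-stage outputs are
#' written under `out_dir` as CSV plus a JSON run manifest.
#'
#' @param baseline an `arterial_network` with the thrombectomy sites, or a
#'   path to a network YAML file.
#' @param ages ages to generate populations for.
#' @param n subjects per age.
#' @param rates aspiration rates, ml/s.
#' @param seed master seed; per-stage seeds derive from it.
#' @param out_dir output directory (created). `NULL` = no files written.
#' @param treat_age the age group whose accepted subjects undergo the
#'   thrombectomy campaign. Default 65.
#' @param n_calibrate size of the preliminary calibration population (0
#'   skips calibration and uses the baseline as supplied).
#' @param max_treated cap on the number of treated subjects (keeps runtime
#'   bounded); `Inf` treats all accepted subjects.
#' @param threshold,max_cycles,settings solver controls.
#' @param configs configuration table; default all twelve.
#' @param resume reuse stage outputs already present in `out_dir`.
#' @param verbose print progress.
#' @return list with `populations` (per age), `calibration`, `campaign`,
#'   `flow_table`, `population_summary` and `manifest`.
#' @export
pipeline_age_filter_treat <- function(baseline, ages = c(25, 35, 45, 55, 65, 75),
                                      n = 10, rates = c(0.5, 5, 10),
                                      seed = 1, out_dir = NULL,
                                      treat_age = 65, n_calibrate = 0,
                                      max_treated = Inf,
                                      threshold = 3, max_cycles = 50,
                                      settings = solver_settings(init_pc = mmhg_to_pa(75)),
                                      configs = enumerate_configurations(),
                                      resume = FALSE, verbose = FALSE) {
  if (is.character(baseline)) baseline <- load_network(baseline)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage_file <- function(nm) if (is.null(out_dir)) NULL
                             else file.path(out_dir, nm)

  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, length(ages) + 1L)

  # stage 0: calibration
  calibration <- NULL
  if (n_calibrate > 0) {
    if (verbose) cat("calibrating baseline on", n_calibrate, "subjects\n")
    youngest <- min(ages)
    prelim <- build_population(baseline, youngest, n_calibrate,
                               seed = stage_seeds[length(stage_seeds)],
                               threshold = threshold, max_cycles = max_cycles,
                               settings = settings, keep_state = FALSE,
                               verbose = verbose)
    ok <- prelim$subjects[prelim$subjects$converged, , drop = FALSE]
    sel <- calibrate_baseline(ok)
    idx <- as.integer(rownames(ok)[sel$index])
    baseline <- apply_scalings(baseline,
                               prelim$subjects[idx, scaling_factor_names])
    calibration <- list(index = idx, distance = sel$distance,
                        sbp = ok$sbp[sel$index], dbp = ok$dbp[sel$index])
  }

  # stage 1: populations per age
  populations <- list()
  for (k in seq_along(ages)) {
    age <- ages[k]
    subj_file <- stage_file(paste0("subjects_age", age, ".csv"))
    if (resume && !is.null(subj_file) && file.exists(subj_file)) {
      # checkpoint: subject scalings and pressures fully determine the
      # later stages (networks are rebuilt deterministically from them)
      subjects <- utils::read.csv(subj_file)
      populations[[as.character(age)]] <- structure(
        list(subjects = subjects, states = list(), baseline = baseline,
             age = age, seed = stage_seeds[k],
             summary = population_pressure_summary(subjects, age)),
        class = "mt_population")
      next
    }
    if (verbose) cat("population age", age, "\n")
    populations[[as.character(age)]] <-
      build_population(baseline, age, n, seed = stage_seeds[k],
                       threshold = threshold, max_cycles = max_cycles,
                       settings = settings, verbose = verbose)
  }
  pop_summary <- do.call(rbind, lapply(populations, `[[`, "summary"))
  rownames(pop_summary) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(pop_summary, stage_file("population_summary.csv"),
                     row.names = FALSE)
    for (age in names(populations))
      utils::write.csv(populations[[age]]$subjects,
                       stage_file(paste0("subjects_age", age, ".csv")),
                       row.names = FALSE)
  }

  # stage 2: thrombectomy campaign on the treated age group
  campaign <- NULL
  flow_table <- NULL
  pop_t <- populations[[as.character(treat_age)]]
  if (!is.null(pop_t) && any(pop_t$subjects$accepted %in% TRUE)) {
    idx <- which(pop_t$subjects$accepted %in% TRUE)
    if (is.finite(max_treated)) idx <- utils::head(idx, max_treated)
    nets <- subject_networks(pop_t, idx)
    if (verbose) cat("campaign:", length(nets), "subjects x",
                     nrow(configs), "configs x", length(rates), "rates\n")
    campaign <- run_campaign(nets, rates = rates, configs = configs,
                             threshold = threshold, max_cycles = max_cycles,
                             settings = settings, verbose = verbose)
    flow_table <- tryCatch(campaign_flow_table(campaign),
                           error = function(e) NULL)
    if (!is.null(out_dir)) {
      utils::write.csv(campaign$results, stage_file("campaign_results.csv"),
                       row.names = FALSE)
      if (!is.null(flow_table))
        utils::write.csv(flow_table, stage_file("mca_flow_table.csv"),
                         row.names = FALSE)
    }
  }

  manifest <- list(
    seed = seed, ages = ages, n = n, rates = rates,
    treat_age = treat_age, n_calibrate = n_calibrate,
    threshold_mmhg = threshold, max_cycles = max_cycles,
    cfl = settings$cfl, sample_dt = settings$sample_dt,
    package_version = as.character(utils::packageVersion("mtflow")),
    stage_seeds = stage_seeds)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, stage_file("manifest.json"),
                         auto_unbox = TRUE, digits = NA)

  list(populations = populations, calibration = calibration,
       campaign = campaign, flow_table = flow_table,
       population_summary = pop_summary, manifest = manifest)
}
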