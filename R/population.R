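#' Age-dependent scaling-factor distributions
#'
#' Mean and standard deviation of the dimensionless scaling ratios applied
#' to a 25-year-old baseline network to emulate ageing, for ages 25 to 75 in
#' decade steps: arterial radius, wall thickness, wall stiffness, peripheral
#' resistance, peripheral compliance and cardiac output. Values are the
#' published ageing distributions shipped with the package.
#'
#' @return data.frame with columns `age`, `factor`, `mean`, `sd`.
#' @export
ageing_scaling_table <- function() {
  utils::read.csv(system.file("extdata", "ageing_scaling_factors.csv",
                              package = "mtflow"))
}

#' Age-dependent brachial pressure reference
#'
#' Population mean and standard deviation of systolic and diastolic brachial
#' pressure (mmHg) per age group, used by the physiological plausibility
#' filter.
#'
#' @return data.frame with columns `age`, `sbp_mean`, `sbp_sd`, `dbp_mean`,
#'   `dbp_sd`.
#' @export
brachial_pressure_reference <- function() {
  utils::read.csv(system.file("extdata", "brachial_pressure_reference.csv",
                              package = "mtflow"))
}

scaling_factor_names <- c("radius", "thickness", "stiffness", "resistance",
                          "compliance", "cardiac_output")

#' Sample ageing scaling factors
#'
#' Draws independent scaling factors per subject from the age-specific
#' normal distributions, redrawing any non-positive value (a negligible
#' probability at the shipped parameters). Reproducible under a fixed seed.
#'
#' @param age one of the table's age keys (25, 35, ..., 75).
#' @param n number of subjects.
#' @param table scaling table, default [ageing_scaling_table()].
#' @param seed optional integer seed applied locally (the caller's RNG
#'   state is restored afterwards); if `NULL`, the current RNG stream is
#'   used.
#' @return data.frame of `n` rows with one column per factor, plus an
#'   `age` attribute.
#' @export
sample_scalings <- function(age, n, table = ageing_scaling_table(),
                            seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  sub <- table[table$age == age, ]
  if (!nrow(sub)) stop("age ", age, " not in the scaling table")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  out <- lapply(scaling_factor_names, function(f) {
    row <- sub[sub$factor == f, ]
    if (!nrow(row)) stop("factor '", f, "' missing for age ", age)
    x <- stats::rnorm(n, row$mean, row$sd)
    while (any(x <= 0))
      x[x <= 0] <- stats::rnorm(sum(x <= 0), row$mean, row$sd)
    x
  })
  out <- as.data.frame(stats::setNames(out, scaling_factor_names))
  attr(out, "age") <- age
  out
}

#' Apply scaling factors to a baseline network
#'
#' Builds one virtual subject's network: every vessel's diastolic lumen area
#' is multiplied by the squared radius factor, wall thickness by the
#' thickness factor and Young's modulus by the stiffness factor (the tube
#' stiffness beta is recomputed); every windkessel outlet's R1 and R2 are
#' multiplied by the resistance factor and its compliance by the compliance
#' factor; the inlet amplitude scale is multiplied by the cardiac-output
#' factor. Uniform scaling preserves the left/right geometric symmetry of
#' the baseline by construction. The operation is homogeneous: applying two
#' scaling sets in sequence equals applying their componentwise product.
#'
#' @param baseline an `arterial_network`.
#' @param s a single-row data.frame (or named list/vector) with entries
#'   `radius`, `thickness`, `stiffness`, `resistance`, `compliance`,
#'   `cardiac_output`.
#' @return the scaled `arterial_network`.
#' @export
apply_scalings <- function(baseline, s) {
  s <- as.list(s)
  missing <- setdiff(scaling_factor_names, names(s))
  if (length(missing))
    stop("scaling sample lacks: ", paste(missing, collapse = ", "))
  net <- baseline
  net$vessels <- lapply(net$vessels, function(v) {
    vessel_segment(v$name, L = v$L, A0 = v$A0 * s$radius^2,
                   h0 = v$h0 * s$thickness, E = v$E * s$stiffness,
                   nu = v$nu, Pext = v$Pext, M = v$M)
  })
  names(net$vessels) <- vapply(net$vessels, `[[`, character(1), "name")
  net$boundaries <- lapply(net$boundaries, function(b) {
    if (b$type == "windkessel") {
      b$params$R1 <- b$params$R1 * s$resistance
      b$params$R2 <- b$params$R2 * s$resistance
      b$params$C <- b$params$C * s$compliance
    } else if (b$type == "inlet") {
      b$params$scale <- b$params$scale * s$cardiac_output
    }
    b
  })
  net
}

#' Physiological plausibility filter on brachial pressures
#'
#' Accepts a subject iff both systolic and diastolic brachial pressure lie
#' within 2.575 standard deviations of the age-specific reference mean
#' (a closed acceptance rectangle: boundary values accept).
#'
#' @param sbp,dbp systolic and diastolic brachial pressure, mmHg
#'   (vectorised).
#' @param age reference age group.
#' @param reference reference table, default
#'   [brachial_pressure_reference()].
#' @param n_sd half-width of the acceptance band in standard deviations.
#'   Default 2.575.
#' @return logical vector: `TRUE` = physiologically plausible.
#' @export
physiological_filter <- function(sbp, dbp, age,
                                 reference = brachial_pressure_reference(),
                                 n_sd = 2.575) {
  row <- reference[reference$age == age, ]
  if (!nrow(row)) stop("age ", age, " not in the pressure reference table")
  # closed acceptance rectangle; tolerance keeps boundary values (e.g. a
  # threshold computed as mean + 2.575 sd) inside despite rounding
  tol <- 1e-9
  abs(sbp - row$sbp_mean) <= n_sd * row$sbp_sd * (1 + tol) &
    abs(dbp - row$dbp_mean) <= n_sd * row$dbp_sd * (1 + tol)
}

#' Select the calibrated baseline subject
#'
#' From a preliminary population simulated at the youngest age's scalings,
#' selects the subject whose systolic/diastolic brachial pressures best
#' agree with the target values (default: the age-25 reference means),
#' minimising the Euclidean distance in (SBP, DBP) space. Ties break to the
#' lowest subject index. Deterministic given the population.
#'
#' @param subjects data.frame with columns `sbp` and `dbp` (one row per
#'   simulated subject), e.g. the `$subjects` element of
#'   [build_population()].
#' @param target numeric `c(SBP, DBP)` in mmHg; default the age-25
#'   reference means.
#' @param metric distance in (SBP, DBP) space: `"euclidean"` (default) or
#'   `"manhattan"`.
#' @return list with `index` of the selected subject and its `distance`.
#' @export
calibrate_baseline <- function(subjects,
                               target = NULL,
                               metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (!nrow(subjects)) stop("empty population: nothing to calibrate against")
  if (is.null(target)) {
    ref <- brachial_pressure_reference()
    r <- ref[which.min(ref$age), ]
    target <- c(r$sbp_mean, r$dbp_mean)
  }
  ds <- abs(subjects$sbp - target[1])
  dd <- abs(subjects$dbp - target[2])
  dist <- switch(metric, euclidean = sqrt(ds^2 + dd^2), manhattan = ds + dd)
  i <- which.min(dist)  # which.min returns the first (lowest-index) minimum
  list(index = i, distance = dist[i])
}

#' Build a virtual population at one age
#'
#' Samples scaling factors, scales the baseline network per subject, runs
#' each subject to its periodic steady state, measures brachial
#' systolic/diastolic pressure at the `"brachial"` site, and applies the
#' physiological plausibility filter. Subjects whose simulation does not
#' converge are flagged and excluded from the summary (not fatal).
#'
#' @param baseline a calibrated baseline `arterial_network` with a
#'   `"brachial"` site.
#' @param age age group (must be a scaling-table key).
#' @param n number of subjects to generate.
#' @param seed integer seed for the scaling draws.
#' @param table,reference scaling and pressure-reference tables.
#' @param threshold,max_cycles,settings solver controls (see
#'   [run_to_convergence()]).
#' @param keep_state keep each subject's final solver state for
#'   warm-starting scenario runs. Default TRUE.
#' @param verbose print one line per subject.
#' @return an object of class `mt_population`: `$subjects` (data.frame with
#'   scaling factors, pressures, convergence and acceptance flags),
#'   `$states` (per-subject solver states, if kept), `$baseline`, `$age`,
#'   `$seed` and `$summary` (per-age acceptance count and pressure
#'   moments).
#' @export
build_population <- function(baseline, age, n, seed = 1,
                             table = ageing_scaling_table(),
                             reference = brachial_pressure_reference(),
                             threshold = 3, max_cycles = 50,
                             settings = solver_settings(init_pc = mmhg_to_pa(75)),
                             keep_state = TRUE, verbose = FALSE) {
  if (n == 0) {
    subjects <- data.frame(matrix(numeric(0), 0, 10,
      dimnames = list(NULL, c(scaling_factor_names, "sbp", "dbp",
                              "converged", "accepted"))))
    return(structure(list(subjects = subjects, states = list(),
                          baseline = baseline, age = age, seed = seed,
                          summary = population_pressure_summary(subjects, age)),
                     class = "mt_population"))
  }
  sc <- sample_scalings(age, n, table = table, seed = seed)
  sbp <- dbp <- rep(NA_real_, n)
  converged <- rep(FALSE, n)
  states <- vector("list", n)
  for (i in seq_len(n)) {
    net_i <- apply_scalings(baseline, sc[i, ])
    sim <- tryCatch(
      suppressWarnings(run_to_convergence(net_i, threshold = threshold,
                                          max_cycles = max_cycles,
                                          settings = settings)),
      error = function(e) NULL)
    if (!is.null(sim) && sim$converged) {
      p <- site_pressures(sim, "brachial")
      sbp[i] <- p[["SBP"]]; dbp[i] <- p[["DBP"]]
      converged[i] <- TRUE
      if (keep_state) states[[i]] <- sim$state
    }
    if (verbose)
      cat(sprintf("subject %d/%d: %s SBP %.1f DBP %.1f\n", i, n,
                  if (converged[i]) "ok" else "FAILED",
                  sbp[i], dbp[i]))
  }
  accepted <- converged &
    physiological_filter(sbp, dbp, age, reference = reference) %in% TRUE
  subjects <- cbind(sc, data.frame(sbp = sbp, dbp = dbp,
                                   converged = converged,
                                   accepted = accepted))
  structure(list(subjects = subjects, states = states, baseline = baseline,
                 age = age, seed = seed,
                 summary = population_pressure_summary(subjects, age)),
            class = "mt_population")
}

population_pressure_summary <- function(subjects, age) {
  acc <- subjects[subjects$accepted %in% TRUE, , drop = FALSE]
  data.frame(age = age, n_total = nrow(subjects), n_accepted = nrow(acc),
             sbp_mean = if (nrow(acc)) mean(acc$sbp) else NA_real_,
             sbp_sd = if (nrow(acc) > 1) stats::sd(acc$sbp) else NA_real_,
             dbp_mean = if (nrow(acc)) mean(acc$dbp) else NA_real_,
             dbp_sd = if (nrow(acc) > 1) stats::sd(acc$dbp) else NA_real_)
}

#' @export
print.mt_population <- function(x, ...) {
  cat("Virtual population, age", x$age, ":", nrow(x$subjects),
      "generated,", sum(x$subjects$accepted %in% TRUE),
      "physiologically plausible\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Networks of the accepted subjects of a population
#'
#' Rebuilds each accepted subject's scaled network from the baseline and
#' its stored scaling factors (deterministic).
#'
#' @param pop an `mt_population`.
#' @param which subject indices; default all accepted subjects.
#' @return named list of `arterial_network`s (names = subject indices).
#' @export
subject_networks <- function(pop, which = NULL) {
  if (is.null(which)) which <- base::which(pop$subjects$accepted %in% TRUE)
  nets <- lapply(which, function(i)
    apply_scalings(pop$baseline, pop$subjects[i, scaling_factor_names]))
  stats::setNames(nets, as.character(which))
}
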