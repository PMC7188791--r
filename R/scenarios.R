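#' Built-in experiment scenarios
#'
#' Reproducible definitions of the study designs: a nitrate ladder (2, 5, 10,
#' 20, 200, 2000 mM KNO3 with 1 vol% O2), a nitrite ladder (1, 2, 5, 10, 40
#' mM KNO2 with 1 vol% O2), the transcription time-course (5 mM KNO3, 1 vol%
#' O2, with liquid harvests for expression sampling), the aerobic N2O
#' reduction design in both its variants (1 vol% O2 with either 100 ppmv or
#' 1 vol% N2O, plus 5 mM KNO3), and an abiotic (uninoculated) control.
#'
#' @return Named list of `vial_scenario` objects.
#' @export
builtin_scenarios <- function() {
  sc <- list()
  for (mM in c(2, 5, 10, 20, 200, 2000))
    sc[[paste0("nitrate_", mM, "mM")]] <-
      scenario(paste0("nitrate_", mM, "mM"), no3_mM = mM)
  for (mM in c(1, 2, 5, 10, 40))
    sc[[paste0("nitrite_", mM, "mM")]] <-
      scenario(paste0("nitrite_", mM, "mM"), no2_mM = mM)
  sc$transcription <- scenario(
    "transcription", no3_mM = 5,
    harvests = data.frame(time_h = c(12, 24, 48), volume_ml = c(5, 5, 5)))
  sc$aerobic_n2o_100ppmv <- scenario(
    "aerobic_n2o_100ppmv", no3_mM = 5, n2o_ppmv = 100,
    duration_h = 48, sample_every_h = 3.6)
  sc$aerobic_n2o_1pct <- scenario(
    "aerobic_n2o_1pct", no3_mM = 5, n2o_ppmv = 10000,
    duration_h = 48, sample_every_h = 3.6)
  sc$abiotic <- scenario("abiotic", inoculum_cells = 0, duration_h = 24)
  sc
}

#' Define one incubation scenario
#'
#' @param name Scenario name.
#' @param geometry A [vial_geometry()].
#' @param no3_mM,no2_mM Medium amendments, mM.
#' @param o2_ppmv,n2o_ppmv Initial headspace injections (default 1 vol% O2).
#' @param inoculum_cells Inoculum, cells per vial (0 = abiotic).
#' @param duration_h,sample_every_h,sample_ml Sampling schedule.
#' @param harvests Optional liquid-harvest table (`time_h`, `volume_ml`).
#' @param params Parameter list as from [default_params()] or
#'   [read_params()].
#' @param noise A [noise_model()] (its seed is overridden by `run_scenario`).
#' @return Object of class `vial_scenario`.
#' @export
scenario <- function(name, geometry = vial_geometry(), no3_mM = 0,
                     no2_mM = 0, o2_ppmv = 10000, n2o_ppmv = 0,
                     inoculum_cells = 2e8, duration_h = 90,
                     sample_every_h = 2, sample_ml = 1, harvests = NULL,
                     params = default_params(), noise = noise_model()) {
  structure(list(name = name, geometry = geometry, no3_mM = no3_mM,
                 no2_mM = no2_mM, o2_ppmv = o2_ppmv, n2o_ppmv = n2o_ppmv,
                 inoculum_cells = inoculum_cells, duration_h = duration_h,
                 sample_every_h = sample_every_h, sample_ml = sample_ml,
                 harvests = harvests, params = params, noise = noise),
            class = "vial_scenario")
}

#' @export
print.vial_scenario <- function(x, ...) {
  cat(sprintf("<vial_scenario '%s'> NO3 %g mM, NO2 %g mM, O2 %g ppmv, N2O %g ppmv, %g h\n",
              x$name, x$no3_mM, x$no2_mM, x$o2_ppmv, x$n2o_ppmv,
              x$duration_h))
  invisible(x)
}

scenario_protocol <- function(sc) {
  standard_protocol(duration_h = sc$duration_h,
                    sample_every_h = sc$sample_every_h,
                    sample_ml = sc$sample_ml,
                    inoculum_cells = sc$inoculum_cells,
                    o2_ppmv = sc$o2_ppmv, n2o_ppmv = sc$n2o_ppmv,
                    harvests = sc$harvests)
}

scenario_init_state <- function(sc) {
  vial_state(sc$geometry, no3_mM = sc$no3_mM, no2_mM = sc$no2_mM)
}

#' Run one scenario end to end
#'
#' Simulation, sampling emulation with seeded noise, and the inference
#' pipeline; optionally writes the artifact bundle (measurements, ground
#' truth, rate/electron-flow series, fits and a Markdown report) to a
#' directory.  Deterministic for a fixed seed.
#'
#' @param sc A [scenario()].
#' @param seed Integer seed for the measurement noise.
#' @param out_dir Optional output directory.
#' @param no_noise If `TRUE`, emit noise-free measurements.
#' @param ... Passed to [simulate_vial()].
#' @return list of class `scenario_run`: `scenario`, `incubation`,
#'   `inference`, `summary` (one-row data.frame), `report` (character).
#' @export
run_scenario <- function(sc, seed = 1, out_dir = NULL, no_noise = FALSE,
                         ...) {
  stopifnot(inherits(sc, "vial_scenario"))
  noise <- sc$noise
  noise$seed <- seed
  if (no_noise) { noise$sd_rel <- 0; noise$floor_gas_umol <- 0
                  noise$floor_no2_uM <- 0 }
  prot <- scenario_protocol(sc)
  inc <- run_incubation(prot, sc$params$kinetic, sc$params$regulatory,
                        sc$geometry, scenario_init_state(sc), noise, ...)
  ## noisy rate series are smoothed before fitting; exact series are not
  noisy <- noise$sd_rel > 0 || noise$floor_gas_umol > 0
  inf <- infer_kinetics(inc$measurements, sc$geometry,
                        no_floor_nM = noise$no_floor_nM, smooth = noisy)
  summ <- summarize_noxide_accumulation(inc$trajectory, inf$fit_anoxic,
                                        noise$no_floor_nM)
  pot <- if (sc$no3_mM > 0)
    potential_generations(sc$no3_mM * sc$geometry$liquid_ml,
                          sc$params$kinetic$yield,
                          max(sc$inoculum_cells, 1))
  else NA_real_
  row <- data.frame(
    scenario = sc$name, seed = seed,
    mu_ox = inf$fit_oxic$mu, mu_anox = inf$fit_anoxic$mu,
    G_ox_h = inf$fit_oxic$generation_time_h,
    G_anox_h = inf$fit_anoxic$generation_time_h,
    generations_anoxic = inf$fit_anoxic$generations,
    potential_generations = pot,
    NO_max_nM = summ$NO_max_nM, NO_steady_nM = summ$NO_steady_nM,
    N2O_max_umol_N = summ$N2O_max_umol_N, NO2_max_umol = summ$NO2_max_umol,
    O2_at_onset_uM = summ$O2_at_onset_uM)
  report <- scenario_report(sc, inf, summ, row, seed)
  out <- structure(list(scenario = sc, incubation = inc, inference = inf,
                        summary = row, noxide = summ, report = report),
                   class = "scenario_run")
  if (!is.null(out_dir)) write_scenario_bundle(out, out_dir)
  out
}

scenario_report <- function(sc, inf, summ, row, seed) {
  fit_line <- function(f) {
    if (!f$ok) return("no qualifying log-linear window")
    sprintf("mu = %.4g /h (se %.2g), R2 = %.4f, window [%.3g, %.3g] h, G(t) = %.3g h",
            f$mu, f$se, f$r2, f$window[1], f$window[2], f$generation_time_h)
  }
  lines <- c(
    sprintf("# Scenario report: %s", sc$name),
    "",
    sprintf("- seed: %d", seed),
    sprintf("- amendments: %g mM KNO3, %g mM KNO2", sc$no3_mM, sc$no2_mM),
    sprintf("- initial headspace: %g ppmv O2, %g ppmv N2O", sc$o2_ppmv,
            sc$n2o_ppmv),
    "",
    "## Growth fits",
    paste0("- oxic: ", fit_line(inf$fit_oxic)),
    paste0("- anoxic: ", fit_line(inf$fit_anoxic)),
    sprintf("- anoxic generations: %.3g (potential %.3g)",
            row$generations_anoxic, row$potential_generations),
    "",
    "## N-oxide accumulation",
    sprintf("- NO_max: %.4g nM; NO_steady: %.4g nM", summ$NO_max_nM,
            summ$NO_steady_nM),
    sprintf("- N2O_max: %.4g umol N2O-N vial^-1 (%.4g nM liquid)",
            summ$N2O_max_umol_N, summ$N2O_max_nM),
    sprintf("- NO2_max: %.4g umol vial^-1 (%.4g uM)", summ$NO2_max_umol,
            summ$NO2_max_uM),
    sprintf("- liquid O2 at denitrification onset: %.4g uM",
            summ$O2_at_onset_uM))
  if (identical(sc$name, "transcription")) {
    lines <- c(lines, "",
               "## Transcript series (copies per ng RNA)",
               "- genes: narG, nirK, norZ, nosZ (norZ is also known under its primer alias norB)",
               "- see transcripts.csv in the bundle")
  }
  paste(lines, collapse = "\n")
}

write_scenario_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_measurements(run$incubation$measurements, p("measurements.csv"),
                     geometry = run$scenario$geometry,
                     protocol = scenario_protocol(run$scenario),
                     seed = run$summary$seed)
  utils::write.csv(run$incubation$truth_table, p("measurements_truth.csv"),
                   row.names = FALSE)
  export_trajectory_csv(run$incubation$trajectory, p("trajectory_truth.csv"))
  utils::write.csv(run$inference$rates, p("rates.csv"), row.names = FALSE)
  utils::write.csv(run$inference$eflow, p("eflow.csv"), row.names = FALSE)
  utils::write.csv(run$inference$ratio, p("nar_nir_ratio.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, p("summary.csv"), row.names = FALSE)
  st <- run$incubation$trajectory$states
  reg <- run$scenario$params$regulatory
  tr <- data.frame(time_h = st$time_h,
                   narG = transcripts_per_ng_rna(st$m_narG, reg),
                   nirK = transcripts_per_ng_rna(st$m_nirK, reg),
                   norZ = transcripts_per_ng_rna(st$m_norZ, reg),
                   nosZ = transcripts_per_ng_rna(st$m_nosZ, reg))
  utils::write.csv(tr, p("transcripts.csv"), row.names = FALSE)
  writeLines(run$report, p("report.md"))
  invisible(out_dir)
}

#' Run a set of scenarios and summarize
#'
#' Triplicate-style replication is realized as seed offsets (`seed`,
#' `seed + 1`, ...) when `replicates > 1`.
#'
#' @param scenarios Named list of [scenario()] objects.
#' @param seed Base seed.
#' @param replicates Number of replicate vials per scenario.
#' @param ... Passed to [run_scenario()].
#' @return data.frame with one summary row per scenario x replicate.
#' @export
run_scenario_set <- function(scenarios, seed = 1, replicates = 1, ...) {
  rows <- list()
  for (sc in scenarios) {
    for (r in seq_len(replicates)) {
      run <- run_scenario(sc, seed = seed + r - 1L, ...)
      rows[[length(rows) + 1L]] <- run$summary
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
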