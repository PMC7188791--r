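#' Headspace sampling with helium back-fill
#'
#' Removes an aliquot of `sample_volume_ml` from a stirred headspace
#' (instantaneous ideal mixing: the aliquot has the current composition), so
#' every gas amount is multiplied by `1 - f` with
#' `f = sample_volume_ml / headspace_ml`, then He is pumped back so the total
#' headspace amount (hence pressure) is restored.  The returned measurement
#' reflects the pre-sampling headspace.
#'
#' @param state State vector.
#' @param sample_volume_ml Sampled volume, mL; must be below the headspace
#'   volume.
#' @param geometry A [vial_geometry()].
#' @return list with `measurement` (one-row data.frame: time-less pre-sample
#'   gas amounts, mixing ratios, liquid NO2- and biomass, and `f`) and the
#'   post-sampling `state`.
#' @export
apply_headspace_sampling <- function(state, sample_volume_ml,
                                     geometry = vial_geometry()) {
  if (sample_volume_ml < 0 || sample_volume_ml >= geometry$headspace_ml)
    stop("invalid protocol: sample volume must be in [0, headspace volume)")
  f <- sample_volume_ml / geometry$headspace_ml
  gases <- c("O2_g", "NO_g", "N2O_g", "N2_g", "He_g")
  pre <- state[gases]
  total_pre <- sum(pre)
  meas <- data.frame(
    O2_umol = pre[["O2_g"]], NO_umol = pre[["NO_g"]],
    N2O_umol = pre[["N2O_g"]], N2_umol = pre[["N2_g"]],
    O2_ppmv = pre[["O2_g"]] / total_pre * 1e6,
    NO_ppmv = pre[["NO_g"]] / total_pre * 1e6,
    N2O_ppmv = pre[["N2O_g"]] / total_pre * 1e6,
    N2_ppmv = pre[["N2_g"]] / total_pre * 1e6,
    no2_uM = state[["NO2_l"]],
    biomass_proxy = state[["biomass"]],
    liquid_ml = geometry$liquid_ml,
    f = f)
  post <- state
  post[gases] <- pre * (1 - f)
  post[["He_g"]] <- post[["He_g"]] + f * total_pre
  list(measurement = meas, state = post)
}

#' Liquid harvest with headspace expansion
#'
#' Removes `volume_ml` of well-mixed liquid: biomass is reduced by the
#' removed fraction while liquid concentrations are unchanged (dissolved
#' amounts drop proportionally because the liquid volume shrinks).  The
#' headspace expands by the harvested volume and He is added to keep the
#' pressure at the geometry value.
#'
#' @param state State vector.
#' @param volume_ml Harvested liquid volume, mL (must not exceed the liquid
#'   volume).
#' @param geometry A [vial_geometry()].
#' @return list with the post-harvest `state` and the updated `geometry`.
#' @export
apply_liquid_harvest <- function(state, volume_ml,
                                 geometry = vial_geometry()) {
  if (volume_ml < 0 || volume_ml > geometry$liquid_ml)
    stop("invalid protocol: harvest volume exceeds the liquid volume")
  frac <- volume_ml / geometry$liquid_ml
  post <- state
  post[["biomass"]] <- state[["biomass"]] * (1 - frac)
  new_geom <- geometry
  new_geom$liquid_ml <- geometry$liquid_ml - volume_ml
  new_geom$headspace_ml <- geometry$headspace_ml + volume_ml
  he_add <- geometry$pressure_atm * (volume_ml / 1000) /
    (R_GAS * geometry$temperature_K) * 1e6
  post[["He_g"]] <- post[["He_g"]] + he_add
  list(state = post, geometry = new_geom)
}

#' Measurement noise model
#'
#' Lognormal multiplicative noise (relative sd per instrument) plus an
#' additive Gaussian detection floor, applied only to emitted measurements,
#' never to the simulated state.  With all sds zero, measurements equal the
#' ground truth exactly.  The seed is an explicit argument; the same seed and
#' protocol give an identical table.
#'
#' @param sd_rel Relative (multiplicative, lognormal sdlog) noise sd for gas
#'   amounts and the nitrite assay.
#' @param floor_gas_umol Additive sd of the gas instruments, umol.
#' @param floor_no2_uM Additive sd of the nitrite assay, uM.
#' @param no_floor_nM Detection floor of the NO analyzer, nM liquid; used by
#'   the denitrification-onset rule downstream.
#' @param seed Integer seed, or `NULL` to draw from the session RNG.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sd_rel = 0.02, floor_gas_umol = 0.001,
                        floor_no2_uM = 0.1, no_floor_nM = 1, seed = NULL) {
  if (sd_rel < 0 || floor_gas_umol < 0 || floor_no2_uM < 0)
    stop("noise sds must be non-negative")
  structure(list(sd_rel = sd_rel, floor_gas_umol = floor_gas_umol,
                 floor_no2_uM = floor_no2_uM, no_floor_nM = no_floor_nM,
                 seed = seed), class = "noise_model")
}

## Run fn with a local RNG state seeded by `seed` (NULL = use current RNG).
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Apply measurement noise to a noise-free measurement table
#'
#' @param table A measurement table as returned by [run_incubation()] with
#'   `noise = noise_model(0, 0, 0)` (or the `truth_table` element).
#' @param noise A [noise_model()].
#' @return The table with noisy gas amounts, mixing ratios and nitrite;
#'   values are clipped at zero.
#' @export
apply_measurement_noise <- function(table, noise = noise_model()) {
  if (noise$sd_rel == 0 && noise$floor_gas_umol == 0 &&
      noise$floor_no2_uM == 0)
    return(table)
  gcols <- c("O2_umol", "NO_umol", "N2O_umol", "N2_umol")
  with_local_seed(noise$seed, function() {
    n <- nrow(table)
    for (g in gcols) {
      table[[g]] <- pmax(
        table[[g]] * exp(stats::rnorm(n, 0, noise$sd_rel)) +
          stats::rnorm(n, 0, noise$floor_gas_umol), 0)
    }
    table$no2_uM <- pmax(
      table$no2_uM * exp(stats::rnorm(n, 0, noise$sd_rel)) +
        stats::rnorm(n, 0, noise$floor_no2_uM), 0)
    table
  })
}

#' Read or write a measurement table as CSV with a metadata sidecar
#'
#' The table itself is a plain CSV with the documented header
#' (`time_h`, per-gas `*_umol` and `*_ppmv`, `no2_uM`, `biomass_proxy`,
#' `liquid_ml`, `f`).  `write_measurements()` also writes a YAML sidecar
#' (`<path>.meta.yaml`) carrying the geometry, the noise seed, and an MD5
#' digest of the protocol event list, so a table's provenance can be
#' checked when it is read back.
#'
#' @param table Measurement table.
#' @param path CSV path.
#' @param geometry A [vial_geometry()].
#' @param protocol The [protocol()] that produced the table (optional).
#' @param seed The noise seed used (optional).
#' @export
write_measurements <- function(table, path, geometry = NULL,
                               protocol = NULL, seed = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  digest <- NULL
  if (!is.null(protocol)) {
    tmp <- tempfile()
    utils::write.csv(as.data.frame(protocol), tmp, row.names = FALSE)
    digest <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  meta <- list(geometry = if (!is.null(geometry)) unclass(geometry),
               protocol_md5 = digest, seed = seed,
               n_rows = nrow(table))
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_measurements
#' @return `read_measurements()`: the table, with the sidecar (if present)
#'   attached as attribute `"meta"`.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("time_h", "O2_umol", "NO_umol", "N2O_umol", "N2_umol",
            "no2_uM", "liquid_ml", "f")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("measurement table is missing columns: ",
         paste(miss, collapse = ", "))
  side <- paste0(path, ".meta.yaml")
  if (file.exists(side)) attr(tab, "meta") <- yaml::read_yaml(side)
  tab
}

#' Run one incubation: simulate, sample, add measurement noise
#'
#' Alternates ODE integration with discrete protocol events and emits the
#' measurement table the instruments would see.  Noise touches only the
#' emitted table; the returned ground truth is the noise-free trajectory.
#'
#' @param protocol A [protocol()].
#' @param kin A [kinetic_params()].
#' @param reg A [regulatory_params()].
#' @param geometry A [vial_geometry()].
#' @param init_state Initial state; defaults to a sterile He-filled vial
#'   (amendments are usually set here, see [vial_state()]).
#' @param noise A [noise_model()].
#' @param ... Passed to [simulate_vial()] (integrator options).
#' @return list of class `incubation`: `measurements` (noisy table),
#'   `truth_table` (noise-free table), `trajectory` (a `vial_trajectory`).
#' @export
run_incubation <- function(protocol, kin = kinetic_params(),
                           reg = regulatory_params(),
                           geometry = vial_geometry(),
                           init_state = vial_state(geometry),
                           noise = noise_model(), ...) {
  traj <- simulate_vial(protocol, kin, reg, geometry, init_state, ...)
  truth <- traj$measurements
  meas <- apply_measurement_noise(truth, noise)
  structure(list(measurements = meas, truth_table = truth,
                 trajectory = traj, noise = noise),
            class = "incubation")
}
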