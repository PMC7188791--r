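#' Simulate one sealed vial over a protocol
#'
#' Integrates the vial ODE between discrete protocol events with a
#' stiff-capable implicit solver (`deSolve::lsoda`), applying each event as
#' an instantaneous state (and, for liquid harvests, geometry) change:
#' stop-modify-restart.  Oxygen depletion makes the system stiff, hence the
#' implicit default.
#'
#' @param protocol A [protocol()].
#' @param kin A [kinetic_params()].
#' @param reg A [regulatory_params()].
#' @param geometry A [vial_geometry()].
#' @param init_state Initial state vector (see [vial_state()]).
#' @param rtol,atol Integrator tolerances.  `atol` may be a single value or a
#'   full per-state vector; the default scales the absolute tolerance to the
#'   disparate magnitudes of gas amounts (umol), trace liquid concentrations
#'   (uM) and biomass (cells).
#' @param dt_out Output grid spacing for the dense trajectory, h.
#' @param method `deSolve` method name.
#' @return Object of class `vial_trajectory`: `states` (data.frame of the
#'   dense state series, plus `liquid_ml`), `events` (event log),
#'   `measurements` (noise-free pre-sampling measurement rows with `time_h`
#'   and `f`), `geometry` (final), `geometry_initial`, `kin`, `reg`.
#' @export
simulate_vial <- function(protocol, kin = kinetic_params(),
                          reg = regulatory_params(),
                          geometry = vial_geometry(),
                          init_state = vial_state(geometry),
                          rtol = 1e-8, atol = NULL, dt_out = 0.5,
                          method = "lsoda") {
  stopifnot(inherits(protocol, "vial_protocol"))
  if (is.null(atol))
    atol <- c(rep(1e-7, 5),      # headspace amounts, umol
              rep(1e-9, 5),      # liquid concentrations, uM
              1,                 # biomass, cells
              rep(1e-8, 4),      # enzymes
              rep(1e-9, 4))      # transcripts
  state <- unclass(init_state)[STATE_NAMES]
  geom <- geometry
  henry <- henry_coefficient(c("O2", "NO", "N2O"), geom$temperature_K,
                             geom$salt_load)
  t_now <- protocol$time_h[1]
  if (t_now > 0) t_now <- 0
  rows <- list(); meas <- list(); evlog <- list()
  push_states <- function(m, liquid_ml) {
    df <- as.data.frame(m)
    names(df)[1] <- "time_h"
    df$liquid_ml <- liquid_ml
    rows[[length(rows) + 1L]] <<- df
  }
  rhs <- function(t, y, p) list(state_derivative(y, kin, reg, p$geom, henry))
  integrate_to <- function(t1) {
    if (t1 <= t_now + 1e-12) return(invisible())
    times <- unique(c(seq(t_now, t1, by = dt_out), t1))
    out <- tryCatch(
      deSolve::ode(y = state, times = times, func = rhs,
                   parms = list(geom = geom), method = method,
                   rtol = rtol, atol = atol),
      warning = function(w) w, error = function(e) e)
    if (inherits(out, "condition") ||
        abs(out[nrow(out), 1] - t1) > 1e-8)
      stop(errorCondition(
        paste0("integration failed near t = ", signif(t_now, 6), " h: ",
               if (inherits(out, "condition")) conditionMessage(out)
               else "incomplete solution"),
        class = "denitvial_integration_error",
        last_state = state, last_time = t_now))
    push_states(out, geom$liquid_ml)
    state <<- pmax(out[nrow(out), -1], 0)
    t_now <<- t1
    invisible()
  }
  for (i in seq_len(nrow(protocol))) {
    ev <- protocol[i, ]
    integrate_to(ev$time_h)
    evlog[[length(evlog) + 1L]] <-
      data.frame(time_h = ev$time_h, action = ev$action,
                 detail = .ev_detail(ev))
    if (ev$action == "inoculate") {
      state[["biomass"]] <- state[["biomass"]] + ev$cells
    } else if (ev$action == "inject_gas") {
      amt <- if (!is.na(ev$amount_umol)) ev$amount_umol
             else ppmv_to_amount(ev$ppmv, geom)
      key <- paste0(ev$species, "_g")
      if (!key %in% STATE_NAMES) stop("unknown gas species: ", ev$species)
      state[[key]] <- state[[key]] + amt
      ## injection displaces He so the total stays at the geometry pressure
      state[["He_g"]] <- max(state[["He_g"]] - amt, 0)
    } else if (ev$action == "sample_headspace") {
      s <- apply_headspace_sampling(state, ev$volume_ml, geom)
      m <- s$measurement
      m <- cbind(data.frame(time_h = ev$time_h), m)
      meas[[length(meas) + 1L]] <- m
      state <- s$state
    } else if (ev$action == "harvest_liquid") {
      h <- apply_liquid_harvest(state, ev$volume_ml, geom)
      state <- h$state
      geom <- h$geometry
    } else if (ev$action == "end") {
      break
    }
  }
  ## record the terminal state after the last event (e.g. a final sampling)
  fin <- as.data.frame(as.list(state))
  fin <- cbind(data.frame(time_h = t_now), fin)
  fin$liquid_ml <- geom$liquid_ml
  rows[[length(rows) + 1L]] <- fin
  states <- do.call(rbind, rows)
  states <- states[!duplicated(states$time_h, fromLast = TRUE), ]
  rownames(states) <- NULL
  ## integrator output can undershoot zero by ~atol; clamp the noise
  for (v in STATE_NAMES) {
    neg <- states[[v]] < 0
    if (any(neg)) {
      if (min(states[[v]]) < -1e-6)
        warning("state variable ", v, " went negative beyond tolerance")
      states[[v]][neg] <- 0
    }
  }
  measurements <- if (length(meas) > 0) do.call(rbind, meas)
                  else NULL
  if (!is.null(measurements)) rownames(measurements) <- NULL
  structure(list(states = states,
                 events = do.call(rbind, evlog),
                 measurements = measurements,
                 geometry = geom, geometry_initial = geometry,
                 kin = kin, reg = reg),
            class = "vial_trajectory")
}

.ev_detail <- function(ev) {
  switch(ev$action,
         inoculate = sprintf("%.3g cells", ev$cells),
         inject_gas = if (!is.na(ev$ppmv))
           sprintf("%s %.6g ppmv", ev$species, ev$ppmv)
         else sprintf("%s %.6g umol", ev$species, ev$amount_umol),
         sample_headspace = sprintf("%.3g mL", ev$volume_ml),
         harvest_liquid = sprintf("%.3g mL", ev$volume_ml),
         "")
}

#' @export
print.vial_trajectory <- function(x, ...) {
  cat(sprintf("<vial_trajectory> %d output times over %.4g h, %d events, %d samplings\n",
              nrow(x$states), max(x$states$time_h), nrow(x$events),
              if (is.null(x$measurements)) 0L else nrow(x$measurements)))
  invisible(x)
}

#' True instantaneous electron flows along a trajectory
#'
#' Recomputes the per-process electron rates (umol e- vial^-1 h^-1) from the
#' stored states; this is the simulator's ground truth against which the
#' measurement-based inference can be compared.
#'
#' @param traj A `vial_trajectory`.
#' @return data.frame: `time_h`, `Ve_O2`, `Ve_NAR`, `Ve_NIR`, `Ve_NOR`,
#'   `Ve_N2OR`, `Ve_Nox` (total to N-oxides).
#' @export
trajectory_eflows <- function(traj) {
  st <- traj$states
  geom <- traj$geometry_initial
  henry <- henry_coefficient(c("O2", "NO", "N2O"), geom$temperature_K,
                             geom$salt_load)
  n <- nrow(st)
  out <- matrix(0, n, 5)
  g <- geom
  for (i in seq_len(n)) {
    g$liquid_ml <- st$liquid_ml[i]
    g$headspace_ml <- g$total_ml - g$liquid_ml
    y <- as.numeric(st[i, STATE_NAMES]); names(y) <- STATE_NAMES
    r <- process_rates(y, traj$kin, g, henry)
    out[i, ] <- r[c("v_O2", "v_NAR", "v_NIR", "v_NOR", "v_N2OR")]
  }
  data.frame(time_h = st$time_h, Ve_O2 = out[, 1], Ve_NAR = out[, 2],
             Ve_NIR = out[, 3], Ve_NOR = out[, 4], Ve_N2OR = out[, 5],
             Ve_Nox = rowSums(out[, 2:5, drop = FALSE]))
}

#' Export a trajectory as tidy CSV
#'
#' Long format: `time_h`, `variable`, `value`, `units`.
#'
#' @param traj A `vial_trajectory`.
#' @param path Output CSV path.
#' @export
export_trajectory_csv <- function(traj, path) {
  st <- traj$states
  units <- c(rep("umol", 5), rep("uM", 5), "cells",
             rep("fmol_e_per_cell_h", 4), rep("copies_per_cell", 4), "mL")
  vars <- c(STATE_NAMES, "liquid_ml")
  long <- do.call(rbind, lapply(seq_along(vars), function(j)
    data.frame(time_h = st$time_h, variable = vars[j],
               value = st[[vars[j]]], units = units[j])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
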