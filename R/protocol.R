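#' Experiment protocols: timed event lists
#'
#' A protocol is an ordered table of discrete events applied to a vial:
#' inoculation, gas injection, headspace sampling (with He back-fill), liquid
#' harvest, and the end of the experiment.  Build events with the `ev_*`
#' helpers and assemble them with `protocol()`; times must be non-decreasing,
#' inoculation may occur at most once, and an `end` event is appended at the
#' last event time if missing.
#'
#' @param ... Events created by `ev_inoculate()`, `ev_inject_gas()`,
#'   `ev_sample_headspace()`, `ev_harvest_liquid()`, `ev_end()`, or a single
#'   list/data.frame of such events.
#' @return data.frame of class `vial_protocol` with columns `time_h`,
#'   `action`, `species`, `ppmv`, `amount_umol`, `volume_ml`, `cells`.
#' @export
protocol <- function(...) {
  evs <- list(...)
  if (length(evs) == 1L && is.data.frame(evs[[1]])) {
    out <- evs[[1]]
  } else {
    if (length(evs) == 1L && is.list(evs[[1]]) && !is.data.frame(evs[[1]]) &&
        is.data.frame(evs[[1]][[1]]))
      evs <- evs[[1]]
    out <- do.call(rbind, evs)
  }
  if (is.unsorted(out$time_h))
    stop("protocol event times must be non-decreasing")
  if (sum(out$action == "inoculate") > 1L)
    stop("a protocol may contain at most one inoculation")
  if (!"end" %in% out$action)
    out <- rbind(out, ev_end(max(out$time_h)))
  if (any(out$time_h > out$time_h[out$action == "end"][1]))
    stop("no event may come after 'end'")
  rownames(out) <- NULL
  class(out) <- c("vial_protocol", "data.frame")
  out
}

.ev <- function(time_h, action, species = NA_character_, ppmv = NA_real_,
                amount_umol = NA_real_, volume_ml = NA_real_,
                cells = NA_real_) {
  data.frame(time_h = time_h, action = action, species = species,
             ppmv = ppmv, amount_umol = amount_umol, volume_ml = volume_ml,
             cells = cells, stringsAsFactors = FALSE)
}

#' @rdname protocol
#' @param time_h Event time, h.
#' @param cells Inoculum size, cells per vial.
#' @export
ev_inoculate <- function(time_h, cells) {
  if (cells <= 0) stop("inoculum must be positive")
  .ev(time_h, "inoculate", cells = cells)
}

#' @rdname protocol
#' @param species Gas species name (O2, NO, N2O, N2, He).
#' @param ppmv Target added mixing ratio (converted to umol at the geometry).
#' @param amount_umol Amount to add, umol (alternative to `ppmv`).
#' @export
ev_inject_gas <- function(time_h, species, ppmv = NULL, amount_umol = NULL) {
  if (is.null(ppmv) == is.null(amount_umol))
    stop("give exactly one of 'ppmv' or 'amount_umol'")
  .ev(time_h, "inject_gas", species = species,
      ppmv = if (is.null(ppmv)) NA_real_ else ppmv,
      amount_umol = if (is.null(amount_umol)) NA_real_ else amount_umol)
}

#' @rdname protocol
#' @param volume_ml Sampled (or harvested) volume, mL.
#' @export
ev_sample_headspace <- function(time_h, volume_ml = 1) {
  if (volume_ml <= 0) stop("sample volume must be positive")
  .ev(time_h, "sample_headspace", volume_ml = volume_ml)
}

#' @rdname protocol
#' @export
ev_harvest_liquid <- function(time_h, volume_ml) {
  if (volume_ml <= 0) stop("harvest volume must be positive")
  .ev(time_h, "harvest_liquid", volume_ml = volume_ml)
}

#' @rdname protocol
#' @export
ev_end <- function(time_h) .ev(time_h, "end")

#' Standard batch incubation protocol
#'
#' The routine used throughout: optional gas injections at time zero,
#' inoculation at time zero, headspace sampling at fixed intervals, and a
#' defined end.
#'
#' @param duration_h Length of the incubation, h.
#' @param sample_every_h Headspace sampling interval, h (default 3).
#' @param sample_ml Sampled aliquot per cycle, mL (default 1).
#' @param inoculum_cells Cells added at time zero; `0` for an abiotic vial.
#' @param o2_ppmv,n2o_ppmv Initial headspace injections (0 = none).
#' @param harvests Optional data.frame with `time_h` and `volume_ml` of
#'   liquid harvests.
#' @return A [protocol()].
#' @export
standard_protocol <- function(duration_h = 90, sample_every_h = 3,
                              sample_ml = 1, inoculum_cells = 2e8,
                              o2_ppmv = 10000, n2o_ppmv = 0,
                              harvests = NULL) {
  evs <- list()
  if (o2_ppmv > 0) evs <- c(evs, list(ev_inject_gas(0, "O2", ppmv = o2_ppmv)))
  if (n2o_ppmv > 0) evs <- c(evs, list(ev_inject_gas(0, "N2O",
                                                     ppmv = n2o_ppmv)))
  if (inoculum_cells > 0)
    evs <- c(evs, list(ev_inoculate(0, inoculum_cells)))
  st <- seq(sample_every_h, duration_h, by = sample_every_h)
  samp <- lapply(st, ev_sample_headspace, volume_ml = sample_ml)
  evs <- c(evs, samp)
  if (!is.null(harvests))
    evs <- c(evs, lapply(seq_len(nrow(harvests)), function(i)
      ev_harvest_liquid(harvests$time_h[i], harvests$volume_ml[i])))
  evs <- c(evs, list(ev_end(duration_h)))
  ord <- order(vapply(evs, function(e) e$time_h, numeric(1)))
  protocol(evs[ord])
}
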