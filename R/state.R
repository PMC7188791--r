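#' State vector layout of one vial
#'
#' Order and naming of the state variables: `*_g` headspace amounts
#' (umol vial^-1), `*_l` liquid concentrations (uM), `biomass`
#' (cells vial^-1), `E_*` per-cell enzyme capacities
#' (fmol e- cell^-1 h^-1), `m_*` per-cell transcript levels
#' (copies cell^-1).
#' @export
STATE_NAMES <- c("O2_g", "NO_g", "N2O_g", "N2_g", "He_g",
                 "O2_l", "NO_l", "N2O_l", "NO3_l", "NO2_l",
                 "biomass",
                 "E_NAR", "E_NIR", "E_NOR", "E_N2OR",
                 "m_narG", "m_nirK", "m_norZ", "m_nosZ")

#' Construct the instantaneous state of one vial
#'
#' Builds the named state vector used by the simulator.  Helium fills the
#' headspace up to the geometry pressure after the named gases are placed.
#' All amounts are absolute (umol per vial); mixing ratios are derived.
#'
#' @param geometry A [vial_geometry()].
#' @param o2_ppmv,n2o_ppmv,no_ppmv Initial headspace mixing ratios.
#' @param no3_mM,no2_mM Medium amendments, mM (stored as uM in state).
#' @param biomass Cells per vial (0 for an uninoculated vial).
#' @param enzymes Named per-cell enzyme capacities (NAR, NIR, NOR, N2OR),
#'   fmol e- cell^-1 h^-1; defaults are the aerobic pre-culture basal pools.
#' @param transcripts Named per-cell transcript levels (narG, nirK, norZ,
#'   nosZ), copies per cell.
#' @return Named numeric vector of class `vial_state`.
#' @export
vial_state <- function(geometry = vial_geometry(),
                       o2_ppmv = 0, n2o_ppmv = 0, no_ppmv = 0,
                       no3_mM = 0, no2_mM = 0, biomass = 0,
                       enzymes = c(NAR = 0.001, NIR = 5e-4, NOR = 0.002,
                                   N2OR = 0.001),
                       transcripts = c(narG = 0.01, nirK = 0.01,
                                       norZ = 0.01, nosZ = 0.01)) {
  if (no3_mM < 0 || no2_mM < 0 || biomass < 0)
    stop("amendments and biomass must be non-negative")
  cap <- headspace_capacity_umol(geometry)
  o2 <- ppmv_to_amount(o2_ppmv, geometry)
  n2o <- ppmv_to_amount(n2o_ppmv, geometry)
  no <- ppmv_to_amount(no_ppmv, geometry)
  he <- max(cap - o2 - n2o - no, 0)
  s <- c(O2_g = o2, NO_g = no, N2O_g = n2o, N2_g = 0, He_g = he,
         O2_l = 0, NO_l = 0, N2O_l = 0,
         NO3_l = no3_mM * 1000, NO2_l = no2_mM * 1000,
         biomass = biomass,
         E_NAR = unname(enzymes[["NAR"]]), E_NIR = unname(enzymes[["NIR"]]),
         E_NOR = unname(enzymes[["NOR"]]),
         E_N2OR = unname(enzymes[["N2OR"]]),
         m_narG = unname(transcripts[["narG"]]),
         m_nirK = unname(transcripts[["nirK"]]),
         m_norZ = unname(transcripts[["norZ"]]),
         m_nosZ = unname(transcripts[["nosZ"]]))
  if (any(s < 0)) stop("state variables must be non-negative")
  class(s) <- c("vial_state", "numeric")
  s
}

#' Total nitrogen in the vial, umol N
#'
#' Sums nitrogen over both phases on an N-atom basis:
#' NO3- + NO2- + NO + 2 N2O + 2 N2, liquid concentrations weighted by the
#' liquid volume.
#'
#' @param state A state vector (named as in [vial_state()]).
#' @param geometry A [vial_geometry()].
#' @return Total N, umol.
#' @export
total_nitrogen <- function(state, geometry) {
  vl <- geometry$liquid_ml / 1000
  unname(state[["NO_g"]] + 2 * state[["N2O_g"]] + 2 * state[["N2_g"]] +
         (state[["NO3_l"]] + state[["NO2_l"]] + state[["NO_l"]] +
          2 * state[["N2O_l"]]) * vl)
}

#' Report per-cell transcripts as copies per ng total RNA
#'
#' Presentation-layer conversion using the fixed RNA-per-cell constant of the
#' regulatory parameter set.
#'
#' @param transcripts_per_cell Numeric vector of per-cell transcript levels.
#' @param reg A [regulatory_params()].
#' @return Copies per ng RNA.
#' @export
transcripts_per_ng_rna <- function(transcripts_per_cell,
                                   reg = regulatory_params()) {
  transcripts_per_cell / reg$rna_ng_per_cell
}
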