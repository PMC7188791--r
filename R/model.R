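#' Transcriptional activation signals and the micro-oxic synthesis gate
#'
#' Maps the instantaneous liquid chemistry onto per-gene transcription
#' activation factors in \[0, 1\] and the post-transcriptional synthesis gate
#' `g_syn`:
#' * `narG`, `nosZ` are repressed by O2 (Hill repression in liquid O2 via the
#'   hypoxia sensor) and need no NO;
#' * `nirK`, `norZ` are activated by NO (Michaelian in liquid NO); optionally
#'   nitrite also activates `nirK`;
#' * `nosZ` takes the maximum of its hypoxia and NO terms (dual induction);
#' * `g_syn = [O2]/([O2] + K_syn)`: de-novo enzyme synthesis requires low-uM
#'   oxygen.
#'
#' @param state A state vector (see [vial_state()]).
#' @param reg A [regulatory_params()].
#' @return Named vector: narG, nirK, norZ, nosZ activations and g_syn.
#' @export
regulation_signals <- function(state, reg = regulatory_params()) {
  o2 <- max(state[["O2_l"]], 0)
  no <- max(state[["NO_l"]], 0)
  no2 <- max(state[["NO2_l"]], 0)
  kh <- reg$K_hypoxia^reg$hill_hypoxia
  a_hyp <- kh / (kh + o2^reg$hill_hypoxia)
  a_no <- no / (reg$K_NO_sensor + no)
  a_no2 <- if (reg$nirK_nitrite_induction) no2 / (reg$K_NO2_sensor + no2)
           else 0
  c(narG = a_hyp,
    nirK = max(a_no, a_no2),
    norZ = a_no,
    nosZ = max(a_hyp, a_no),
    g_syn = if (reg$microoxic_gate) o2 / (o2 + reg$K_syn) else 1)
}

## O2 inhibition factor with Inf meaning "no inhibition".
.inhib <- function(KI, o2) if (is.infinite(KI)) 1 else KI / (KI + o2)

#' Instantaneous process rates of one vial
#'
#' Enzymatic electron rates (umol e- vial^-1 h^-1) for aerobic respiration
#' and the four denitrification steps, and gas-transfer fluxes (umol h^-1,
#' positive into the liquid) for O2, NO and N2O.  Each enzymatic rate is
#' biomass x per-cell capacity x Michaelis-Menten substrate term x O2
#' inhibition x NO toxicity; aerobic respiration is additionally multiplied
#' by `exp(-k_nit * [NO2-] mM)` (log-linear nitrite toxicity).  The four
#' denitrification steps are jointly scaled by a shared electron-supply
#' saturation `e_supply_N / (e_supply_N + potential)` (see
#' [kinetic_params()]); set `e_supply_N = Inf` for purely enzyme-limited
#' kinetics.  Transfer flux
#' is `kLa * (c_eq - c) * V_L` with the Henry-equilibrium concentration
#' `c_eq` computed from the current headspace partial pressure.
#'
#' N2 and He are modelled as headspace-only pools (N2 produced by N2O
#' reduction is routed directly to the headspace), so they carry no transfer
#' flux.
#'
#' @param state State vector.
#' @param kin A [kinetic_params()].
#' @param geometry A [vial_geometry()].
#' @param henry Optional precomputed Henry coefficients named O2, NO, N2O
#'   (mol L^-1 atm^-1); computed from the geometry when `NULL`.
#' @return Named vector: `v_O2, v_NAR, v_NIR, v_NOR, v_N2OR` (umol e- h^-1)
#'   and `F_O2, F_NO, F_N2O` (umol h^-1 into the liquid).
#' @export
process_rates <- function(state, kin = kinetic_params(),
                          geometry = vial_geometry(), henry = NULL) {
  if (is.null(henry))
    henry <- henry_coefficient(c("O2", "NO", "N2O"), geometry$temperature_K,
                               geometry$salt_load)
  o2 <- max(state[["O2_l"]], 0); no <- max(state[["NO_l"]], 0)
  n2o <- max(state[["N2O_l"]], 0); no3 <- max(state[["NO3_l"]], 0)
  no2 <- max(state[["NO2_l"]], 0)
  b <- max(state[["biomass"]], 0) * 1e-9   # cells x fmol -> umol
  tox <- .inhib(kin$K_NO_tox, no)
  v_O2 <- b * kin$vmax_O2 * o2 / (kin$K_O2 + o2) * tox *
    exp(-kin$k_nit * no2 / 1000)
  e_nar <- min(max(state[["E_NAR"]], 0), kin$vmax_NAR)
  e_nir <- min(max(state[["E_NIR"]], 0), kin$vmax_NIR)
  e_nor <- min(max(state[["E_NOR"]], 0), kin$vmax_NOR)
  e_n2or <- min(max(state[["E_N2OR"]], 0), kin$vmax_N2OR)
  v_NAR <- b * e_nar * no3 / (kin$K_NO3 + no3) *
    .inhib(kin$KI_O2_NAR, o2) * tox
  v_NIR <- b * e_nir * no2 / (kin$K_NO2 + no2) *
    .inhib(kin$KI_O2_NIR, o2) * tox
  v_NOR <- b * e_nor * no / (kin$K_NO + no) *
    .inhib(kin$KI_O2_NOR, o2) * tox
  v_N2OR <- b * e_n2or * n2o / (kin$K_N2O + n2o) *
    .inhib(kin$KI_O2_N2OR, o2) * tox
  ## shared electron-supply ceiling of the denitrification chain: the
  ## reductase pool sets the potential, central metabolism caps the per-cell
  ## realized flow; the same saturation factor scales all four steps
  if (is.finite(kin$e_supply_N) && b > 0) {
    pot <- (v_NAR + v_NIR + v_NOR + v_N2OR) / b    # fmol e- cell^-1 h^-1
    s_sup <- kin$e_supply_N / (kin$e_supply_N + pot)
    v_NAR <- v_NAR * s_sup; v_NIR <- v_NIR * s_sup
    v_NOR <- v_NOR * s_sup; v_N2OR <- v_N2OR * s_sup
  }
  ## gas transfer: headspace partial pressure -> equilibrium liquid conc
  vh_l <- geometry$headspace_ml / 1000
  vl_l <- geometry$liquid_ml / 1000
  rt <- R_GAS * geometry$temperature_K
  p <- c(state[["O2_g"]], state[["NO_g"]], state[["N2O_g"]]) * 1e-6 * rt / vh_l
  c_eq <- unname(henry) * p * 1e6                      # uM
  kla <- c(kin$kLa_O2, kin$kLa_NO, kin$kLa_N2O)
  f <- kla * (c_eq - c(state[["O2_l"]], state[["NO_l"]],
                       state[["N2O_l"]])) * vl_l        # umol/h
  c(v_O2 = v_O2, v_NAR = v_NAR, v_NIR = v_NIR, v_NOR = v_NOR,
    v_N2OR = v_N2OR, F_O2 = f[1], F_NO = f[2], F_N2O = f[3])
}

#' Time derivative of the vial state
#'
#' Assembles the full mass balance: the N reaction chain
#' NO3- -> NO2- -> NO -> 1/2 N2O -> 1/2 N2 (N-atom stoichiometry), two-phase
#' gas exchange, biomass growth coupled to the total electron flow through
#' the yield, and the regulatory model for per-cell transcripts (regulated
#' synthesis, first-order decay, growth dilution) and per-cell enzyme
#' capacities (translation gated by `g_syn`, first-order degradation, growth
#' dilution).
#'
#' @inheritParams process_rates
#' @param reg A [regulatory_params()].
#' @return Named derivative vector (same layout as the state).
#' @export
state_derivative <- function(state, kin = kinetic_params(),
                             reg = regulatory_params(),
                             geometry = vial_geometry(), henry = NULL) {
  r <- process_rates(state, kin, geometry, henry)
  sig <- regulation_signals(state, reg)
  vl_l <- geometry$liquid_ml / 1000
  ## N fluxes through the chain, umol N h^-1
  r_nar <- r[["v_NAR"]] / 2   # 2 e- per NO3- -> NO2-
  r_nir <- r[["v_NIR"]]       # 1 e- per NO2- -> NO
  r_nor <- r[["v_NOR"]]       # 1 e- per NO -> 1/2 N2O
  r_n2or <- r[["v_N2OR"]]     # 1 e- per N (2 per N2O molecule)
  v_tot <- r[["v_O2"]] + r[["v_NAR"]] + r[["v_NIR"]] + r[["v_NOR"]] +
    r[["v_N2OR"]]
  mu <- kin$yield * v_tot / max(state[["biomass"]], 1)
  genes <- c("narG", "nirK", "norZ", "nosZ")
  m <- unname(state[c("m_narG", "m_nirK", "m_norZ", "m_nosZ")])
  dm <- reg$alpha_basal + unname(reg$alpha_max) * unname(sig[genes]) -
    (reg$delta_m + mu) * m
  e <- unname(state[c("E_NAR", "E_NIR", "E_NOR", "E_N2OR")])
  de <- unname(reg$k_transl) * m * sig[["g_syn"]] -
    (unname(reg$k_degE) + mu) * e
  d <- c(O2_g = -r[["F_O2"]],
         NO_g = -r[["F_NO"]],
         N2O_g = -r[["F_N2O"]],
         N2_g = r_n2or / 2,
         He_g = 0,
         O2_l = (r[["F_O2"]] - r[["v_O2"]] / 4) / vl_l,
         NO_l = (r[["F_NO"]] + r_nir - r_nor) / vl_l,
         N2O_l = (r[["F_N2O"]] + r_nor / 2 - r_n2or / 2) / vl_l,
         NO3_l = -r_nar / vl_l,
         NO2_l = (r_nar - r_nir) / vl_l,
         biomass = kin$yield * v_tot,
         E_NAR = de[1], E_NIR = de[2], E_NOR = de[3], E_N2OR = de[4],
         m_narG = dm[1], m_nirK = dm[2], m_norZ = dm[3], m_nosZ = dm[4])
  d
}
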