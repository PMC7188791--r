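#' Kinetic parameters of the vial model
#'
#' Per-cell maximal electron rates (fmol e- cell^-1 h^-1) and half-saturation
#' constants (uM, liquid phase) for aerobic respiration and the four
#' denitrification steps, inhibition constants, toxicity coefficients, the
#' cell yield per electron, and volumetric gas-transfer coefficients.
#'
#' For the four reductases the `vmax_*` values are ceilings on the per-cell
#' enzyme capacity (the instantaneous capacity is a state variable built by
#' the regulatory model and clamped at the ceiling).  Aerobic respiration is
#' treated as constitutive machinery at `vmax_O2`.
#'
#' Defaults are a single frozen calibration chosen to reproduce the
#' qualitative behaviour of batch denitrification in a haloarchaeon:
#' aerobic specific growth about 0.2 h^-1, anoxic about 0.1 h^-1, steady NO
#' in the tens of nM, and respiratory arrest near 18 uM NO.
#'
#' @param vmax_O2,K_O2 Aerobic respiration: max e- rate and O2 half-saturation.
#' @param vmax_NAR,K_NO3 Nitrate reductase capacity target and NO3- half-sat.
#' @param vmax_NIR,K_NO2 Nitrite reductase capacity target and NO2- half-sat.
#' @param vmax_NOR,K_NO Nitric oxide reductase capacity target and NO half-sat.
#' @param vmax_N2OR,K_N2O Nitrous oxide reductase capacity target and N2O
#'   half-sat.
#' @param KI_O2_NAR,KI_O2_NIR,KI_O2_NOR,KI_O2_N2OR O2 inhibition constants
#'   (uM) on catalysis; `Inf` disables the inhibition.  The NAR term stands
#'   for electron competition by the terminal oxidase, which keeps nitrate
#'   respiration marginal until O2 falls to low-uM levels.
#' @param K_NO_tox NO toxicity constant (uM): non-competitive inhibition
#'   `K/(K+[NO])` applied to all respiration.
#' @param k_nit Aerobic nitrite toxicity coefficient (per mM): aerobic e- rate
#'   is multiplied by `exp(-k_nit * [NO2-] mM)`.
#' @param e_supply_N Per-cell electron-supply ceiling of the denitrification
#'   chain, fmol e- cell^-1 h^-1 (`Inf` = none).  The reductase pool built
#'   during the micro-oxic transition normally exceeds this ceiling, so
#'   anaerobic growth is supply-limited and exponential while the per-cell
#'   enzyme margin is diluted by division; respiration declines only once
#'   the pool drops below the ceiling.
#' @param yield Cell yield per electron, cells per umol e-.
#' @param kLa_O2,kLa_NO,kLa_N2O Volumetric gas-transfer coefficients, h^-1.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(vmax_O2 = 7.2, K_O2 = 0.5,
                           vmax_NAR = 40, K_NO3 = 50,
                           vmax_NIR = 100, K_NO2 = 20,
                           vmax_NOR = 300, K_NO = 0.15,
                           vmax_N2OR = 100, K_N2O = 0.1,
                           KI_O2_NAR = 1, KI_O2_NIR = 0.05, KI_O2_NOR = 0.05,
                           KI_O2_N2OR = 0.2,
                           K_NO_tox = 0.9, k_nit = 0.11,
                           e_supply_N = 5, yield = 3e7,
                           kLa_O2 = 50, kLa_NO = 50, kLa_N2O = 50) {
  p <- list(vmax_O2 = vmax_O2, K_O2 = K_O2, vmax_NAR = vmax_NAR,
            K_NO3 = K_NO3, vmax_NIR = vmax_NIR, K_NO2 = K_NO2,
            vmax_NOR = vmax_NOR, K_NO = K_NO, vmax_N2OR = vmax_N2OR,
            K_N2O = K_N2O, KI_O2_NAR = KI_O2_NAR, KI_O2_NIR = KI_O2_NIR,
            KI_O2_NOR = KI_O2_NOR, KI_O2_N2OR = KI_O2_N2OR, K_NO_tox = K_NO_tox, k_nit = k_nit,
            e_supply_N = e_supply_N, yield = yield, kLa_O2 = kLa_O2,
            kLa_NO = kLa_NO, kLa_N2O = kLa_N2O)
  finite_pos <- setdiff(names(p), c("KI_O2_NAR", "KI_O2_NIR", "KI_O2_NOR",
                                    "KI_O2_N2OR", "K_NO_tox", "k_nit",
                                    "e_supply_N"))
  if (is.na(p$e_supply_N) || p$e_supply_N <= 0)
    stop("e_supply_N must be positive (Inf = no ceiling)")
  for (nm in finite_pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("kinetic parameter '", nm, "' must be a positive finite number")
  for (nm in c("KI_O2_NAR", "KI_O2_NIR", "KI_O2_NOR", "KI_O2_N2OR",
               "K_NO_tox"))
    if (is.na(p[[nm]]) || p[[nm]] <= 0)
      stop("inhibition constant '", nm, "' must be positive (Inf = none)")
  if (k_nit < 0) stop("k_nit must be non-negative")
  structure(p, class = "kinetic_params")
}

#' Regulatory parameters: transcription, translation and the micro-oxic gate
#'
#' Encodes the tentative regulatory circuit: a hypoxia sensor represses
#' transcription of `narG` and `nosZ` under oxic conditions (Hill repression
#' in liquid O2); an NO sensor activates `nirK`, `norZ` and (as a second
#' input) `nosZ`; optionally nitrite also activates `nirK`.  Enzyme synthesis
#' (translation) is additionally gated by the micro-oxic factor
#' `g_syn = [O2] / ([O2] + K_syn)`: de-novo synthesis of the reductases
#' requires low-uM oxygen and stops under strict anoxia, while transcription
#' itself is unaffected (the gate is post-transcriptional).
#'
#' @param K_hypoxia Hypoxia sensor half-saturation, uM O2.
#' @param hill_hypoxia Hill coefficient of the O2 repression.
#' @param K_NO_sensor NO sensor half-saturation, uM NO.
#' @param nirK_nitrite_induction Logical; let nitrite also activate `nirK`.
#' @param K_NO2_sensor Nitrite activation constant for `nirK`, uM (used only
#'   if `nirK_nitrite_induction` is `TRUE`).
#' @param alpha_basal Basal transcription rate, transcripts cell^-1 h^-1.
#' @param alpha_max Maximal regulated transcription rate (same units), named
#'   per gene.
#' @param delta_m Transcript first-order decay, h^-1.
#' @param k_transl Translation rates: enzyme capacity (fmol e- cell^-1 h^-1)
#'   produced per transcript per hour, named per gene.
#' @param k_degE Enzyme first-order degradation, h^-1, named per enzyme.
#' @param K_syn Micro-oxic synthesis half-saturation, uM O2 (> 0).
#' @param microoxic_gate Logical; `FALSE` forces `g_syn = 1` (no micro-oxic
#'   gating of enzyme synthesis), for counterfactual runs.
#' @param rna_ng_per_cell Total RNA per cell, ng; presentation-only constant
#'   used to report transcripts as copies per ng RNA.
#' @return Object of class `regulatory_params`.
#' @export
regulatory_params <- function(K_hypoxia = 3, hill_hypoxia = 2,
                              K_NO_sensor = 0.02,
                              nirK_nitrite_induction = FALSE,
                              K_NO2_sensor = 100,
                              alpha_basal = 0.02,
                              alpha_max = c(narG = 20, nirK = 20, norZ = 20,
                                            nosZ = 20),
                              delta_m = 2,
                              k_transl = c(narG = 0.9, nirK = 2.2,
                                           norZ = 5.5, nosZ = 1.9),
                              k_degE = c(NAR = 0.01, NIR = 0.05, NOR = 0.025,
                                         N2OR = 0.025),
                              K_syn = 0.2, microoxic_gate = TRUE,
                              rna_ng_per_cell = 1e-4) {
  genes <- c("narG", "nirK", "norZ", "nosZ")
  enz <- c("NAR", "NIR", "NOR", "N2OR")
  alpha_max <- alpha_max[genes]; k_transl <- k_transl[genes]
  k_degE <- k_degE[enz]
  if (anyNA(alpha_max) || anyNA(k_transl) || anyNA(k_degE))
    stop("alpha_max/k_transl must be named for narG, nirK, norZ, nosZ; ",
         "k_degE for NAR, NIR, NOR, N2OR")
  p <- list(K_hypoxia = K_hypoxia, hill_hypoxia = hill_hypoxia,
            K_NO_sensor = K_NO_sensor,
            nirK_nitrite_induction = isTRUE(nirK_nitrite_induction),
            K_NO2_sensor = K_NO2_sensor, alpha_basal = alpha_basal,
            alpha_max = alpha_max, delta_m = delta_m, k_transl = k_transl,
            k_degE = k_degE, K_syn = K_syn,
            microoxic_gate = isTRUE(microoxic_gate),
            rna_ng_per_cell = rna_ng_per_cell)
  num <- unlist(p[setdiff(names(p), c("nirK_nitrite_induction",
                                      "microoxic_gate"))])
  if (any(!is.finite(num)) || any(num < 0))
    stop("regulatory parameters must be finite and non-negative")
  if (K_syn <= 0) stop("K_syn must be positive")
  structure(p, class = "regulatory_params")
}

#' Read or write model parameters as a YAML file
#'
#' Parameters are stored under two top-level keys, `kinetic` and
#' `regulatory`, each a flat map of the constructor arguments of
#' [kinetic_params()] and [regulatory_params()].  The shipped default
#' calibration lives at `system.file("extdata", "default_params.yaml",
#' package = "denitvial")`.
#'
#' @param path File path.
#' @return `read_params()`: list with elements `kinetic` and `regulatory`.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!all(c("kinetic", "regulatory") %in% names(raw)))
    stop("parameter file must contain 'kinetic' and 'regulatory' sections")
  kin <- do.call(kinetic_params, lapply(raw$kinetic, .num_inf))
  rg <- raw$regulatory
  for (nm in c("alpha_max", "k_transl", "k_degE"))
    rg[[nm]] <- unlist(rg[[nm]])
  reg <- do.call(regulatory_params, rg)
  list(kinetic = kin, regulatory = reg)
}

.num_inf <- function(x) {
  if (is.character(x) && length(x) == 1L && x %in% c("Inf", ".inf")) Inf else x
}

#' @rdname read_params
#' @param kinetic A [kinetic_params()] object.
#' @param regulatory A [regulatory_params()] object.
#' @export
write_params <- function(kinetic, regulatory, path) {
  stopifnot(inherits(kinetic, "kinetic_params"),
            inherits(regulatory, "regulatory_params"))
  to_list <- function(p) lapply(unclass(p), function(x) {
    if (is.numeric(x) && any(is.infinite(x))) "Inf"
    else if (!is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(list(kinetic = to_list(kinetic),
                        regulatory = to_list(regulatory)), path)
  invisible(path)
}

#' Default calibrated parameters
#'
#' The frozen default calibration, identical to the constructors' defaults
#' and mirrored in the shipped `default_params.yaml`.
#'
#' @return list with `kinetic` and `regulatory` elements.
#' @export
default_params <- function() {
  list(kinetic = kinetic_params(), regulatory = regulatory_params())
}
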