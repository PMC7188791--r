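## Ideal-gas constant, L atm mol^-1 K^-1 (fixed; all headspace bookkeeping
## uses absolute amounts in umol, mixing ratios are presentation only).
R_GAS <- 0.0820574

.denitvial <- new.env(parent = emptyenv())

#' Gas species constants
#'
#' Reads the shipped table of gas constants: freshwater Henry solubility at a
#' reference temperature (`solubility_ref`, mol L^-1 atm^-1 at `T_ref` K), the
#' van't Hoff temperature coefficient (`vant_hoff_K`, K), the Setschenow
#' salting-out coefficient (`setschenow`, L mol^-1 of NaCl-equivalent salt),
#' and the number of nitrogen atoms per molecule (`n_atoms`).
#'
#' Freshwater solubilities and van't Hoff coefficients are the standard
#' compilation values (Sander 2015, Atmos. Chem. Phys. 15:4399).  The
#' Setschenow coefficient is shared across gases and calibrated so that 1 vol%
#' O2 at 308.15 K over a 20% w/v salt medium equilibrates to about 9 uM
#' dissolved O2, the system's one solubility anchor.  Users may supply their
#' own CSV with the same columns to override any constant.
#'
#' @param path Optional path to a replacement CSV with the same columns.
#' @return data.frame with one row per species (O2, NO, N2O, N2, He).
#' @export
gas_species_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.denitvial$species)) return(.denitvial$species)
    path <- system.file("extdata", "gas_species.csv", package = "denitvial",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .denitvial$species <- tab
    return(tab)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "solubility_ref", "T_ref", "vant_hoff_K", "setschenow",
            "n_atoms")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("species table is missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$solubility_ref <= 0))
    stop("species solubilities must be positive")
  tab
}

#' Vial geometry and physical conditions
#'
#' A closed two-phase system at fixed temperature and pressure: a serum vial
#' of `total_ml` holding `liquid_ml` of salt medium, the rest headspace.
#'
#' @param total_ml Total vial volume, mL (default 120).
#' @param liquid_ml Liquid (medium) volume, mL (default 50).
#' @param temperature_K Temperature, K (default 308.15, i.e. 35 C).
#' @param pressure_atm Headspace pressure, atm (default 1).
#' @param salt_load Salt load of the medium, w/v fraction (default 0.20).
#' @return Object of class `vial_geometry`.
#' @export
vial_geometry <- function(total_ml = 120, liquid_ml = 50,
                          temperature_K = 308.15, pressure_atm = 1,
                          salt_load = 0.20) {
  if (total_ml <= 0 || liquid_ml <= 0 || temperature_K <= 0 ||
      pressure_atm <= 0 || salt_load < 0)
    stop("invalid geometry: volumes, temperature and pressure must be positive")
  headspace_ml <- total_ml - liquid_ml
  if (headspace_ml <= 0)
    stop("invalid geometry: liquid volume must be less than total volume")
  structure(list(total_ml = total_ml, liquid_ml = liquid_ml,
                 headspace_ml = headspace_ml, temperature_K = temperature_K,
                 pressure_atm = pressure_atm, salt_load = salt_load),
            class = "vial_geometry")
}

#' @export
print.vial_geometry <- function(x, ...) {
  cat(sprintf(
    "<vial_geometry> %g mL vial, %g mL liquid / %g mL headspace, %g K, %g atm, salt %g w/v\n",
    x$total_ml, x$liquid_ml, x$headspace_ml, x$temperature_K, x$pressure_atm,
    x$salt_load))
  invisible(x)
}

## Total headspace capacity at geometry pressure, umol.
headspace_capacity_umol <- function(geometry) {
  geometry$pressure_atm * (geometry$headspace_ml / 1000) /
    (R_GAS * geometry$temperature_K) * 1e6
}

#' Convert a headspace mixing ratio to an absolute amount
#'
#' Ideal-gas conversion of a mixing ratio (ppmv of the headspace at the
#' geometry's pressure and temperature) to umol in the headspace.
#'
#' @param ppmv Mixing ratio, parts per million by volume (0 to 1e6).
#' @param geometry A [vial_geometry()].
#' @return Amount in the headspace, umol.
#' @export
ppmv_to_amount <- function(ppmv, geometry = vial_geometry()) {
  stopifnot(inherits(geometry, "vial_geometry"))
  if (any(!is.finite(ppmv)) || any(ppmv < 0) || any(ppmv > 1e6))
    stop("mixing ratio must be within [0, 1e6] ppmv")
  ppmv * 1e-6 * headspace_capacity_umol(geometry)
}

#' @rdname ppmv_to_amount
#' @param amount_umol Amount in headspace, umol.
#' @export
amount_to_ppmv <- function(amount_umol, geometry = vial_geometry()) {
  stopifnot(inherits(geometry, "vial_geometry"))
  if (any(!is.finite(amount_umol)) || any(amount_umol < 0))
    stop("amount must be non-negative")
  amount_umol / headspace_capacity_umol(geometry) * 1e6
}

#' Effective Henry solubility of a gas in the vial medium
#'
#' Freshwater solubility at the reference temperature, van't Hoff corrected to
#' `temperature_K`, then reduced by the Setschenow salting-out factor
#' `exp(-ks * c_salt)` where the salt molarity is taken as NaCl-equivalent,
#' `salt_load * 1000 / 58.44` mol/L.
#'
#' @param species Character vector of species names (O2, NO, N2O, N2, He).
#' @param temperature_K Temperature, K (273-373).
#' @param salt_load Salt w/v fraction of the medium.
#' @param table Species constants, see [gas_species_table()].
#' @return Solubility, mol L^-1 atm^-1 (named by species).
#' @export
henry_coefficient <- function(species, temperature_K = 308.15, salt_load = 0,
                              table = gas_species_table()) {
  if (temperature_K < 273 || temperature_K > 373)
    stop("temperature must be within 273-373 K")
  idx <- match(species, table$name)
  if (anyNA(idx))
    stop("unknown gas species: ",
         paste(species[is.na(idx)], collapse = ", "))
  h_fresh <- table$solubility_ref[idx] *
    exp(table$vant_hoff_K[idx] * (1 / temperature_K - 1 / table$T_ref[idx]))
  salt_molar <- salt_load * 1000 / 58.44
  h <- h_fresh * exp(-table$setschenow[idx] * salt_molar)
  names(h) <- species
  h
}

#' Equilibrium partitioning of a gas between headspace and liquid
#'
#' Distributes a total amount over the two phases so that the dissolved
#' concentration obeys Henry's law against the resulting headspace partial
#' pressure.  Mass is conserved exactly:
#' `headspace_umol + liquid_uM * liquid_L = total_umol`.
#'
#' @param total_umol Total amount of the gas in the vial, umol.
#' @param species Species name.
#' @inheritParams henry_coefficient
#' @param geometry A [vial_geometry()].
#' @return list with `headspace_umol` and `liquid_uM`.
#' @export
equilibrium_partition <- function(total_umol, species,
                                  geometry = vial_geometry(),
                                  table = gas_species_table()) {
  if (any(total_umol < 0)) stop("total amount must be non-negative")
  h <- henry_coefficient(species, geometry$temperature_K, geometry$salt_load,
                         table)
  ## dissolved/headspace amount ratio: H * R * T * V_L / V_H
  ratio <- h * R_GAS * geometry$temperature_K *
    geometry$liquid_ml / geometry$headspace_ml
  headspace <- total_umol / (1 + ratio)
  p_atm <- headspace * 1e-6 * R_GAS * geometry$temperature_K /
    (geometry$headspace_ml / 1000)
  liquid_uM <- h * p_atm * 1e6
  list(headspace_umol = unname(headspace), liquid_uM = unname(liquid_uM))
}
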