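## Kinetics with all inhibitions and the supply ceiling disabled, so each
## rate reduces to biomass x capacity x Michaelis-Menten.
kin_plain <- kinetic_params(KI_O2_NAR = Inf, KI_O2_NIR = Inf,
                            KI_O2_NOR = Inf, KI_O2_N2OR = Inf,
                            K_NO_tox = Inf, k_nit = 0, e_supply_N = Inf)

test_that("each rate sits at half-maximum when substrate equals its K", {
  kin <- kin_plain
  b <- 1e9
  st <- make_state(o2_l = kin$K_O2, no3_l = kin$K_NO3, no2_l = kin$K_NO2,
                   no_l = kin$K_NO, n2o_l = kin$K_N2O, biomass = b,
                   E = c(NAR = 2, NIR = 2, NOR = 2, N2OR = 2))
  r <- process_rates(st, kin)
  expect_equal(r[["v_O2"]], b * 1e-9 * kin$vmax_O2 / 2)
  expect_equal(r[["v_NAR"]], b * 1e-9 * 2 / 2)
  expect_equal(r[["v_NIR"]], b * 1e-9 * 2 / 2)
  expect_equal(r[["v_NOR"]], b * 1e-9 * 2 / 2)
  expect_equal(r[["v_N2OR"]], b * 1e-9 * 2 / 2)
})

test_that("the log-linear nitrite toxicity halves aerobic respiration at ln2/k_nit", {
  kin <- kinetic_params(K_NO_tox = Inf, e_supply_N = Inf)
  no2_mM <- log(2) / kin$k_nit
  st0 <- make_state(o2_l = 100, biomass = 1e9)
  st1 <- make_state(o2_l = 100, no2_l = no2_mM * 1000, biomass = 1e9)
  r0 <- process_rates(st0, kin)
  r1 <- process_rates(st1, kin)
  expect_equal(r1[["v_O2"]] / r0[["v_O2"]], 0.5, tolerance = 1e-12)
})

test_that("18 uM NO arrests all respiration below 5% of the uninhibited rate", {
  kin <- kinetic_params()   # default NO toxicity constant
  st <- make_state(o2_l = 100, no3_l = 1e5, no2_l = 1e4, no_l = 18,
                   n2o_l = 10, biomass = 1e9,
                   E = c(NAR = 5, NIR = 5, NOR = 5, N2OR = 5))
  kin_notox <- kin; kin_notox$K_NO_tox <- Inf
  r_tox <- process_rates(st, kin)
  r_free <- process_rates(st, kin_notox)
  for (v in c("v_O2", "v_NAR", "v_NIR", "v_NOR", "v_N2OR"))
    expect_lt(r_tox[[v]] / r_free[[v]], 0.05)
})

test_that("the electron-supply ceiling rescales the chain without changing shares", {
  kin <- kinetic_params(KI_O2_NIR = Inf, KI_O2_NOR = Inf, KI_O2_N2OR = Inf,
                        K_NO_tox = Inf)
  st <- make_state(no3_l = 1e4, no2_l = 1e4, no_l = 10, n2o_l = 10,
                   biomass = 1e9, E = c(NAR = 8, NIR = 4, NOR = 6, N2OR = 2))
  kin_inf <- kin; kin_inf$e_supply_N <- Inf
  r_inf <- process_rates(st, kin_inf)
  r_cap <- process_rates(st, kin)
  v <- c("v_NAR", "v_NIR", "v_NOR", "v_N2OR")
  pot <- sum(r_inf[v]) / (1e9 * 1e-9)
  s <- kin$e_supply_N / (kin$e_supply_N + pot)
  expect_equal(unname(r_cap[v]), unname(r_inf[v]) * s, tolerance = 1e-12)
  expect_equal(r_cap[["v_O2"]], r_inf[["v_O2"]])
})

test_that("the state derivative conserves nitrogen and books electrons exactly", {
  kin <- kinetic_params(); reg <- regulatory_params()
  geom <- vial_geometry()
  st <- make_state(o2_l = 1, no3_l = 3000, no2_l = 150, no_l = 0.05,
                   n2o_l = 0.03, biomass = 3e9,
                   E = c(NAR = 3, NIR = 2, NOR = 6, N2OR = 2))
  st[["O2_g"]] <- 3; st[["NO_g"]] <- 0.1; st[["N2O_g"]] <- 0.5
  d <- state_derivative(st, kin, reg, geom)
  vl <- geom$liquid_ml / 1000
  dn <- d[["NO_g"]] + 2 * d[["N2O_g"]] + 2 * d[["N2_g"]] +
    (d[["NO3_l"]] + d[["NO2_l"]] + d[["NO_l"]] + 2 * d[["N2O_l"]]) * vl
  expect_equal(dn, 0, tolerance = 1e-12)
  ## total electron consumption equals the stoichiometric sum over substrates
  r <- process_rates(st, kin, geom)
  e_tot <- 4 * (r[["v_O2"]] / 4) + 2 * (r[["v_NAR"]] / 2) +
    1 * r[["v_NIR"]] + 1 * r[["v_NOR"]] + 1 * r[["v_N2OR"]]
  expect_equal(e_tot,
               r[["v_O2"]] + r[["v_NAR"]] + r[["v_NIR"]] + r[["v_NOR"]] +
                 r[["v_N2OR"]])
  expect_equal(d[["biomass"]], kin$yield * e_tot)
})

test_that("gas transfer relaxes an abiotic vial toward Henry equilibrium", {
  kin <- kinetic_params(); reg <- regulatory_params(); geom <- vial_geometry()
  st <- vial_state(geom, o2_ppmv = 10000)    # all O2 in headspace, none dissolved
  d <- state_derivative(st, kin, reg, geom)
  eq <- equilibrium_partition(st[["O2_g"]], "O2", geom)
  expect_gt(d[["O2_l"]], 0)                  # dissolving
  expect_equal(d[["O2_g"]], -d[["O2_l"]] * geom$liquid_ml / 1000)
  ## flux magnitude equals kLa * (c_eq_of_headspace - 0) * V_L
  h <- henry_coefficient("O2", geom$temperature_K, geom$salt_load)
  c_eq <- unname(h) * (st[["O2_g"]] * 1e-6 * 0.0820574 * geom$temperature_K /
                         (geom$headspace_ml / 1000)) * 1e6
  expect_equal(d[["O2_l"]] * geom$liquid_ml / 1000,
               kin$kLa_O2 * c_eq * geom$liquid_ml / 1000, tolerance = 1e-12)
})
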