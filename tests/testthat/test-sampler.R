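test_that("headspace sampling dilutes by (1-f) and restores pressure with He", {
  geom <- vial_geometry()
  st <- vial_state(geom, o2_ppmv = 10000)
  st[["N2_g"]] <- 100
  st[["He_g"]] <- st[["He_g"]] - 100   # keep capacity consistent
  ## zero volume is the identity
  s0 <- apply_headspace_sampling(st, 0, geom)
  expect_equal(s0$state, st)
  ## f = 0.05: the sampled gas drops to 95%, He replaces the removed moles
  v <- 0.05 * geom$headspace_ml
  s <- apply_headspace_sampling(st, v, geom)
  expect_equal(s$measurement$f, 0.05)
  expect_equal(s$measurement$N2_umol, 100)        # pre-sample measurement
  expect_equal(s$state[["N2_g"]], 95)
  tot_before <- sum(st[c("O2_g", "NO_g", "N2O_g", "N2_g", "He_g")])
  tot_after <- sum(s$state[c("O2_g", "NO_g", "N2O_g", "N2_g", "He_g")])
  expect_equal(tot_after, tot_before)
  ## two consecutive samplings compound to (1-f)^2 absent production
  s2 <- apply_headspace_sampling(s$state, v, geom)
  expect_equal(s2$state[["N2_g"]], 100 * 0.95^2)
  expect_error(apply_headspace_sampling(st, geom$headspace_ml, geom),
               "invalid protocol")
})

test_that("liquid harvest scales biomass, keeps concentrations, tracks volumes", {
  geom <- vial_geometry()
  st <- vial_state(geom, no3_mM = 5, biomass = 1e9)
  st[["NO_l"]] <- 0.05; st[["N2O_l"]] <- 0.02
  expect_equal(apply_liquid_harvest(st, 0, geom)$state, st)
  h <- apply_liquid_harvest(st, 25, geom)
  expect_equal(h$state[["biomass"]], 5e8)
  expect_equal(h$state[["NO3_l"]], st[["NO3_l"]])    # concentration unchanged
  expect_equal(h$geometry$liquid_ml, 25)
  expect_equal(h$geometry$headspace_ml, 95)
  ## He back-fill keeps the headspace at the geometry pressure
  he_added <- h$state[["He_g"]] - st[["He_g"]]
  expect_equal(he_added, 1 * 0.025 / (0.0820574 * 308.15) * 1e6,
               tolerance = 1e-9)
  ## N bookkeeping: removed N equals concentration x removed volume
  n_before <- total_nitrogen(st, geom)
  n_after <- total_nitrogen(h$state, h$geometry)
  removed <- (st[["NO3_l"]] + st[["NO2_l"]] + st[["NO_l"]] +
                2 * st[["N2O_l"]]) * 0.025
  expect_equal(n_before - n_after, removed, tolerance = 1e-12)
  expect_error(apply_liquid_harvest(st, 60, geom), "harvest volume")
})

test_that("zero-noise incubations reproduce the truth and seeds are reproducible", {
  run <- default_run()
  expect_identical(run$incubation$measurements, run$incubation$truth_table)
  truth <- run$incubation$truth_table
  nm <- noise_model(sd_rel = 0.02, seed = 42)
  t1 <- apply_measurement_noise(truth, nm)
  t2 <- apply_measurement_noise(truth, nm)
  expect_identical(t1, t2)
  t3 <- apply_measurement_noise(truth, noise_model(sd_rel = 0.02, seed = 43))
  expect_false(identical(t1, t3))
})

test_that("the relative noise level is realized empirically", {
  truth <- data.frame(time_h = seq_len(600),
                      O2_umol = 20, NO_umol = 5, N2O_umol = 5, N2_umol = 50,
                      O2_ppmv = 0, NO_ppmv = 0, N2O_ppmv = 0, N2_ppmv = 0,
                      no2_uM = 100, biomass_proxy = 1, liquid_ml = 50,
                      f = 0.014)
  noisy <- apply_measurement_noise(truth, noise_model(
    sd_rel = 0.02, floor_gas_umol = 0, floor_no2_uM = 0, seed = 7))
  ratio <- noisy$N2_umol / truth$N2_umol - 1
  expect_equal(stats::sd(ratio), 0.02, tolerance = 0.15)
  expect_equal(mean(ratio), 0, tolerance = 0.005)
})

test_that("sampled nitrogen reconciles with what remains in the vial", {
  run <- default_run()
  err <- nitrogen_balance_error(run, init_n_umol = 5 * 50)
  expect_lt(err, 1e-6)
})

test_that("measurement CSVs round-trip with their metadata sidecar", {
  run <- default_run()
  tab <- run$incubation$truth_table
  tmp <- tempfile(fileext = ".csv")
  prot <- standard_protocol(duration_h = 12, inoculum_cells = 2e8)
  write_measurements(tab, tmp, geometry = vial_geometry(), protocol = prot,
                     seed = 1)
  back <- read_measurements(tmp)
  expect_equal(back$N2_umol, tab$N2_umol)
  meta <- attr(back, "meta")
  expect_equal(meta$seed, 1)
  expect_equal(meta$geometry$liquid_ml, 50)
  expect_match(meta$protocol_md5, "^[0-9a-f]{32}$")
  expect_error(read_measurements({
    f2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), f2, row.names = FALSE)
    f2
  }), "missing columns")
})
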