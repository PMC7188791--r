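mk_table <- function(time_h, f, n2 = 0, n2o = 0, no = 0, o2 = 0, no2 = 0,
                     liquid_ml = 50) {
  data.frame(time_h = time_h, O2_umol = o2, NO_umol = no, N2O_umol = n2o,
             N2_umol = n2, no2_uM = no2, liquid_ml = liquid_ml, f = f)
}

test_that("dilution correction books the He back-fill exactly", {
  ## hand oracle: 100 umol, 5% sampled, 105 next hour -> 105 - 95 = 10/h
  tab <- mk_table(c(0, 1), f = c(0.05, 0.05), n2 = c(100, 105))
  r <- dilution_corrected_production(tab)
  expect_equal(r$P_N2, 10)
  expect_equal(r$t_mid, 0.5)
  ## f = 0: plain first differences
  tab0 <- mk_table(0:3, f = 0, n2 = c(0, 2, 6, 12))
  expect_equal(dilution_corrected_production(tab0)$P_N2, c(2, 4, 6))
  ## O2 consumption is the negated corrected production
  tabo <- mk_table(c(0, 1), f = c(0.1, 0.1), o2 = c(100, 80))
  expect_equal(dilution_corrected_production(tabo)$C_O2, 10)
  ## errors name the problem
  tabna <- mk_table(c(0, 1), f = c(NA, 0.05), n2 = c(1, 2))
  expect_error(dilution_corrected_production(tabna), "missing sampled fraction")
  expect_error(dilution_corrected_production(mk_table(c(1, 1), f = 0)),
               "strictly increasing")
})

test_that("reductase rates walk the nitrogen chain backwards", {
  ## P(N2-N) = 2 (i.e. 1 umol N2/h), nitrite rising at 1 umol/h
  r <- data.frame(t_mid = 1, P_NO = 0, P_N2O = 0, P_N2 = 1, C_O2 = 0,
                  dNO2 = 1)
  red <- reductase_rates(r)
  expect_equal(red$R_N2OR, 2)
  expect_equal(red$R_NOR, 2)
  expect_equal(red$R_NIR, 2)
  expect_equal(red$R_NAR, 3)
  expect_false(red$negative_flag)
  ## nothing produced, nothing inferred
  z <- reductase_rates(data.frame(t_mid = 1, P_NO = 0, P_N2O = 0, P_N2 = 0,
                                  C_O2 = 0, dNO2 = 0))
  expect_equal(unlist(z[c("R_NAR", "R_NIR", "R_NOR", "R_N2OR")]),
               c(R_NAR = 0, R_NIR = 0, R_NOR = 0, R_N2OR = 0))
  ## steady chain: only N2 accumulates, nitrite constant -> all steps equal
  s <- reductase_rates(data.frame(t_mid = 1, P_NO = 0, P_N2O = 0, P_N2 = 3,
                                  C_O2 = 0, dNO2 = 0))
  expect_true(all(abs(unlist(s[c("R_NAR", "R_NIR", "R_NOR", "R_N2OR")]) -
                        6) < 1e-12))
})

test_that("electron flows apply the step stoichiometry and clip noise", {
  red <- data.frame(t_mid = 1:3, R_NAR = c(1, 2, -0.1), R_NIR = c(1, 1, 0),
                    R_NOR = c(1, 1, 0), R_N2OR = c(1, 1, 0))
  ef <- electron_flows(red, o2_rate = c(1, 0, 0))
  expect_equal(ef$Ve_NAR, c(2, 4, 0))        # 2 e- per NO3- -> NO2-
  expect_equal(ef$Ve_O2[1], 4)               # 4 e- per O2
  expect_equal(ef$Ve_NIR, c(1, 1, 0))
  expect_equal(ef$clipped, c(FALSE, FALSE, TRUE))
  expect_equal(ef$Ve_Nox, c(5, 7, 0))
  ## ratio: balanced chain gives exactly 2; zero NIR is masked
  ratio <- nar_nir_ratio(ef)
  expect_equal(ratio$ratio[1], 2)
  expect_true(is.na(ratio$ratio[3]))
  ## NAR rising while NIR constant: strictly increasing ratio
  red2 <- data.frame(t_mid = 1:4, R_NAR = c(1, 1.5, 2, 3), R_NIR = 1,
                     R_NOR = 1, R_N2OR = 1)
  expect_true(all(diff(nar_nir_ratio(electron_flows(red2, 0))$ratio) > 0))
})

test_that("log-linear fitting recovers exact and noisy exponentials", {
  tt <- 0:11
  vv <- exp(0.2 * tt)
  fit <- fit_log_linear_phase(tt, vv)
  expect_true(fit$ok)
  expect_equal(fit$mu, 0.2, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$generation_time_h, log(2) / 0.2)
  expect_equal(fit$window, c(0, 11))
  ## Monte-Carlo: 2% multiplicative noise, 200 draws
  mus <- numeric(200); cover <- logical(200)
  set.seed(101)
  for (i in 1:200) {
    y <- vv * exp(rnorm(12, 0, 0.02))
    f <- fit_log_linear_phase(tt, y, r2_threshold = 0.9)
    mus[i] <- f$mu
    cover[i] <- abs(f$mu - 0.2) <= qt(0.975, f$n - 2) * f$se
  }
  expect_equal(mean(mus), 0.2, tolerance = 0.05)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.995)
  ## piecewise exponential-then-flat: the window excludes the plateau
  t2 <- 0:14
  v2 <- c(exp(0.3 * 0:9), rep(exp(2.7), 5))
  f2 <- fit_log_linear_phase(t2, v2, r2_threshold = 0.995)
  expect_true(f2$ok)
  expect_lte(f2$window[2], 9)
  expect_equal(f2$mu, 0.3, tolerance = 1e-9)
  ## no qualifying window is a result, not an error
  f3 <- fit_log_linear_phase(1:3, c(1, 2, 4))
  expect_false(f3$ok)
  expect_true(is.na(f3$mu))
})

test_that("generation times and relative declines match the worked arithmetic", {
  expect_equal(generation_time(log(2)), 1)
  expect_equal(generation_time(0.201), 3.449, tolerance = 1e-3)
  expect_equal(generation_time(0.115), 6.027, tolerance = 1e-3)
  expect_error(generation_time(0), "positive")
  expect_equal(relative_growth_change(0.028, 0.119), 76.47, tolerance = 1e-3)
  expect_equal(relative_growth_change(0.002, 0.119), 98.32, tolerance = 1e-3)
  expect_equal(relative_growth_change(0.07, 0.07), 0)
  expect_error(relative_growth_change(0.1, 0), "positive")
})

test_that("generation accounting: realized doublings and the acceptor budget", {
  ## e-flow quadrupling across the window means exactly two doublings
  tt <- seq(0, 6, by = 1)
  vv <- 2^(tt / 3)                # quadruples over 6 h
  fit <- fit_log_linear_phase(tt, vv)
  expect_equal(anoxic_generations(fit), 2, tolerance = 1e-9)
  ## equivalence mu*dt/ln2 == log2(fold change) on exact data
  expect_equal(fit$mu * diff(fit$window) / log(2),
               log2(vv[length(vv)] / vv[1]), tolerance = 1e-9)
  ## potential generations from the nitrate budget, 5 e- per N
  expect_equal(potential_generations(250, 3e7, 2e8),
               log2(1 + 3e7 * 5 * 250 / 2e8))
  expect_error(potential_generations(10, -1, 1), "positive")
})

test_that("inferred rates are invariant to the time unit up to scale", {
  run <- default_run()
  tab_h <- run$incubation$truth_table
  tab_min <- tab_h
  tab_min$time_h <- tab_h$time_h * 60
  r_h <- dilution_corrected_production(tab_h)
  r_min <- dilution_corrected_production(tab_min)
  expect_equal(r_min$P_N2 * 60, r_h$P_N2, tolerance = 1e-12)
  expect_equal(r_min$t_mid / 60, r_h$t_mid, tolerance = 1e-12)
  f_h <- fit_log_linear_phase(r_h$t_mid, pmax(r_h$P_N2, 1e-12))
  f_min <- fit_log_linear_phase(r_min$t_mid, pmax(r_min$P_N2, 1e-12))
  expect_equal(f_min$mu * 60, f_h$mu, tolerance = 1e-8)
  expect_equal(f_min$generations, f_h$generations, tolerance = 1e-8)
})

test_that("N-oxide summaries behave on constructed and simulated series", {
  run <- default_run()
  summ <- summarize_noxide_accumulation(run$incubation$trajectory,
                                        run$inference$fit_anoxic)
  expect_true(is.finite(summ$NO_max_nM) && is.finite(summ$NO_steady_nM))
  expect_gte(summ$NO_max_nM, summ$NO_steady_nM)
  expect_gt(summ$O2_at_onset_uM, 0)
  expect_gt(summ$NO2_max_umol, 0)
  ## monotone NO series: the maximum is the last value
  traj <- run$incubation$trajectory
  traj$states <- data.frame(time_h = 0:10, traj$states[1, STATE_NAMES,
                                                       drop = FALSE],
                            row.names = NULL)
  traj$states[STATE_NAMES] <- 0
  traj$states$NO_l <- seq(0, 0.1, length.out = 11)
  traj$states$liquid_ml <- 50
  s2 <- summarize_noxide_accumulation(traj, NULL)
  expect_equal(s2$NO_max_nM, 100)
  expect_true(is.na(s2$NO_steady_nM))
})
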