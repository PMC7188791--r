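#!/usr/bin/env Rscript
## Calibration summary for the frozen default parameter set.
##
## Runs the reference experiments under the shipped defaults and prints the
## quantities the calibration targets: apparent oxic/anoxic growth rates,
## generations of exponential anaerobic growth, N-oxide accumulation, and
## the timing of the semi-aerobic N2O reduction.  Edit kinetic_params() /
## regulatory_params() overrides below to explore re-calibration; the
## shipped defaults live in inst/extdata/default_params.yaml.
##
## Usage: Rscript scripts/calibrate.R

suppressPackageStartupMessages(library(denitvial))

scs <- builtin_scenarios()
pick <- c("nitrate_2mM", "nitrate_5mM", "nitrate_200mM", "nitrite_2mM",
          "nitrite_5mM", "aerobic_n2o_100ppmv")
for (nm in pick) {
  run <- run_scenario(scs[[nm]], seed = 1, no_noise = TRUE)
  st <- run$incubation$trajectory$states
  cat(sprintf(
    "%-20s mu_ox=%6.3f mu_anox=%6.3f gens=%5.2f NO_max=%5.1f nM NO2_max=%6.2f umol O2_onset=%5.2f uM\n",
    nm, run$summary$mu_ox, run$summary$mu_anox,
    run$summary$generations_anoxic, run$summary$NO_max_nM,
    run$summary$NO2_max_umol, run$summary$O2_at_onset_uM))
}

run <- run_scenario(scs$aerobic_n2o_100ppmv, seed = 1, no_noise = TRUE)
st <- run$incubation$trajectory$states
tot_n2o <- st$N2O_g + st$N2O_l * st$liquid_ml / 1000
cat(sprintf(
  "semi-aerobic N2O: half-consumed at %.1f h ([O2] %.2f uM); NO appears at %.1f h\n",
  st$time_h[which(tot_n2o < tot_n2o[2] / 2)[1]],
  st$O2_l[which(tot_n2o < tot_n2o[2] / 2)[1]],
  st$time_h[which(st$NO_l > 0.02)[1]]))
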