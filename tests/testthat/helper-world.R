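# small fixture builders shared across test files

tiny_world <- function(seed = 42, n = 3, years = 2025:2030) {
  generate_world(n, seed, world_config(years = years))
}

# config with PM2.5 emissions large enough that disk-mean concentrations
# exceed the GEMM counterfactual, so the PM2.5 causes are active
pm_active_config <- function(years = 2025:2030) {
  base <- c(CO2 = 9e5, `PM2.5` = 5000, CO = 2000, SO2 = 400, NO2 = 1200)
  world_config(emission_base_t = base, years = years)
}

# scalar, test-local re-derivation of the hazard-ratio formulas (kept
# independent of the package's vectorised implementation)
oracle_rr <- function(C, row) {
  if (row$form == "GEMM") {
    z <- max(0, C - row$z_cf)
    exp(row$theta * log(1 + z / row$alpha) /
          (1 + exp(-(z - row$mu) / row$nu)))
  } else {
    exp(row$beta * max(0, C - row$c0) / row$per_unit)
  }
}
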