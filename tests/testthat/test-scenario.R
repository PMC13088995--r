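test_that("adoption ramp is zero at start, one at the end, linear between", {
  expect_identical(ramp_fraction(2025), 0)
  expect_identical(ramp_fraction(2050), 1)
  expect_equal(ramp_fraction(2038), 13 / 25)
  expect_equal(ramp_fraction(2010), 0)
  expect_equal(ramp_fraction(2099), 1)
  expect_error(ramp_schedule(2050, 2025), "precede")
})

test_that("identity multipliers leave local pollutants at BAU in every year", {
  world <- tiny_world(seed = 21, n = 2, years = 2025:2040)
  spec <- scenario_spec("DAC-CCS", pollutant_multipliers = c(
    `PM2.5` = 1, CO = 1, SO2 = 1, NO2 = 1
  ))
  out <- apply_scenario(world$bau, spec)
  local <- out$pollutant != "CO2"
  expect_equal(out$mass[local], world$bau$mass[local])
})

test_that("scenario scaling matches a per-row brute-force recomputation", {
  world <- tiny_world(seed = 22, n = 3, years = 2025:2050)
  kappa <- c(`PM2.5` = 0.7, CO = 1.3, SO2 = 0.6, NO2 = 1.1)
  spec <- scenario_spec("PSC-CCU", pollutant_multipliers = kappa)
  out <- apply_scenario(world$bau, spec)

  # endpoint arithmetic: full deployment in 2050
  bau50 <- world$bau[world$bau$year == 2050 & world$bau$pollutant == "SO2", ]
  out50 <- out[out$year == 2050 & out$pollutant == "SO2", ]
  expect_equal(out50$mass, 0.6 * bau50$mass)

  # row-wise oracle over the whole ramp
  for (i in sample(nrow(world$bau), 50)) {
    row <- world$bau[i, ]
    f <- max(0, min(1, (row$year - 2025) / 25))
    k <- if (row$pollutant == "CO2") 1 else kappa[[row$pollutant]]
    expect_equal(out$mass[i], row$mass * (1 + f * (k - 1)))
  }
})

test_that("unknown pollutants in multipliers are rejected", {
  expect_error(
    scenario_spec("DAC-CCS", pollutant_multipliers = c(O3 = 1.2)),
    "may only name"
  )
  expect_error(scenario_spec("XYZ"), "unknown scenario_id")
})

test_that("saved carbon is zero before the ramp and equals BAU CO2 at full CCS offset", {
  world <- tiny_world(seed = 23, n = 3, years = 2025:2050)
  for (id in c("DAC-CCS", "PSC-CCS")) {
    spec <- scenario_spec(id)
    scen <- apply_scenario(world$bau, spec)
    expect_equal(co2_saved(world$bau, scen, spec, 2025), 0)
    bau_co2_2050 <- sum(world$bau$mass[world$bau$pollutant == "CO2" &
                                         world$bau$year == 2050])
    expect_equal(co2_saved(world$bau, scen, spec, 2050), bau_co2_2050)

    # intermediate year: brute-force ledger over the offset stream
    y <- 2033
    f <- (y - 2025) / 25
    ledger <- sum(f * world$bau$mass[world$bau$pollutant == "CO2" &
                                       world$bau$year == y])
    expect_equal(co2_saved(world$bau, scen, spec, y), ledger)
  }
  spec <- scenario_spec("DAC-CCS")
  scen <- apply_scenario(world$bau, spec)
  expect_error(co2_saved(world$bau, scen, spec, 2060), "not covered")
})

test_that("CCU neutrality factor scales the displaced fossil CO2", {
  world <- tiny_world(seed = 29, n = 2, years = 2025:2050)
  spec <- scenario_spec("DAC-CCU", ccu_neutrality = 0.8)
  scen <- apply_scenario(world$bau, spec)
  bau_co2 <- sum(world$bau$mass[world$bau$pollutant == "CO2" &
                                  world$bau$year == 2050])
  expect_equal(co2_saved(world$bau, scen, spec, 2050), 0.8 * bau_co2)
})

test_that("fuel coverage equals the deployment fraction of BAU fuel", {
  spec <- scenario_spec("PSC-CCU")
  expect_equal(fuel_quantities(100, spec, 2025), c(NA_t = 0, NJ_t = 0))
  expect_equal(fuel_quantities(1e6, spec, 2050), c(NA_t = 1e6, NJ_t = 1e6))
  expect_equal(fuel_quantities(100, spec, 2038), c(NA_t = 52, NJ_t = 52))
  expect_error(fuel_quantities(-1, spec, 2030), ">= 0")
})

test_that("deployment is monotone relative to BAU and idempotent", {
  world <- tiny_world(seed = 24, n = 1, years = 2025:2050)
  spec <- scenario_spec("PSC-CCS")
  out <- apply_scenario(world$bau, spec)
  ratio <- out$mass / world$bau$mass
  for (p in c("SO2", "NO2", "PM2.5", "CO")) {
    r <- ratio[out$pollutant == p][order(out$year[out$pollutant == p])]
    expect_true(all(diff(r) <= 1e-12))  # kappa < 1: non-increasing vs BAU
  }

  # same (bau, spec) twice gives identical output, and application commutes
  # with restricting the year range
  expect_identical(out, apply_scenario(world$bau, spec))
  sub <- world$bau[world$bau$year <= 2030, ]
  expect_equal(apply_scenario(sub, spec),
               out[out$year <= 2030, ])
})

test_that("scenario YAML round-trips the spec list", {
  path <- withr::local_tempfile(fileext = ".yaml")
  specs <- default_scenarios()
  write_scenarios_yaml(specs, path)
  back <- read_scenarios_yaml(path)
  expect_equal(names(back), names(specs))
  expect_equal(back[["PSC-CCS"]]$pollutant_multipliers,
               specs[["PSC-CCS"]]$pollutant_multipliers)
  expect_equal(back[["DAC-CCU"]]$ramp, specs[["DAC-CCU"]]$ramp)
})
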