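test_that("GEMM hazard ratio honours the counterfactual and the null effect", {
  row <- list(form = "GEMM", theta = 0.1430, z_cf = 2.4,
              alpha = 1.6, mu = 15.5, nu = 36.8)
  expect_identical(gemm_hazard_ratio(0, row), 1)
  expect_identical(gemm_hazard_ratio(2.4, row), 1)
  expect_identical(gemm_hazard_ratio(1.7, row), 1)
  null_row <- modifyList(row, list(theta = 0))
  expect_identical(gemm_hazard_ratio(c(0, 10, 400), null_row), c(1, 1, 1))

  # direct evaluation of the stated formula at C = 10
  z <- 10 - 2.4
  hand <- exp(0.1430 * log(1 + z / 1.6) / (1 + exp(-(z - 15.5) / 36.8)))
  expect_equal(gemm_hazard_ratio(10, row), hand)
  expect_error(gemm_hazard_ratio(10, list(form = "log-linear")), "GEMM row")
})

test_that("log-linear relative risk honours reference level and slope scale", {
  row <- list(form = "log-linear", beta = 0.01, c0 = 5, per_unit = 10)
  expect_identical(loglinear_rr(5, row), 1)
  expect_identical(loglinear_rr(0, row), 1)
  expect_equal(loglinear_rr(15, row), exp(0.01))
  null_row <- modifyList(row, list(beta = 0))
  expect_identical(loglinear_rr(c(0, 50, 500), null_row), c(1, 1, 1))

  # the CO row is expressed per mg/m3
  co <- default_erf_table()
  co <- co[co$disease_id == "CCVD-CO", ]
  expect_equal(loglinear_rr(1000, co), exp(co$beta))
})

test_that("population attributable fraction follows (RR-1)/RR", {
  expect_identical(attributable_fraction(1), 0)
  expect_identical(attributable_fraction(2), 0.5)
  expect_equal(attributable_fraction(1e6), 1 - 1e-6)
  expect_lt(1 - attributable_fraction(1e7), 1e-6)
  expect_error(attributable_fraction(0.9), ">= 1")
  rr <- 1 + runif(100) * 10
  paf <- attributable_fraction(rr)
  expect_true(all(paf >= 0 & paf < 1))
})

test_that("hazard ratios are non-decreasing in concentration for every packaged row", {
  erf <- default_erf_table()
  grid <- seq(0, 500, by = 2.5)
  for (i in seq_len(nrow(erf))) {
    row <- erf[i, ]
    rr <- if (row$form == "GEMM") gemm_hazard_ratio(grid, row) else
      loglinear_rr(grid, row)
    expect_true(all(diff(rr) >= 0), info = row$disease_id)
    expect_true(all(rr >= 1), info = row$disease_id)
  }
})

test_that("a textbook stratum gives the closed-form death count", {
  # RR = 2 at C = c0 + per_unit when beta = log(2)
  erf <- default_erf_table()
  erf$beta[erf$disease_id == "RD-NO2"] <- log(2)
  conc <- tibble::tibble(airport_id = "A", year = 2030, pollutant = "NO2",
                         conc_ugm3 = 10)
  pop <- tibble::tibble(airport_id = "A", age_band = "70-74",
                        sex = "male", count = 1e5)
  rates <- tibble::tibble(disease_id = "RD-NO2", age_band = "70-74",
                          sex = "male", rate = 0.01)
  res <- attributable_deaths(conc, pop, rates, erf)
  expect_equal(res$attributable_deaths, 500)

  # zero concentration everywhere -> zero deaths everywhere
  res0 <- attributable_deaths(dplyr::mutate(conc, conc_ugm3 = 0),
                              pop, rates, erf)
  expect_equal(res0$attributable_deaths, 0)
})

test_that("missing baseline rates are rejected naming the stratum", {
  conc <- tibble::tibble(airport_id = "A", year = 2030, pollutant = "NO2",
                         conc_ugm3 = 10)
  pop <- tibble::tibble(airport_id = "A", age_band = "70-74",
                        sex = "female", count = 100)
  rates <- tibble::tibble(disease_id = "RD-NO2", age_band = "70-74",
                          sex = "male", rate = 0.01)
  expect_error(attributable_deaths(conc, pop, rates),
               "RD-NO2/70-74/female")
})

test_that("stratified accounting matches an independent brute-force loop", {
  world <- generate_world(3, seed = 77, pm_active_config(years = 2030))
  specs <- default_scenarios()
  scen <- apply_scenario(world$bau, specs[["DAC-CCU"]])
  conc <- concentration_table(scen, world$registry)
  erf <- default_erf_table()
  got <- attributable_deaths(conc, world$population, world$rates, erf)

  # brute force: loop over every (record, disease, band, sex) with scalar math
  expected <- 0
  n_checked <- 0
  for (i in seq_len(nrow(conc))) {
    cr <- conc[i, ]
    rows <- erf[erf$pollutant == cr$pollutant & is.na(erf$age_band), ]
    for (j in seq_len(nrow(rows))) {
      row <- rows[j, ]
      for (band in age_bands()) {
        low <- if (band == "95+") 95 else as.numeric(sub("-.*", "", band))
        if (low < row$min_age) next
        for (s in c("male", "female")) {
          cnt <- world$population$count[
            world$population$airport_id == cr$airport_id &
              world$population$age_band == band & world$population$sex == s]
          rate <- world$rates$rate[world$rates$disease_id == row$disease_id &
                                     world$rates$age_band == band &
                                     world$rates$sex == s]
          rr <- oracle_rr(cr$conc_ugm3, row)
          expected <- expected + cnt * rate * (rr - 1) / rr
          n_checked <- n_checked + 1
        }
      }
    }
  }
  expect_gt(n_checked, 0)
  expect_equal(sum(got$attributable_deaths), expected, tolerance = 1e-9)

  # deaths never exceed baseline deaths in any stratum
  base <- dplyr::left_join(
    got, world$population, by = c("airport_id", "age_band", "sex")
  )
  base <- dplyr::left_join(
    base, world$rates, by = c("disease_id", "age_band", "sex")
  )
  expect_true(all(got$attributable_deaths <= base$count * base$rate + 1e-12))
})

test_that("age-specific parameter rows override the all-age row for their band", {
  erf <- default_erf_table()
  boost <- erf[erf$disease_id == "IHD", ]
  boost$age_band <- "80-84"
  boost$theta <- boost$theta * 2
  erf2 <- dplyr::bind_rows(erf, boost)

  conc <- tibble::tibble(airport_id = "A", year = 2030, pollutant = "PM2.5",
                         conc_ugm3 = 30)
  pop <- tidyr::expand_grid(airport_id = "A", age_band = age_bands(),
                            sex = c("male", "female")) |>
    dplyr::mutate(count = 1000)
  rates <- tidyr::expand_grid(disease_id = disease_ids(),
                              age_band = age_bands(),
                              sex = c("male", "female")) |>
    dplyr::mutate(rate = 0.01)
  d1 <- attributable_deaths(conc, pop, rates, erf)
  d2 <- attributable_deaths(conc, pop, rates, erf2)
  m1 <- aggregate_mortality(d1[d1$disease_id == "IHD", ], "age_band")
  m2 <- aggregate_mortality(d2[d2$disease_id == "IHD", ], "age_band")
  cmp <- dplyr::inner_join(m1, m2, by = "age_band")
  changed <- cmp$age_band[abs(cmp$deaths.x - cmp$deaths.y) > 1e-12]
  expect_identical(changed, "80-84")
  expect_gt(cmp$deaths.y[cmp$age_band == "80-84"],
            cmp$deaths.x[cmp$age_band == "80-84"])
})

test_that("small exposures linearise to count * rate * beta * dC / unit", {
  erf <- default_erf_table()
  row <- erf[erf$disease_id == "RD-SO2", ]
  dC <- 1e-3 * row$per_unit / row$beta * 0.5  # beta*dC/unit = 5e-4
  conc <- tibble::tibble(airport_id = "A", year = 2030, pollutant = "SO2",
                         conc_ugm3 = dC)
  pop <- tibble::tibble(airport_id = "A", age_band = "60-64",
                        sex = "male", count = 1e6)
  rates <- tidyr::expand_grid(disease_id = c("RD-SO2", "CCVD-SO2"),
                              age_band = "60-64", sex = "male") |>
    dplyr::mutate(rate = 0.02)
  res <- attributable_deaths(conc, pop, rates, erf)
  d <- res$attributable_deaths[res$disease_id == "RD-SO2"]
  linear <- 1e6 * 0.02 * row$beta * dC / row$per_unit
  expect_lt(abs(d - linear) / linear, 0.001)
})

test_that("marginal aggregations all reconcile to one grand total", {
  world <- tiny_world(seed = 31, n = 3, years = 2025:2027)
  scen <- apply_scenario(world$bau, scenario_spec("PSC-CCU"))
  conc <- concentration_table(scen, world$registry)
  res <- attributable_deaths(conc, world$population, world$rates)

  total <- aggregate_mortality(res)$deaths
  for (cut in list("sex", "age_band", "disease", "airport", "year",
                   c("sex", "age_band"))) {
    expect_equal(sum(aggregate_mortality(res, cut)$deaths), total)
  }
  expect_error(aggregate_mortality(res, "altitude"), "unknown grouping")

  # top-k ranking agrees with a brute-force sort
  by_ap <- aggregate_mortality(res, "airport")
  brute <- by_ap$airport_id[order(-by_ap$deaths)][1:2]
  top <- dplyr::slice_max(by_ap, deaths, n = 2)
  expect_identical(top$airport_id, brute)
})

test_that("lowering every concentration weakly lowers total deaths", {
  world <- generate_world(2, seed = 55, pm_active_config(years = 2040))
  scen <- apply_scenario(world$bau, scenario_spec("DAC-CCU"))
  conc <- concentration_table(scen, world$registry)
  hi <- attributable_deaths(conc, world$population, world$rates)
  lo <- attributable_deaths(dplyr::mutate(conc, conc_ugm3 = conc_ugm3 * 0.5),
                            world$population, world$rates)
  expect_lte(sum(lo$attributable_deaths), sum(hi$attributable_deaths))
})
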