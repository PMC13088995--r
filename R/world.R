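#' World configuration for the synthetic-data generator
#'
#' Bundles every distributional choice the generator makes: wind-speed
#' distribution, population size and age structure, baseline mortality
#' schedules, and business-as-usual (BAU) emission levels. Defaults emulate
#' the statistical structure the downstream analysis assumes — lognormal
#' wind speeds, elderly-skewed mortality, gently rising aviation traffic —
#' at the magnitude of a large international airport and its 20-km
#' neighbourhood. All values are overridable.
#'
#' @param wind_median_ms Median of the lognormal wind-speed distribution, m/s.
#' @param wind_sdlog Log-scale standard deviation of wind speeds.
#' @param release_height_m Effective release height of airport emissions, m
#'   (ground-level operations by default).
#' @param exposure_radius_m Radius of the exposed disk around each airport, m.
#' @param pop_median Median population within the exposure disk, persons.
#' @param pop_sdlog Log-scale SD of the per-airport population.
#' @param age_weights Named numeric vector over [age_bands()]: relative size
#'   of each band before normalisation. The default holds bands roughly flat
#'   to age 59 then decays geometrically (factor `elderly_decay`).
#' @param elderly_decay Geometric decay factor per 5-year band above age 60.
#' @param sex_split Fraction of each stratum that is male.
#' @param base_rates Named numeric vector: baseline annual mortality rate per
#'   person at the 70-74 reference band, one entry per disease category.
#' @param age_rate_factor Named numeric vector: multiplicative rate change per
#'   5-year band away from the 70-74 reference (rates rise with age).
#' @param male_rate_ratio Named numeric vector: male/female baseline-rate
#'   ratio per disease (type 2 diabetes is slightly female-dominant).
#' @param emission_base_t Named numeric vector: mean 2025 emitted mass per
#'   airport and pollutant, tonnes/year.
#' @param emission_growth Annual multiplicative growth of emissions (0.015 =
#'   +1.5 %/yr).
#' @param airport_size_sdlog Log-scale SD of the per-airport traffic size
#'   factor multiplying all of an airport's emissions.
#' @param co2_per_fuel_t Tonnes of CO2 emitted per tonne of jet fuel burned
#'   (standard kerosene combustion stoichiometry), used to infer BAU fuel
#'   tonnage from the CO2 inventory.
#' @param years Integer vector of inventory years.
#'
#' @return An object of class `world_config` (a validated list).
#' @export
world_config <- function(wind_median_ms = 3.5,
                         wind_sdlog = 0.4,
                         release_height_m = 0,
                         exposure_radius_m = 20000,
                         pop_median = 5e5,
                         pop_sdlog = 0.8,
                         age_weights = NULL,
                         elderly_decay = 0.75,
                         sex_split = 0.5,
                         base_rates = NULL,
                         age_rate_factor = NULL,
                         male_rate_ratio = NULL,
                         emission_base_t = c(
                           CO2 = 9e5, `PM2.5` = 60, CO = 2000,
                           SO2 = 400, NO2 = 1200
                         ),
                         emission_growth = 0.015,
                         airport_size_sdlog = 0.9,
                         co2_per_fuel_t = 3.16,
                         years = 2025:2050) {
  diseases <- disease_ids()
  if (is.null(age_weights)) {
    bands <- age_bands()
    w <- rep(1, length(bands))
    over60 <- which(age_band_lower(bands) >= 60)
    w[over60] <- elderly_decay^(seq_along(over60))
    age_weights <- setNames(w, bands)
  }
  if (is.null(base_rates)) {
    base_rates <- c(
      stroke = 0.006, LC = 0.003, LRI = 0.002, COPD = 0.004,
      IHD = 0.009, T2DM = 0.0025, `CCVD-CO` = 0.011, `RD-NO2` = 0.007,
      `CCVD-SO2` = 0.011, `RD-SO2` = 0.007
    )
  }
  if (is.null(age_rate_factor)) {
    age_rate_factor <- setNames(
      c(1.35, 1.3, 1.35, 1.35, 1.4, 1.3, 1.4, 1.4, 1.4, 1.4), diseases
    )
  }
  if (is.null(male_rate_ratio)) {
    male_rate_ratio <- setNames(
      c(1.2, 1.35, 1.1, 1.3, 1.25, 0.93, 1.25, 1.3, 1.25, 1.3), diseases
    )
  }
  check_that(wind_median_ms > 0 && wind_sdlog >= 0,
             "wind-speed configuration must be positive")
  check_that(exposure_radius_m > 0, "exposure_radius_m must be > 0")
  check_that(all(age_weights >= 0) && any(age_weights > 0),
             "age_weights must be non-negative with positive mass")
  check_that(setequal(names(age_weights), age_bands()),
             "age_weights must cover every 5-year band 0-4 .. 95+")
  for (nm in c("base_rates", "age_rate_factor", "male_rate_ratio")) {
    v <- get(nm)
    check_that(setequal(names(v), diseases),
               paste0(nm, " must name all ten disease categories"))
  }
  check_that(all(base_rates >= 0 & base_rates < 1),
             "baseline rates must lie in [0, 1)")
  check_that(setequal(names(emission_base_t), POLLUTANTS),
             "emission_base_t must name all five pollutants")
  check_that(all(emission_base_t >= 0), "emission bases must be >= 0")
  check_that(length(years) >= 1, "year range must be non-empty")
  check_that(co2_per_fuel_t > 0, "co2_per_fuel_t must be > 0")
  structure(
    list(
      wind_median_ms = wind_median_ms, wind_sdlog = wind_sdlog,
      release_height_m = release_height_m,
      exposure_radius_m = exposure_radius_m,
      pop_median = pop_median, pop_sdlog = pop_sdlog,
      age_weights = age_weights[age_bands()],
      sex_split = sex_split,
      base_rates = base_rates, age_rate_factor = age_rate_factor,
      male_rate_ratio = male_rate_ratio,
      emission_base_t = emission_base_t[POLLUTANTS],
      emission_growth = emission_growth,
      airport_size_sdlog = airport_size_sdlog,
      co2_per_fuel_t = co2_per_fuel_t,
      years = as.integer(years)
    ),
    class = "world_config"
  )
}

#' The ten disease-pollutant categories
#'
#' Six diseases attributed to PM2.5 (stroke, lung cancer, lower respiratory
#' infections, COPD, ischemic heart disease, type 2 diabetes) plus four
#' gaseous-pollutant categories: cardiovascular/cerebrovascular disease from
#' CO and from SO2, respiratory disease from NO2 and from SO2.
#'
#' @return Character vector of disease identifiers.
#' @export
disease_ids <- function() {
  c("stroke", "LC", "LRI", "COPD", "IHD", "T2DM",
    "CCVD-CO", "RD-NO2", "CCVD-SO2", "RD-SO2")
}

#' Generate a synthetic airport registry
#'
#' Each airport gets a mean annual wind speed drawn from a lognormal
#' distribution, a release height and exposure radius from the config, and a
#' hidden traffic size factor reused by [generate_bau_emissions()] and
#' [generate_population_and_rates()] so busy airports sit in busy regions.
#'
#' @param n Number of airports (the study scale is 1134).
#' @param seed Integer seed fixing all randomness.
#' @param config A [world_config()].
#' @return A tibble of airport records: `airport_id`, `name`,
#'   `mean_wind_speed`, `release_height`, `exposure_radius`, `region_tag`,
#'   `size_factor`.
#' @export
generate_airports <- function(n, seed, config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  check_that(n >= 0, "n must be >= 0")
  if (n == 0) {
    return(tibble::tibble(
      airport_id = character(), name = character(),
      mean_wind_speed = numeric(), release_height = numeric(),
      exposure_radius = numeric(), region_tag = character(),
      size_factor = numeric()
    ))
  }
  regions <- c("AS", "EU", "NA", "SA", "AF", "OC")
  with_seed(child_seed(seed, "airports"), {
    tibble::tibble(
      airport_id = sprintf("AP%04d", seq_len(n)),
      name = sprintf("Synthetic International %04d", seq_len(n)),
      mean_wind_speed = rlnorm(n, meanlog = log(config$wind_median_ms),
                               sdlog = config$wind_sdlog),
      release_height = config$release_height_m,
      exposure_radius = config$exposure_radius_m,
      region_tag = sample(regions, n, replace = TRUE),
      size_factor = rlnorm(n, meanlog = 0, sdlog = config$airport_size_sdlog)
    )
  })
}

#' Generate population strata and baseline mortality rates
#'
#' Populations within each airport's exposure disk are lognormal across
#' airports (correlated with the airport's traffic size factor) and spread
#' over 5-year age bands by the configured age schedule; both sexes are
#' present in every band. Baseline cause-specific mortality rates follow a
#' geometric age gradient anchored at the 70-74 band, with per-disease
#' male/female ratios.
#'
#' @param registry Airport registry from [generate_airports()].
#' @param seed Integer seed.
#' @param config A [world_config()].
#' @return A list with tibbles `population` (`airport_id`, `age_band`, `sex`,
#'   `count`) and `rates` (`disease_id`, `age_band`, `sex`, `rate`).
#' @export
generate_population_and_rates <- function(registry, seed,
                                          config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  check_that(nrow(registry) > 0, "registry must be non-empty")
  bands <- age_bands()
  shares <- config$age_weights / sum(config$age_weights)

  population <- with_seed(child_seed(seed, "population"), {
    totals <- config$pop_median *
      registry$size_factor^0.5 *
      rlnorm(nrow(registry), 0, config$pop_sdlog)
    tidyr::expand_grid(
      airport_id = registry$airport_id,
      age_band = bands,
      sex = SEXES
    ) |>
      dplyr::mutate(
        count = totals[match(.data$airport_id, registry$airport_id)] *
          unname(shares[.data$age_band]) *
          ifelse(.data$sex == "male", config$sex_split, 1 - config$sex_split)
      ) |>
      dplyr::mutate(count = round(.data$count))
  })

  ref_idx <- match("70-74", bands)
  rates <- tidyr::expand_grid(
    disease_id = disease_ids(), age_band = bands, sex = SEXES
  ) |>
    dplyr::mutate(
      steps = match(.data$age_band, bands) - ref_idx,
      rate = unname(config$base_rates[.data$disease_id]) *
        unname(config$age_rate_factor[.data$disease_id])^.data$steps *
        ifelse(.data$sex == "male",
               2 * config$male_rate_ratio[.data$disease_id] /
                 (1 + config$male_rate_ratio[.data$disease_id]),
               2 / (1 + config$male_rate_ratio[.data$disease_id])),
      rate = pmin(.data$rate, 0.999)
    ) |>
    dplyr::select(-"steps")

  list(population = population, rates = rates)
}

#' Generate a business-as-usual emission inventory
#'
#' Per-airport 2025 base masses are the configured pollutant means scaled by
#' the airport's traffic size factor and a lognormal airport-by-pollutant
#' deviation; every later year follows the deterministic growth law
#' `mass(y) = mass(2025) * (1 + g)^(y - 2025)`, emulating projected traffic
#' growth under an already-decarbonising baseline fleet.
#'
#' @param registry Airport registry.
#' @param years Integer vector of contiguous years (default from config).
#' @param seed Integer seed.
#' @param config A [world_config()].
#' @return Tibble with columns `airport_id`, `year`, `pollutant`, `mass`
#'   (tonnes/year).
#' @export
generate_bau_emissions <- function(registry, years = NULL, seed = 1,
                                   config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  if (is.null(years)) years <- config$years
  check_that(length(years) >= 1, "year range must be non-empty")
  years <- as.integer(years)
  check_that(all(diff(sort(years)) == 1) || length(years) == 1,
             "years must form a contiguous range")
  base <- with_seed(child_seed(seed, "emissions"), {
    tidyr::expand_grid(
      airport_id = registry$airport_id, pollutant = POLLUTANTS
    ) |>
      dplyr::mutate(
        base_mass = config$emission_base_t[.data$pollutant] *
          registry$size_factor[match(.data$airport_id, registry$airport_id)] *
          rlnorm(dplyr::n(), 0, 0.2)
      )
  })
  g <- config$emission_growth
  tidyr::expand_grid(base, year = sort(years)) |>
    dplyr::mutate(mass = .data$base_mass * (1 + g)^(.data$year - min(years))) |>
    dplyr::select("airport_id", "year", "pollutant", "mass") |>
    dplyr::arrange(.data$airport_id, .data$year, .data$pollutant)
}

#' Generate a complete synthetic world bundle
#'
#' Convenience wrapper running [generate_airports()],
#' [generate_population_and_rates()] and [generate_bau_emissions()] from one
#' master seed (each stage uses its own derived child seed, so bundles are
#' reproducible stage by stage).
#'
#' @param n_airports Number of airports.
#' @param seed Master seed.
#' @param config A [world_config()].
#' @return List with `registry`, `population`, `rates`, `bau` and the config.
#' @export
generate_world <- function(n_airports, seed, config = world_config()) {
  registry <- generate_airports(n_airports, seed, config)
  pr <- generate_population_and_rates(registry, seed, config)
  bau <- generate_bau_emissions(registry, config$years, seed, config)
  list(registry = registry, population = pr$population, rates = pr$rates,
       bau = bau, config = config)
}

#' Write a world bundle as plain CSV files
#'
#' Emits `airports.csv`, `population.csv`, `baseline_rates.csv` and
#' `emissions_bau.csv` into `dir`. Column dictionaries are documented in the
#' package vignette; units are m/s (wind), persons (counts), deaths/person/yr
#' (rates) and tonnes/yr (masses).
#'
#' @param world Bundle from [generate_world()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    airports = file.path(dir, "airports.csv"),
    population = file.path(dir, "population.csv"),
    rates = file.path(dir, "baseline_rates.csv"),
    bau = file.path(dir, "emissions_bau.csv")
  )
  write_table_csv(world$registry, paths["airports"])
  write_table_csv(world$population, paths["population"])
  write_table_csv(world$rates, paths["rates"])
  write_table_csv(world$bau, paths["bau"])
  invisible(paths)
}
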