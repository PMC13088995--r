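#' Linear adoption ramp for a capture pathway
#'
#' Pathway usage is zero today and reaches full deployment at the end year,
#' changing proportionally in between. The fraction is clamped to \[0, 1\]
#' outside the ramp window.
#'
#' @param year Numeric year (vectorised).
#' @param schedule List with `start_year` and `end_year` (defaults 2025 and
#'   2050).
#' @return Deployment fraction in \[0, 1\].
#' @export
ramp_fraction <- function(year, schedule = ramp_schedule()) {
  stopifnot(schedule$start_year < schedule$end_year)
  f <- (year - schedule$start_year) /
    (schedule$end_year - schedule$start_year)
  pmin(pmax(f, 0), 1)
}

#' @rdname ramp_fraction
#' @param start_year First year of adoption (fraction 0).
#' @param end_year Year of full deployment (fraction 1).
#' @export
ramp_schedule <- function(start_year = 2025, end_year = 2050) {
  check_that(start_year < end_year, "start_year must precede end_year")
  list(start_year = start_year, end_year = end_year)
}

#' Specification of one CCUS scenario
#'
#' A scenario couples a capture mode (direct air capture, DAC, or point
#' source capture at a waste-to-energy plant, PSC) with a fate for the
#' captured CO2: permanent storage (CCS) or conversion to synthetic jet fuel
#' (CCU). Local-pollutant side effects of the fully deployed pathway are
#' expressed as dimensionless multipliers `kappa` relative to BAU; CO2 is
#' handled by the fate rule (offset stream for CCS, fuel displacement for
#' CCU), not by a multiplier.
#'
#' @param scenario_id One of `"DAC-CCS"`, `"DAC-CCU"`, `"PSC-CCS"`,
#'   `"PSC-CCU"`.
#' @param pollutant_multipliers Named vector over the four local pollutants;
#'   1 means no change at full deployment.
#' @param ramp A [ramp_schedule()].
#' @param ccu_neutrality Fraction of displaced fossil CO2 actually neutral
#'   under the CCU fate (1 = synthetic fuel fully displaces fossil CO2).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario_id,
                          pollutant_multipliers = NULL,
                          ramp = ramp_schedule(),
                          ccu_neutrality = 1) {
  check_that(scenario_id %in% SCENARIO_IDS,
             paste0("unknown scenario_id: ", scenario_id))
  if (is.null(pollutant_multipliers)) {
    pollutant_multipliers <- default_kappa()[[scenario_id]]
  }
  check_that(all(names(pollutant_multipliers) %in% LOCAL_POLLUTANTS),
             "pollutant_multipliers may only name PM2.5, CO, SO2, NO2")
  check_that(all(pollutant_multipliers >= 0), "kappa must be >= 0")
  full <- setNames(rep(1, length(LOCAL_POLLUTANTS)), LOCAL_POLLUTANTS)
  full[names(pollutant_multipliers)] <- pollutant_multipliers
  parts <- strsplit(scenario_id, "-")[[1]]
  structure(
    list(scenario_id = scenario_id, capture_mode = parts[1], fate = parts[2],
         ramp = ramp, pollutant_multipliers = full,
         ccu_neutrality = ccu_neutrality),
    class = "scenario_spec"
  )
}

#' Packaged default local-pollutant multipliers
#'
#' Illustrative, non-authoritative values chosen only to reproduce the
#' qualitative pathway ordering (point-source co-capture scrubs flue gas;
#' DAC plants carry an energy penalty; fuel-synthesis conversion adds
#' process emissions). Override per scenario via [scenario_spec()].
#'
#' @return Named list of named kappa vectors, one per scenario.
#' @export
default_kappa <- function() {
  ccu <- c(`PM2.5` = 1.05, CO = 1.10, SO2 = 1.20, NO2 = 1.30)
  list(
    `DAC-CCS` = c(`PM2.5` = 1.05, CO = 1.05, SO2 = 1.05, NO2 = 1.05),
    `DAC-CCU` = ccu,
    `PSC-CCS` = c(`PM2.5` = 0.85, CO = 0.95, SO2 = 0.60, NO2 = 0.85),
    `PSC-CCU` = ccu
  )
}

#' Default specs for all four scenarios
#'
#' @param ramp A [ramp_schedule()] shared by all pathways.
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function(ramp = ramp_schedule()) {
  setNames(lapply(SCENARIO_IDS, scenario_spec, ramp = ramp), SCENARIO_IDS)
}

#' Apply a CCUS scenario to a BAU inventory
#'
#' Local pollutants are scaled by the ramped multiplier:
#' `mass_s(y) = mass_bau(y) * (1 + f(y) * (kappa_p - 1))`. CO2 mass at the
#' source is unchanged; an `offset_tonnes` column records the CO2 removed
#' (CCS: captured and stored; CCU: fossil CO2 displaced by synthetic fuel,
#' times the neutrality factor), so net CO2 is `mass - offset_tonnes`.
#'
#' @param bau BAU inventory from [generate_bau_emissions()].
#' @param spec A [scenario_spec()].
#' @return Inventory tibble with `scenario_id` and `offset_tonnes` columns.
#' @export
apply_scenario <- function(bau, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  check_that(all(bau$pollutant %in% POLLUTANTS),
             "inventory contains an unknown pollutant")
  f <- ramp_fraction(bau$year, spec$ramp)
  kappa <- spec$pollutant_multipliers
  is_co2 <- bau$pollutant == "CO2"
  k <- ifelse(is_co2, 1, kappa[bau$pollutant])
  neut <- if (spec$fate == "CCU") spec$ccu_neutrality else 1
  dplyr::mutate(
    bau,
    scenario_id = spec$scenario_id,
    mass = .data$mass * (1 + f * (k - 1)),
    offset_tonnes = ifelse(is_co2, f * neut * bau$mass, 0)
  )
}

#' CO2 saved relative to BAU (SNC)
#'
#' The saved net carbon for a year is the difference between net BAU CO2 and
#' net scenario CO2, offsets included. For CCS pathways at full deployment
#' this equals the whole BAU CO2 mass (emissions completely offset).
#'
#' @param bau BAU inventory.
#' @param scenario_inventory Output of [apply_scenario()].
#' @param spec The matching [scenario_spec()].
#' @param year Year to evaluate.
#' @return Tonnes of CO2 saved in that year (summed over airports).
#' @export
co2_saved <- function(bau, scenario_inventory, spec, year) {
  check_that(year %in% bau$year && year %in% scenario_inventory$year,
             paste0("year ", year, " not covered by both inventories"))
  bau_co2 <- sum(bau$mass[bau$pollutant == "CO2" & bau$year == year])
  s <- scenario_inventory[scenario_inventory$pollutant == "CO2" &
                            scenario_inventory$year == year, ]
  scen_net <- sum(s$mass - s$offset_tonnes)
  bau_co2 - scen_net
}

#' Alternative-energy and displaced-fuel tonnages
#'
#' At deployment fraction `f` the pathway covers `f` of BAU fuel service:
#' for CCU that tonnage is synthetic fuel produced; for CCS it is the fuel
#' tonnage whose emissions are offset. The same tonnage of conventional
#' JET-A purchases is displaced, so `NA = NJ = f * bau_fuel`.
#'
#' @param bau_fuel BAU jet-fuel consumption in the year, tonnes.
#' @param spec A [scenario_spec()].
#' @param year Year to evaluate.
#' @return Named vector `c(NA_t = ..., NJ_t = ...)` in tonnes.
#' @export
fuel_quantities <- function(bau_fuel, spec, year) {
  check_that(bau_fuel >= 0, "bau_fuel must be >= 0")
  f <- ramp_fraction(year, spec$ramp)
  c(NA_t = f * bau_fuel, NJ_t = f * bau_fuel)
}

#' Write scenario specs to YAML
#'
#' @param specs Named list from [default_scenarios()].
#' @param path Output file (`scenarios.yaml`).
#' @return Invisibly, `path`.
#' @export
write_scenarios_yaml <- function(specs, path) {
  yaml::write_yaml(lapply(specs, function(s) {
    list(scenario_id = s$scenario_id, capture_mode = s$capture_mode,
         fate = s$fate,
         ramp = s$ramp,
         pollutant_multipliers = as.list(s$pollutant_multipliers),
         ccu_neutrality = s$ccu_neutrality)
  }), path)
  invisible(path)
}

#' Read scenario specs from YAML
#'
#' @param path YAML file written by [write_scenarios_yaml()].
#' @return Named list of [scenario_spec()] objects.
#' @export
read_scenarios_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(s) {
    scenario_spec(
      s$scenario_id,
      pollutant_multipliers = unlist(s$pollutant_multipliers),
      ramp = ramp_schedule(s$ramp$start_year, s$ramp$end_year),
      ccu_neutrality = s$ccu_neutrality
    )
  })
  setNames(specs, vapply(specs, function(s) s$scenario_id, character(1)))
}
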