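#' Published per-ton fuel-cost anchors for the four pathways
#'
#' 2020 and 2050 cost per tonne of fuel (USD/t): DAC-CCS 2649.90 falling to
#' 1144.30; DAC-CCU 7549.90 to 4062.50; PSC-CCS 856.65 to 697.00; PSC-CCU
#' 4283.25 to 3252.88.
#'
#' @return Tibble with `scenario_id`, `anchor_2020`, `anchor_2050`.
#' @export
default_cost_schedule <- function() {
  tibble::tibble(
    scenario_id = SCENARIO_IDS,
    anchor_2020 = c(2649.90, 7549.90, 856.65, 4283.25),
    anchor_2050 = c(1144.30, 4062.50, 697.00, 3252.88)
  )
}

#' Pathway fuel cost per tonne in a given year
#'
#' Interpolates between the 2020 and 2050 anchors. Linear interpolation by
#' default; an exponential-decay alternative (constant annual decline rate
#' hitting the same anchors) is available via `method = "exponential"`.
#'
#' @param scenario_id One of the four pathway ids.
#' @param year Year in \[2020, 2050\] (vectorised).
#' @param schedule Tibble from [default_cost_schedule()].
#' @param method `"linear"` (default) or `"exponential"`.
#' @return Cost of the alternative-energy pathway, USD per tonne of fuel.
#' @export
cost_per_ton <- function(scenario_id, year,
                         schedule = default_cost_schedule(),
                         method = c("linear", "exponential")) {
  method <- match.arg(method)
  row <- schedule[schedule$scenario_id == scenario_id, ]
  check_that(nrow(row) == 1,
             paste0("unknown scenario_id: ", scenario_id))
  check_that(all(row$anchor_2020 > 0 & row$anchor_2050 > 0),
             "cost anchors must be > 0")
  check_that(all(year >= 2020 & year <= 2050),
             "year must lie in [2020, 2050]")
  w <- (year - 2020) / 30
  if (method == "linear") {
    (1 - w) * row$anchor_2020 + w * row$anchor_2050
  } else {
    row$anchor_2020 * (row$anchor_2050 / row$anchor_2020)^w
  }
}

#' Default JET-A and carbon price series
#'
#' Stand-in price paths, flagged non-authoritative and overridable by CSV:
#' JET-A flat at 600 USD/t over 2024-2050; carbon price rising linearly from
#' 8 to 18 USD/t (low bound) and 12 to 28 USD/t (high bound). The levels are
#' calibrated once, analytically, so the packaged world reproduces the
#' study's qualitative economics: with roughly 3.16 t CO2 saved per tonne of
#' fuel covered, carbon revenue per tonne of fuel (3.16 x carbon price) must
#' stay below even the cheapest pathway's cost margin over JET-A (697 - 600
#' = 97 USD/t in 2050) for every net-benefit band to remain negative, with
#' the point-source storage pathway least negative. See the methods
#' vignette.
#'
#' @param path Optional CSV with columns `year`, `jet_a_price`,
#'   `carbon_price_low`, `carbon_price_high`.
#' @return Tibble `PriceSeries`.
#' @export
default_price_series <- function(path = NULL) {
  if (!is.null(path)) {
    ps <- readr::read_csv(path, show_col_types = FALSE)
  } else {
    years <- 2024:2050
    w <- (years - 2024) / (2050 - 2024)
    ps <- tibble::tibble(
      year = years,
      jet_a_price = 600,
      carbon_price_low = 8 + w * (18 - 8),
      carbon_price_high = 12 + w * (28 - 12)
    )
  }
  check_that(all(ps$jet_a_price > 0 & ps$carbon_price_low > 0 &
                   ps$carbon_price_high > 0), "prices must be > 0")
  check_that(all(ps$carbon_price_low <= ps$carbon_price_high),
             "carbon_price_low must not exceed carbon_price_high")
  ps
}

#' Cost of alternative-energy adoption
#'
#' `CAE = NA * PA` (alternative-energy cost), `CJF = NJ * PJ` (displaced
#' jet-fuel cost), `C = CAE - CJF`. `C` may be negative if the alternative
#' is cheaper than the displaced JET-A.
#'
#' @param NA_t Alternative-energy quantity, tonnes (>= 0).
#' @param PA Alternative-energy price, USD/t (> 0).
#' @param NJ_t Displaced jet-fuel quantity, tonnes (>= 0).
#' @param PJ JET-A price, USD/t (> 0).
#' @return Named vector `c(CAE = ..., CJF = ..., C = ...)`, USD.
#' @export
pathway_cost <- function(NA_t, PA, NJ_t, PJ) {
  check_that(NA_t >= 0 && NJ_t >= 0, "quantities must be >= 0")
  check_that(PA > 0 && PJ > 0, "prices must be > 0")
  cae <- NA_t * PA
  cjf <- NJ_t * PJ
  c(CAE = cae, CJF = cjf, C = cae - cjf)
}

#' Carbon revenue band
#'
#' `Re = SNC * PC` evaluated at the low and high carbon price.
#'
#' @param SNC Saved net carbon, tonnes CO2 (>= 0).
#' @param PC_min,PC_max Carbon price band, USD/t.
#' @return Named vector `c(Re_min = ..., Re_max = ...)`, USD.
#' @export
revenue <- function(SNC, PC_min, PC_max) {
  check_that(SNC >= 0, "SNC must be >= 0")
  check_that(PC_min <= PC_max, "PC_min must not exceed PC_max")
  c(Re_min = SNC * PC_min, Re_max = SNC * PC_max)
}

#' Assemble cost-benefit rows
#'
#' Net benefit `N = Re - C` applied at each band edge, so
#' `N_min = Re_min - C` and `N_max = Re_max - C`.
#'
#' @param rows Tibble with columns `year`, `scenario_id`, `CAE`, `CJF`, `C`,
#'   `Re_min`, `Re_max` (one row per scenario-year).
#' @return The input with `N_min`, `N_max` columns appended.
#' @export
net_benefit <- function(rows) {
  need <- c("year", "scenario_id", "C", "Re_min", "Re_max")
  check_that(all(need %in% names(rows)),
             "rows must carry year, scenario_id, C, Re_min, Re_max")
  check_that(!anyNA(rows[need]), "mismatched year coverage (NA in inputs)")
  dplyr::mutate(rows,
                N_min = .data$Re_min - .data$C,
                N_max = .data$Re_max - .data$C)
}

#' Cost-benefit table for one scenario over its ramp years
#'
#' For each year: deployment fraction from the ramp, BAU fuel inferred from
#' the BAU CO2 inventory (CO2 per tonne of fuel from the world config),
#' alternative/displaced tonnages from [fuel_quantities()], pathway price
#' from [cost_per_ton()], saved carbon from [co2_saved()], and the
#' `C`/`Re`/`N` chain from the cost-benefit equations.
#'
#' @param bau BAU inventory.
#' @param spec A [scenario_spec()].
#' @param config A [world_config()] (for the CO2-per-fuel factor).
#' @param prices Price series from [default_price_series()].
#' @param schedule Cost schedule from [default_cost_schedule()].
#' @param years Years to evaluate (default: inventory years present in the
#'   price series).
#' @return Tibble of `CostBenefitRow`s.
#' @export
cost_benefit_table <- function(bau, spec, config = world_config(),
                               prices = default_price_series(),
                               schedule = default_cost_schedule(),
                               years = NULL) {
  inv_years <- sort(unique(bau$year))
  if (is.null(years)) years <- intersect(inv_years, prices$year)
  check_that(all(years %in% inv_years), "years must be covered by the inventory")
  check_that(all(years %in% prices$year), "years must be covered by the prices")
  scen <- apply_scenario(bau, spec)
  purrr::map_dfr(years, function(y) {
    p <- prices[prices$year == y, ]
    bau_co2 <- sum(bau$mass[bau$pollutant == "CO2" & bau$year == y])
    bau_fuel <- bau_co2 / config$co2_per_fuel_t
    q <- fuel_quantities(bau_fuel, spec, y)
    pa <- cost_per_ton(spec$scenario_id, y, schedule)
    cost <- pathway_cost(q[["NA_t"]], pa, q[["NJ_t"]], p$jet_a_price)
    snc <- co2_saved(bau, scen, spec, y)
    re <- revenue(snc, p$carbon_price_low, p$carbon_price_high)
    tibble::tibble(
      year = y, scenario_id = spec$scenario_id,
      NA_t = q[["NA_t"]], PA = pa, NJ_t = q[["NJ_t"]], PJ = p$jet_a_price,
      SNC = snc, PC_min = p$carbon_price_low, PC_max = p$carbon_price_high,
      CAE = cost[["CAE"]], CJF = cost[["CJF"]], C = cost[["C"]],
      Re_min = re[["Re_min"]], Re_max = re[["Re_max"]]
    )
  }) |>
    net_benefit()
}
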