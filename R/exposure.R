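#' Packaged exposure-response parameter table
#'
#' Ten disease-pollutant rows. The six PM2.5 causes use the GEMM (Global
#' Exposure Mortality Model) hazard-ratio form with cause-level parameters
#' theta, alpha, mu, nu and counterfactual 2.4 micrograms/m3; the type 2
#' diabetes row is a synthetic GEMM-form extension (the original GEMM covers
#' five causes) and is flagged as such in its `note`. The four gaseous
#' causes (CO and SO2 cardiovascular/cerebrovascular disease, NO2 and SO2
#' respiratory disease) use a log-linear relative risk per `per_unit`
#' micrograms/m3 with placeholder, overridable slopes. `min_age` gives the
#' youngest eligible 5-year band (25 for adult-onset PM2.5 causes, 0
#' otherwise); an optional `age_band` column allows age-specific rows that
#' override the all-age row for that band.
#'
#' @param path Optional path to a CSV with the same schema (to supply your
#'   own coefficients).
#' @return Tibble of exposure-response parameters.
#' @export
default_erf_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "erf_table.csv", package = "ccusair")
  }
  erf <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           age_band = readr::col_character(),
                           note = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  validate_erf_table(erf)
  erf
}

validate_erf_table <- function(erf) {
  check_that(all(erf$form %in% c("GEMM", "log-linear")),
             "form must be GEMM or log-linear")
  g <- erf[erf$form == "GEMM", ]
  check_that(all(!is.na(g$theta) & !is.na(g$alpha) & !is.na(g$mu) &
                   !is.na(g$nu) & !is.na(g$z_cf)),
             "GEMM rows must populate theta, alpha, mu, nu, z_cf")
  check_that(all(g$alpha > 0 & g$nu > 0), "GEMM rows need alpha > 0, nu > 0")
  l <- erf[erf$form == "log-linear", ]
  check_that(all(!is.na(l$beta) & !is.na(l$c0) & !is.na(l$per_unit)),
             "log-linear rows must populate beta, c0, per_unit")
  base <- erf[is.na(erf$age_band), ]
  check_that(all(disease_ids() %in% base$disease_id),
             "table must cover all ten disease categories with all-age rows")
  invisible(erf)
}

#' GEMM hazard ratio
#'
#' `z = max(0, C - z_cf)`;
#' `HR = exp( theta * log(1 + z/alpha) / (1 + exp(-(z - mu)/nu)) )`.
#' Below the counterfactual concentration the hazard ratio is exactly 1.
#'
#' @param C Concentration in micrograms/m3 (vectorised).
#' @param params A single GEMM row of the ERF table (data frame or list).
#' @return Hazard ratio (>= 1 for theta >= 0, non-decreasing in C).
#' @export
gemm_hazard_ratio <- function(C, params) {
  check_that(params$form == "GEMM", "gemm_hazard_ratio needs a GEMM row")
  z <- pmax(0, C - params$z_cf)
  exp(params$theta * log(1 + z / params$alpha) /
        (1 + exp(-(z - params$mu) / params$nu)))
}

#' Log-linear relative risk
#'
#' `RR = exp( beta * max(0, C - c0) / per_unit )` — the slope `beta` is
#' expressed per `per_unit` micrograms/m3 increment (10 for the SO2/NO2
#' rows, 1000 i.e. per mg/m3 for the CO row).
#'
#' @param C Concentration in micrograms/m3 (vectorised).
#' @param params A single log-linear ERF row.
#' @return Relative risk (>= 1 for beta >= 0).
#' @export
loglinear_rr <- function(C, params) {
  check_that(params$form == "log-linear", "loglinear_rr needs a log-linear row")
  per_unit <- if (is.null(params$per_unit) || is.na(params$per_unit)) 10 else
    params$per_unit
  c0 <- if (is.null(params$c0) || is.na(params$c0)) 0 else params$c0
  exp(params$beta * pmax(0, C - c0) / per_unit)
}

#' Population attributable fraction
#'
#' `PAF = (RR - 1) / RR`, the share of baseline deaths in an exposed stratum
#' attributable to the exposure.
#'
#' @param RR Relative risk or hazard ratio, >= 1 (vectorised).
#' @return Fraction in [0, 1).
#' @export
attributable_fraction <- function(RR) {
  check_that(all(RR >= 1), "RR must be >= 1")
  (RR - 1) / RR
}

# expand the ERF table to one parameter row per (disease, age_band), with
# age-specific rows overriding the all-age row for their band
expand_erf <- function(erf) {
  bands <- age_bands()
  base <- erf[is.na(erf$age_band), ]
  specific <- erf[!is.na(erf$age_band), ]
  grid <- tidyr::expand_grid(
    dplyr::select(base, -"age_band"), age_band = bands
  )
  grid <- grid[age_band_lower(grid$age_band) >= grid$min_age, ]
  if (nrow(specific) > 0) {
    key_s <- paste(specific$disease_id, specific$age_band)
    grid <- grid[!(paste(grid$disease_id, grid$age_band) %in% key_s), ]
    grid <- dplyr::bind_rows(grid, specific)
  }
  grid
}

# vectorised RR over mixed-form parameter rows
erf_relative_risk <- function(C, rows) {
  rr <- numeric(length(C))
  is_g <- rows$form == "GEMM"
  if (any(is_g)) {
    z <- pmax(0, C[is_g] - rows$z_cf[is_g])
    rr[is_g] <- exp(rows$theta[is_g] * log(1 + z / rows$alpha[is_g]) /
                      (1 + exp(-(z - rows$mu[is_g]) / rows$nu[is_g])))
  }
  if (any(!is_g)) {
    rr[!is_g] <- exp(rows$beta[!is_g] *
                       pmax(0, C[!is_g] - rows$c0[!is_g]) /
                       rows$per_unit[!is_g])
  }
  rr
}

#' Attributable deaths per stratum
#'
#' For every concentration record, eligible age band, sex and matching
#' disease: `deaths = count * baseline_rate * PAF(RR(C))`. GEMM causes other
#' than lower respiratory infections apply to ages 25+ only; gaseous causes
#' apply to all ages. Deaths can never exceed the stratum's baseline deaths
#' since PAF < 1.
#'
#' @param concentrations Output of [concentration_table()].
#' @param population Strata tibble (`airport_id`, `age_band`, `sex`, `count`).
#' @param baseline_rates Rates tibble (`disease_id`, `age_band`, `sex`,
#'   `rate`).
#' @param erf_table ERF table from [default_erf_table()].
#' @return Tibble of `MortalityResult` rows with `attributable_deaths`.
#' @export
attributable_deaths <- function(concentrations, population, baseline_rates,
                                erf_table = default_erf_table()) {
  validate_erf_table(erf_table)
  erf_long <- expand_erf(erf_table)

  joined <- dplyr::inner_join(
    concentrations, erf_long,
    by = "pollutant", relationship = "many-to-many"
  )
  joined$RR <- erf_relative_risk(joined$conc_ugm3, joined)
  joined$paf <- (joined$RR - 1) / joined$RR

  keep <- intersect(
    c("airport_id", "year", "scenario_id", "disease_id", "age_band", "paf"),
    names(joined)
  )
  out <- dplyr::inner_join(
    joined[, keep], population,
    by = c("airport_id", "age_band"),
    relationship = "many-to-many"
  )
  out <- dplyr::left_join(
    out, baseline_rates, by = c("disease_id", "age_band", "sex")
  )
  if (anyNA(out$rate)) {
    bad <- out[is.na(out$rate), c("disease_id", "age_band", "sex")]
    bad <- unique(bad)
    abort(paste0(
      "missing baseline rate for stratum ",
      paste(bad$disease_id[1], bad$age_band[1], bad$sex[1], sep = "/")
    ))
  }
  out$attributable_deaths <- out$count * out$rate * out$paf
  cols <- intersect(
    c("airport_id", "year", "scenario_id", "disease_id", "age_band", "sex",
      "attributable_deaths"),
    names(out)
  )
  dplyr::as_tibble(out[, cols])
}

#' Aggregate a mortality table along reporting cuts
#'
#' Grouped sums of attributable deaths; every marginal table sums back to
#' the same grand total.
#'
#' @param results Output of [attributable_deaths()].
#' @param by Character subset of `scenario`, `year`, `sex`, `age_band`,
#'   `disease`, `airport` (empty = grand total).
#' @return Tibble of grouped totals with a `deaths` column.
#' @export
aggregate_mortality <- function(results, by = character()) {
  check_that(nrow(results) > 0, "results must be non-empty")
  key_map <- c(scenario = "scenario_id", year = "year", sex = "sex",
               age_band = "age_band", disease = "disease_id",
               airport = "airport_id")
  bad <- setdiff(by, names(key_map))
  check_that(length(bad) == 0,
             paste0("unknown grouping key(s): ", paste(bad, collapse = ", ")))
  cols <- unname(key_map[by])
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
    dplyr::summarise(deaths = sum(.data$attributable_deaths),
                     .groups = "drop")
}
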