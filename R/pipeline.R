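#' Configuration for a full pipeline run
#'
#' Collects every input of the assessment chain: the master seed, the world
#' scale, the world/dispersion configurations, scenario specs, the
#' exposure-response table and the price/cost schedules. Tables can be
#' supplied as file paths (CSV/YAML, same schemas the pipeline writes) or as
#' in-memory objects.
#'
#' @param seed Master seed driving every random stage.
#' @param n_airports Number of synthetic airports.
#' @param years Assessment years.
#' @param world A [world_config()].
#' @param scenarios Named list of [scenario_spec()]s, or path to a
#'   `scenarios.yaml`.
#' @param erf_table ERF tibble, or path to an `erf_table.csv`.
#' @param prices Price series tibble, or path to a `prices.csv`.
#' @param cost_schedule Cost-anchor tibble.
#' @param dispersion A [dispersion_params()].
#' @param top_k Number of airports in the ranking report.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_airports = 25, years = 2025:2050,
                       world = NULL, scenarios = NULL,
                       erf_table = NULL, prices = NULL,
                       cost_schedule = default_cost_schedule(),
                       dispersion = dispersion_params(),
                       top_k = 10) {
  if (is.null(world)) world <- world_config(years = years)
  if (is.character(scenarios)) scenarios <- read_scenarios_yaml(scenarios)
  if (is.null(scenarios)) scenarios <- default_scenarios()
  if (is.character(erf_table)) erf_table <- default_erf_table(erf_table)
  if (is.null(erf_table)) erf_table <- default_erf_table()
  if (is.character(prices)) prices <- default_price_series(prices)
  if (is.null(prices)) prices <- default_price_series()
  check_that(all(years >= 2025 & years <= 2050) && all(years %in% world$years),
             "year range must be within the supported window (2025-2050)")
  structure(
    list(seed = seed, n_airports = n_airports, years = as.integer(years),
         world = world, scenarios = scenarios, erf_table = erf_table,
         prices = prices, cost_schedule = cost_schedule,
         dispersion = dispersion, top_k = top_k),
    class = "run_config"
  )
}

# pure in-memory evaluation of the whole chain; deterministic in the seed
compute_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  world <- generate_world(config$n_airports, config$seed, config$world)
  world$bau <- world$bau[world$bau$year %in% config$years, ]

  inventories <- lapply(config$scenarios, function(spec) {
    apply_scenario(world$bau, spec)
  })
  concentrations <- dplyr::bind_rows(lapply(inventories, function(inv) {
    concentration_table(inv, world$registry, config$dispersion)
  }))
  mortality <- attributable_deaths(
    concentrations, world$population, world$rates, config$erf_table
  )
  cb_years <- intersect(config$years, config$prices$year)
  cost_benefit <- dplyr::bind_rows(lapply(config$scenarios, function(spec) {
    cost_benefit_table(world$bau, spec, config$world, config$prices,
                       config$cost_schedule, years = cb_years)
  }))
  list(world = world, inventories = inventories,
       concentrations = concentrations, mortality = mortality,
       cost_benefit = cost_benefit)
}

#' Run the full assessment pipeline
#'
#' Generate the synthetic world, apply all scenarios, disperse, estimate
#' attributable mortality and evaluate the cost-benefit chain; write every
#' stage output as CSV plus a JSON manifest with MD5 checksums. All stages
#' are recomputed deterministically from the master seed, so with
#' `resume = TRUE` any deleted intermediate file is regenerated
#' byte-identically while existing files are left untouched.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param resume If `TRUE`, only missing output files are (re)written.
#' @return Invisibly, a result bundle: stage tables plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  res <- compute_pipeline(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- c(
    airports = "airports.csv", population = "population.csv",
    rates = "baseline_rates.csv", bau = "emissions_bau.csv",
    concentrations = "concentrations.csv", mortality = "mortality.csv",
    cost_benefit = "cost_benefit.csv"
  )
  tables <- list(
    airports = res$world$registry, population = res$world$population,
    rates = res$world$rates, bau = res$world$bau,
    concentrations = res$concentrations, mortality = res$mortality,
    cost_benefit = res$cost_benefit
  )
  for (spec in config$scenarios) {
    key <- paste0("emissions_", gsub("-", "_", spec$scenario_id))
    files[key] <- paste0(key, ".csv")
    tables[[key]] <- res$inventories[[spec$scenario_id]]
  }
  for (key in names(files)) {
    path <- file.path(out_dir, files[[key]])
    if (!resume || !file.exists(path)) write_table_csv(tables[[key]], path)
  }

  paths <- file.path(out_dir, files)
  manifest <- list(
    seed = config$seed, n_airports = config$n_airports,
    years = range(config$years),
    scenarios = names(config$scenarios),
    files = as.list(setNames(unname(tools::md5sum(paths)), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(res, list(manifest = manifest, out_dir = out_dir)))
}

#' Write reporting cuts from a result bundle
#'
#' Mirrors the study's reporting: scenario-year totals, sex split, age
#' split, disease split, a top-k airport ranking (in the final assessment
#' year) and the cost-benefit bands. Each cut is written as
#' `report_<cut>.csv`; every mortality cut reconciles with the same grand
#' total.
#'
#' @param bundle Result of [run_pipeline()].
#' @param cuts Character subset of `scenario_year`, `sex`, `age`, `disease`,
#'   `top_airports`, `cost_benefit`.
#' @param out_dir Output directory (default: the bundle's).
#' @param top_k Airports to keep in the ranking.
#' @return Invisibly, a named list of the report tibbles.
#' @export
write_reports <- function(bundle,
                          cuts = c("scenario_year", "sex", "age", "disease",
                                   "top_airports", "cost_benefit"),
                          out_dir = bundle$out_dir, top_k = 10) {
  known <- c("scenario_year", "sex", "age", "disease", "top_airports",
             "cost_benefit")
  bad <- setdiff(cuts, known)
  check_that(length(bad) == 0,
             paste0("unknown report cut(s): ", paste(bad, collapse = ", ")))
  m <- bundle$mortality
  reports <- list()
  if ("scenario_year" %in% cuts) {
    reports$scenario_year <- aggregate_mortality(m, c("scenario", "year"))
  }
  if ("sex" %in% cuts) {
    reports$sex <- aggregate_mortality(m, c("scenario", "year", "sex"))
  }
  if ("age" %in% cuts) {
    reports$age <- aggregate_mortality(m, c("scenario", "year", "age_band"))
  }
  if ("disease" %in% cuts) {
    reports$disease <- aggregate_mortality(m, c("scenario", "year", "disease"))
  }
  if ("top_airports" %in% cuts) {
    final <- max(m$year)
    reports$top_airports <-
      aggregate_mortality(m[m$year == final, ],
                          c("scenario", "airport")) |>
      dplyr::group_by(.data$scenario_id) |>
      dplyr::slice_max(.data$deaths, n = top_k) |>
      dplyr::mutate(rank = dplyr::row_number(), year = final) |>
      dplyr::ungroup()
  }
  if ("cost_benefit" %in% cuts) reports$cost_benefit <- bundle$cost_benefit
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports)) {
      write_table_csv(reports[[nm]],
                      file.path(out_dir, paste0("report_", nm, ".csv")))
    }
  }
  invisible(reports)
}

#' Sensitivity sweep over model parameters
#'
#' Re-evaluates the pipeline once per perturbation and tabulates output
#' deltas against the unperturbed baseline. Supported perturbation targets:
#'
#' * `erf_theta` — shift a GEMM row's theta by `delta_se` standard errors;
#' * `erf_beta` — shift a log-linear row's beta by `delta_se` standard
#'   errors;
#' * `cost_anchor` — multiply a pathway's 2020/2050 cost anchors by
#'   `factor`.
#'
#' @param config Baseline [run_config()].
#' @param perturbations List of perturbations; each a list with `name`,
#'   `target`, and the target's fields (`disease_id` + `delta_se`, or
#'   `scenario_id` + `factor` and optional `anchor` = `"2020"`, `"2050"`,
#'   `"both"`).
#' @return Tibble with one baseline row and one row per perturbation:
#'   total deaths, total cost and net-benefit bounds, plus deltas.
#' @export
sensitivity_sweep <- function(config, perturbations = list()) {
  eval_once <- function(cfg, name) {
    res <- compute_pipeline(cfg)
    tibble::tibble(
      name = name,
      total_deaths = sum(res$mortality$attributable_deaths),
      total_C = sum(res$cost_benefit$C),
      total_N_min = sum(res$cost_benefit$N_min),
      total_N_max = sum(res$cost_benefit$N_max)
    )
  }
  out <- eval_once(config, "baseline")
  for (p in perturbations) {
    cfg <- config
    if (identical(p$target, "erf_theta")) {
      i <- which(cfg$erf_table$disease_id == p$disease_id &
                   cfg$erf_table$form == "GEMM")
      check_that(length(i) > 0,
                 paste0("no GEMM row for disease: ", p$disease_id))
      cfg$erf_table$theta[i] <- pmax(
        0, cfg$erf_table$theta[i] + p$delta_se * cfg$erf_table$theta_se[i]
      )
    } else if (identical(p$target, "erf_beta")) {
      i <- which(cfg$erf_table$disease_id == p$disease_id &
                   cfg$erf_table$form == "log-linear")
      check_that(length(i) > 0,
                 paste0("no log-linear row for disease: ", p$disease_id))
      cfg$erf_table$beta[i] <- pmax(
        0, cfg$erf_table$beta[i] + p$delta_se * cfg$erf_table$beta_se[i]
      )
    } else if (identical(p$target, "cost_anchor")) {
      j <- which(cfg$cost_schedule$scenario_id == p$scenario_id)
      check_that(length(j) == 1,
                 paste0("unknown scenario_id: ", p$scenario_id))
      anchor <- if (is.null(p$anchor)) "both" else p$anchor
      if (anchor %in% c("2020", "both")) {
        cfg$cost_schedule$anchor_2020[j] <-
          cfg$cost_schedule$anchor_2020[j] * p$factor
      }
      if (anchor %in% c("2050", "both")) {
        cfg$cost_schedule$anchor_2050[j] <-
          cfg$cost_schedule$anchor_2050[j] * p$factor
      }
    } else {
      abort(paste0("unknown perturbation target: ", p$target))
    }
    out <- dplyr::bind_rows(out, eval_once(cfg, p$name))
  }
  base <- out[out$name == "baseline", ]
  dplyr::mutate(out,
                delta_deaths = .data$total_deaths - base$total_deaths,
                delta_N_max = .data$total_N_max - base$total_N_max)
}
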