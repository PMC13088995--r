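#' Gaussian-plume dispersion parameters
#'
#' Briggs open-country power-law coefficients for the horizontal and
#' vertical plume spreads, by Pasquill stability class A-F, plus the
#' numerical settings of the disk-mean quadrature.
#'
#' @param stability_class Pasquill letter, `"A"` to `"F"` (default `"D"`,
#'   neutral — the long-term average condition assumed for annual means).
#' @param r_min Inner integration cutoff in metres, avoiding the near-source
#'   singularity of the sector-averaged plume.
#' @param n_quad Number of composite-trapezoid quadrature points.
#' @return A `dispersion_params` list.
#' @export
dispersion_params <- function(stability_class = "D", r_min = 100,
                              n_quad = 2000) {
  check_that(stability_class %in% names(briggs_coefficients()),
             paste0("unknown stability class: ", stability_class))
  check_that(r_min > 0, "r_min must be > 0")
  check_that(n_quad >= 16, "n_quad must be >= 16")
  structure(
    list(stability_class = stability_class, r_min = r_min, n_quad = n_quad),
    class = "dispersion_params"
  )
}

# Briggs (open country) sigma formulas: sigma = a*x*(1 + b*x)^p
briggs_coefficients <- function() {
  list(
    A = list(y = c(0.22, 1e-4, -0.5), z = c(0.20, 0, 0)),
    B = list(y = c(0.16, 1e-4, -0.5), z = c(0.12, 0, 0)),
    C = list(y = c(0.11, 1e-4, -0.5), z = c(0.08, 2e-4, -0.5)),
    D = list(y = c(0.08, 1e-4, -0.5), z = c(0.06, 1.5e-3, -0.5)),
    E = list(y = c(0.06, 1e-4, -0.5), z = c(0.03, 3e-4, -1)),
    F = list(y = c(0.04, 1e-4, -0.5), z = c(0.016, 3e-4, -1))
  )
}

briggs_sigma <- function(x, coef) {
  a <- coef[1]; b <- coef[2]; p <- coef[3]
  a * x * (1 + b * x)^p
}

#' Vertical and horizontal plume spread
#'
#' Briggs open-country forms, e.g. class D vertical:
#' `sigma_z = 0.06 * x * (1 + 0.0015 * x)^(-1/2)`. Strictly positive and
#' non-decreasing in downwind distance for all packaged classes.
#'
#' @param distance Downwind distance in metres (vectorised, must be > 0).
#' @param params A [dispersion_params()].
#' @return Plume spread in metres.
#' @export
sigma_z <- function(distance, params = dispersion_params()) {
  check_that(all(distance > 0), "distance must be > 0")
  briggs_sigma(distance, briggs_coefficients()[[params$stability_class]]$z)
}

#' @rdname sigma_z
#' @export
sigma_y <- function(distance, params = dispersion_params()) {
  check_that(all(distance > 0), "distance must be > 0")
  briggs_sigma(distance, briggs_coefficients()[[params$stability_class]]$y)
}

# sector-averaged ground-level concentration integrand at radius r, g/m^3
# per unit Q/u: sqrt(2/pi) / sigma_z * exp(-H^2 / (2 sigma_z^2)) is the
# crosswind-integrated concentration; division by 2*pi*r distributes it
# uniformly around the compass (handled by the disk-mean formula).
plume_integrand <- function(r, H, params) {
  sz <- sigma_z(r, params)
  sqrt(2 / pi) / sz * exp(-H^2 / (2 * sz^2))
}

#' Disk-mean ground-level concentration from a steady point source
#'
#' With no wind-direction information the crosswind-integrated reflected
#' Gaussian plume is averaged uniformly over the compass (sector averaging),
#' giving a radius-only field; its mean over the exposure disk of radius `R`
#' is
#' \deqn{\bar{C} = \frac{1}{\pi R^2} \int_{r_{min}}^{R}
#'   \sqrt{2/\pi}\, \frac{Q}{u\,\sigma_z(r)}
#'   \exp\!\left(-\frac{H^2}{2\sigma_z(r)^2}\right) dr,}
#' evaluated by a composite trapezoid rule with `n_quad` points and
#' converted to micrograms per cubic metre.
#'
#' @param Q Emission rate, g/s (>= 0).
#' @param u Mean wind speed, m/s (> 0).
#' @param H Effective release height, m.
#' @param R Exposure-disk radius, m (> `r_min`).
#' @param params A [dispersion_params()].
#' @return Disk-mean concentration in micrograms per cubic metre.
#' @export
disk_mean_concentration <- function(Q, u, H = 0, R = 20000,
                                    params = dispersion_params()) {
  check_that(Q >= 0, "Q must be >= 0")
  check_that(u > 0, "u must be > 0")
  check_that(R > params$r_min, "R must exceed r_min")
  if (Q == 0) return(0)
  r <- seq(params$r_min, R, length.out = params$n_quad)
  g <- plume_integrand(r, H, params)
  integral <- sum((g[-1] + g[-length(g)]) / 2 * diff(r))
  (Q / u) * integral / (pi * R^2) * 1e6
}

#' Annual-mass to emission-rate conversion
#'
#' @param mass_t Annual emitted mass, tonnes/year.
#' @return Long-term mean emission rate, g/s.
#' @export
mass_to_rate <- function(mass_t) {
  mass_t * 1e6 / (365.25 * 24 * 3600)
}

#' Disk-mean concentrations for a whole inventory
#'
#' Converts each (airport, year, pollutant) annual mass to a steady emission
#' rate and evaluates [disk_mean_concentration()] with the airport's wind
#' speed, release height and exposure radius. CO2 rows are skipped (no
#' exposure-response pathway uses CO2 concentrations).
#'
#' @param inventory Emission inventory (optionally with `scenario_id`).
#' @param registry Airport registry covering every airport in the inventory.
#' @param params A [dispersion_params()].
#' @return Tibble of concentration records with `conc_ugm3`.
#' @export
concentration_table <- function(inventory, registry,
                                params = dispersion_params()) {
  missing <- setdiff(unique(inventory$airport_id), registry$airport_id)
  check_that(length(missing) == 0,
             paste0("airport(s) missing from registry: ",
                    paste(missing, collapse = ", ")))
  check_that(all(is.finite(registry$mean_wind_speed) &
                   registry$mean_wind_speed > 0),
             paste0("airport missing positive wind speed: ",
                    paste(registry$airport_id[
                      !is.finite(registry$mean_wind_speed) |
                        registry$mean_wind_speed <= 0], collapse = ", ")))
  rows <- inventory[inventory$pollutant != "CO2", , drop = FALSE]
  idx <- match(rows$airport_id, registry$airport_id)
  u <- registry$mean_wind_speed[idx]
  H <- registry$release_height[idx]
  R <- registry$exposure_radius[idx]

  # concentration is linear in Q: evaluate the geometry factor once per
  # airport (u, H, R fixed) and scale by mass
  geom_key <- paste(rows$airport_id)
  uniq <- !duplicated(geom_key)
  unit_conc <- setNames(
    mapply(function(uu, hh, rr) {
      disk_mean_concentration(1, uu, hh, rr, params)
    }, u[uniq], H[uniq], R[uniq]),
    geom_key[uniq]
  )
  out <- dplyr::mutate(
    rows,
    conc_ugm3 = mass_to_rate(.data$mass) * unname(unit_conc[geom_key])
  )
  keep <- intersect(
    c("airport_id", "year", "scenario_id", "pollutant", "conc_ugm3"),
    names(out)
  )
  dplyr::as_tibble(out[, keep])
}
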