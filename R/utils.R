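#' @importFrom rlang abort warn .data
#' @importFrom stats rlnorm rnorm runif setNames
NULL

POLLUTANTS <- c("CO2", "PM2.5", "CO", "SO2", "NO2")
LOCAL_POLLUTANTS <- c("PM2.5", "CO", "SO2", "NO2")
SCENARIO_IDS <- c("DAC-CCS", "DAC-CCU", "PSC-CCS", "PSC-CCU")
SEXES <- c("male", "female")

#' Five-year age bands used throughout the package
#'
#' Twenty bands, "0-4" through "95+", partitioning ages 0 to 95+.
#'
#' @return Character vector of band labels, youngest first.
#' @export
age_bands <- function() {
  c(paste(seq(0, 90, by = 5), seq(4, 94, by = 5), sep = "-"), "95+")
}

# lower edge of an age band, in years
age_band_lower <- function(band) {
  suppressWarnings(low <- as.numeric(sub("-.*", "", band)))
  ifelse(band == "95+", 95, low)
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' One master seed drives the whole pipeline; each stage draws from its own
#' deterministic child seed so stages can be regenerated independently. The
#' derivation is a fixed integer hash of the master seed and the stage name,
#' reduced modulo 2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label (e.g. `"airports"`, `"emissions"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) %% 1000003L) * 2038L + h) %% 2147483647L
}

# run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop() with a consistent prefix naming the offending field
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# deterministic CSV writer: fixed column order, no timestamps, LF endings
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
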