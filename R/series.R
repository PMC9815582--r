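#' Valve sensor series
#'
#' A `valve_series` holds one Hall-effect sensor's record for one clam: a
#' strictly increasing timestamp vector (local clock), the raw reading in
#' millivolts (the Arduino reports 0--5000 mV), and a logical QC mask. Missing
#' ticks are represented by `NA` voltages, never silently interpolated.
#'
#' @param clam_id small integer label for the animal.
#' @param time POSIXct (or numeric seconds) timestamps, strictly increasing.
#' @param mv numeric millivolt readings in `[0, 5000]`; `NA` marks a missing
#'   tick.
#' @param nominal_period_s nominal sampling period in seconds (default 5).
#' @param masked logical vector of the same length; `TRUE` marks samples
#'   excluded by quality control. Defaults to all `FALSE`.
#' @return an object of class `valve_series`.
#' @export
valve_series <- function(clam_id, time, mv, nominal_period_s = 5, masked = NULL) {
  time <- as_clock_time(time)
  mv <- as.numeric(mv)
  if (length(time) != length(mv)) stop("time and mv must have equal length")
  if (length(time) == 0L) stop("empty valve series")
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) {
    stop("timestamps not strictly increasing at position ", which(dt <= 0)[1] + 1L)
  }
  bad <- !is.na(mv) & (mv < 0 | mv > 5000)
  if (any(bad)) stop("voltage outside [0, 5000] mV at position ", which(bad)[1])
  masked <- masked %||% rep(FALSE, length(mv))
  structure(
    list(clam_id = as.integer(clam_id), time = time, mv = mv,
         nominal_period_s = as.numeric(nominal_period_s),
         masked = as.logical(masked)),
    class = "valve_series"
  )
}

#' @export
print.valve_series <- function(x, ...) {
  cat(sprintf("<valve_series> clam %d: %d samples @ %gs, %s .. %s (%.1f%% masked, %.1f%% missing)\n",
              x$clam_id, length(x$mv), x$nominal_period_s,
              format(x$time[1]), format(x$time[length(x$time)]),
              100 * mean(x$masked), 100 * mean(is.na(x$mv))))
  invisible(x)
}

#' Samples usable for analysis (not missing, not QC-masked)
#' @param series a `valve_series`.
#' @return logical vector.
#' @export
valid_samples <- function(series) !is.na(series$mv) & !series$masked

.ENV_VARIABLES <- c("PAR", "pH", "DO", "temperature", "chlorophyll_a", "phycoerythrin")
.ENV_UNITS <- c(PAR = "umol photons/m2s", pH = "pH units", DO = "mg/L",
                temperature = "degC", chlorophyll_a = "RFU", phycoerythrin = "RFU")

#' Environmental sensor series
#'
#' One environmental variable on its own time grid. Unit conventions and
#' validity constraints follow the instrument: PAR and fluorescence (RFU)
#' cannot be negative, dissolved oxygen must be positive.
#'
#' @param variable one of `"PAR"`, `"pH"`, `"DO"`, `"temperature"`,
#'   `"chlorophyll_a"`, `"phycoerythrin"`.
#' @param time POSIXct (or numeric seconds) timestamps, strictly increasing.
#' @param value numeric readings (`NA` allowed).
#' @param units unit string; defaults to the conventional unit per variable.
#' @param nominal_period_s sampling period in seconds; if `NULL`, inferred
#'   from the median spacing (a warning is issued if observed spacings stray
#'   more than 20% from that median — serial logging jitters, larger drifts
#'   signal a clock problem).
#' @return an object of class `env_series`.
#' @export
env_series <- function(variable, time, value, units = NULL, nominal_period_s = NULL) {
  variable <- match.arg(variable, .ENV_VARIABLES)
  time <- as_clock_time(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) stop("time and value must have equal length")
  if (length(time) == 0L) stop("empty environmental series")
  dt <- diff(as.numeric(time))
  if (length(dt) && any(dt <= 0)) {
    stop("timestamps not strictly increasing at position ", which(dt <= 0)[1] + 1L)
  }
  ok <- !is.na(value)
  if (variable %in% c("PAR", "chlorophyll_a", "phycoerythrin") && any(value[ok] < 0))
    stop(variable, " values must be >= 0")
  if (variable == "DO" && any(value[ok] <= 0)) stop("DO values must be > 0")
  if (is.null(nominal_period_s)) {
    nominal_period_s <- if (length(dt)) median(dt) else NA_real_
    if (length(dt) && any(abs(dt - nominal_period_s) > 0.2 * nominal_period_s)) {
      warning("irregular sampling in ", variable,
              " series: spacings deviate >20% from the median of ",
              nominal_period_s, " s")
    }
  }
  structure(
    list(variable = variable, time = time, value = value,
         units = units %||% unname(.ENV_UNITS[variable]),
         nominal_period_s = as.numeric(nominal_period_s)),
    class = "env_series"
  )
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("<env_series> %s [%s]: %d samples @ %gs, %s .. %s\n",
              x$variable, x$units, length(x$value), x$nominal_period_s,
              format(x$time[1]), format(x$time[length(x$time)])))
  invisible(x)
}

series_span <- function(s) c(as.numeric(s$time[1]), as.numeric(s$time[length(s$time)]))
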