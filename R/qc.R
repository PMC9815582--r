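#' Detect rail faults (saltwater intrusion / shorting)
#'
#' A shorted or flooded Hall sensor pins near a supply rail: the trace leaves
#' its normal band around ~2500 mV and sits at nearly 5000 mV or at zero.
#' Every maximal run of at least `min_duration_s` during which the voltage
#' stays at or below `low_mv` (kind `rail_low`) or at or above `high_mv`
#' (kind `rail_high`) is flagged. Single-tick excursions are electrical
#' noise, hence the persistence requirement.
#'
#' QC always inspects the raw trace (masking is kept separately), so running
#' it again on an already-masked series returns identical flags.
#'
#' @param series a [valve_series()].
#' @param low_mv,high_mv rail thresholds in mV (defaults 100 and 4900).
#' @param min_duration_s minimum persistence in seconds (default 300).
#' @return data.frame of flags with columns `clam_id`, `kind`, `start`,
#'   `end`, `detail` (possibly zero rows).
#' @export
detect_rail_fault <- function(series, low_mv = 100, high_mv = 4900,
                              min_duration_s = 300) {
  stopifnot(length(series$mv) > 0)
  dt <- series$nominal_period_s
  flags <- list()
  for (kind in c("rail_low", "rail_high")) {
    hit <- if (kind == "rail_low") series$mv <= low_mv else series$mv >= high_mv
    hit[is.na(hit)] <- FALSE
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths * dt >= min_duration_s)
    if (any(keep)) {
      flags[[kind]] <- data.frame(
        clam_id = series$clam_id,
        kind = kind,
        start = series$time[starts[keep]],
        end = series$time[ends[keep]] + dt,
        detail = sprintf("%d ticks %s %g mV", r$lengths[keep],
                         if (kind == "rail_low") "<=" else ">=",
                         if (kind == "rail_low") low_mv else high_mv),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(flags) == 0L) return(empty_flags())
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

empty_flags <- function() {
  data.frame(clam_id = integer(0), kind = character(0),
             start = as_clock_time(numeric(0)), end = as_clock_time(numeric(0)),
             detail = character(0), stringsAsFactors = FALSE)
}

#' Detect loss of diurnal signal
#'
#' A healthy clam trace is dominated by a ~24-h cycle. For each sliding
#' window of `window_days` (stepped one day at a time) the fraction of
#' periodogram power falling in the 20--28 h band (after mean removal) is
#' computed; windows whose band fraction falls below `power_ratio_min` are
#' flagged `diurnal_loss` and adjacent flagged windows are merged. A window
#' with no variance at all (dead sensor) is flagged too.
#'
#' The default threshold 0.1 sits orders of magnitude above the band
#' fraction of white noise (roughly one Fourier bin out of thousands) and
#' well below that of any visible diurnal cycle; see the package vignette
#' for the calibration.
#'
#' @param series a [valve_series()].
#' @param window_days sliding-window length in days (default 3).
#' @param power_ratio_min minimum 20--28 h band power fraction (default 0.1).
#' @return data.frame of flags as in [detect_rail_fault()].
#' @export
detect_diurnal_loss <- function(series, window_days = 3, power_ratio_min = 0.1) {
  t_s <- as.numeric(series$time)
  span_days <- (t_s[length(t_s)] - t_s[1]) / .DAY_S
  if (span_days < window_days)
    stop("series spans ", round(span_days, 2), " days; need >= ", window_days)
  day0 <- floor(t_s[1] / .DAY_S)
  n_starts <- floor(span_days - window_days) + 1L
  flagged <- logical(n_starts)
  win_start <- (day0 + seq_len(n_starts) - 1L) * .DAY_S
  for (i in seq_len(n_starts)) {
    sel <- t_s >= win_start[i] & t_s < win_start[i] + window_days * .DAY_S
    x <- series$mv[sel]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (!length(x) || !is.finite(x[1])) { flagged[i] <- TRUE; next }
    x <- x - mean(x)
    if (sum(x^2) == 0) { flagged[i] <- TRUE; next }  # dead-flat window
    n <- length(x)
    window_h <- window_days * 24
    p <- Mod(fft(x)[2:(floor(n / 2) + 1)])^2
    k <- seq_along(p)                       # cycles per window
    band <- window_h / k >= 20 & window_h / k <= 28
    flagged[i] <- sum(p[band]) / sum(p) < power_ratio_min
  }
  if (!any(flagged)) return(empty_flags())
  r <- rle(flagged)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    clam_id = series$clam_id, kind = "diurnal_loss",
    start = as_clock_time(win_start[starts[keep]]),
    end = as_clock_time(win_start[ends[keep]] + window_days * .DAY_S),
    detail = sprintf("20-28h band power fraction < %g over %d window(s)",
                     power_ratio_min, r$lengths[keep]),
    stringsAsFactors = FALSE
  )
}

#' Apply QC flags as a mask
#'
#' Marks every sample falling inside a flagged span as masked. The raw
#' voltages are retained (so QC remains idempotent); downstream statistics
#' use [valid_samples()].
#'
#' @param series a [valve_series()].
#' @param flags flag data.frame (rows for other clams are ignored).
#' @return the series with its `masked` field updated.
#' @export
apply_qc_mask <- function(series, flags) {
  f <- flags[flags$clam_id == series$clam_id, , drop = FALSE]
  if (nrow(f) == 0L) return(series)
  t_s <- as.numeric(series$time)
  m <- series$masked
  for (i in seq_len(nrow(f))) {
    m <- m | (t_s >= as.numeric(f$start[i]) & t_s < as.numeric(f$end[i]))
  }
  series$masked <- m
  series
}

#' Run all QC checks and summarize
#'
#' @param series_list list of [valve_series()].
#' @param ... passed to [detect_rail_fault()] / [detect_diurnal_loss()]
#'   (`low_mv`, `high_mv`, `min_duration_s`, `window_days`,
#'   `power_ratio_min`).
#' @param diurnal if `FALSE`, skip the spectral diurnal-loss check (useful
#'   for short spans).
#' @return a `qc_report`: list with `flags` (combined data.frame) and
#'   `masked_fraction` (named per clam: flagged time / span time).
#' @export
qc_report <- function(series_list, ..., diurnal = TRUE) {
  dots <- list(...)
  rail_args <- dots[names(dots) %in% c("low_mv", "high_mv", "min_duration_s")]
  diur_args <- dots[names(dots) %in% c("window_days", "power_ratio_min")]
  flags <- lapply(series_list, function(s) {
    f <- do.call(detect_rail_fault, c(list(s), rail_args))
    if (diurnal) f <- rbind(f, do.call(detect_diurnal_loss, c(list(s), diur_args)))
    f
  })
  flags <- do.call(rbind, flags)
  rownames(flags) <- NULL
  masked_fraction <- vapply(series_list, function(s) {
    sp <- series_span(s)
    f <- flags[flags$clam_id == s$clam_id, , drop = FALSE]
    if (nrow(f) == 0L) return(0)
    # clip flag spans to the series span and merge overlaps before summing
    iv <- cbind(pmax(as.numeric(f$start), sp[1]), pmin(as.numeric(f$end), sp[2]))
    iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
    if (nrow(iv) == 0L) return(0)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    tot <- 0; cur <- iv[1, ]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= cur[2]) cur[2] <- max(cur[2], iv[i, 2])
      else { tot <- tot + cur[2] - cur[1]; cur <- iv[i, ] }
    }
    tot <- tot + cur[2] - cur[1]
    min(1, tot / (sp[2] - sp[1]))
  }, numeric(1))
  names(masked_fraction) <- vapply(series_list, function(s) as.character(s$clam_id), character(1))
  structure(list(flags = flags, masked_fraction = masked_fraction),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d flag(s); masked fraction: %s\n", nrow(x$flags),
              paste(sprintf("clam %s %.1f%%", names(x$masked_fraction),
                            100 * x$masked_fraction), collapse = ", ")))
  invisible(x)
}
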