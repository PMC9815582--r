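#' Read a raw valvometer log
#'
#' Parses the tab-delimited serial-capture dialect: first column a timestamp
#' (`YYYY-mm-dd HH:MM:SS`, `T` separator also accepted), remaining columns
#' integer millivolt readings, optional header line, UTF-8, LF endings.
#' Serial capture occasionally garbles a line; unparseable rows are skipped
#' and counted, but more than `max_skip_fraction` of them aborts the read
#' (that much corruption signals a broken capture, not line noise).
#'
#' @param path path to the log file.
#' @param column_map integer vector assigning a clam id to each sensor column
#'   (in file order, excluding the timestamp column). Default `1..k`.
#' @param nominal_period_s expected tick period in seconds (default 5).
#' @param max_skip_fraction hard-error threshold on the fraction of skipped
#'   rows (default 0.1).
#' @return a list with elements `series` (list of [valve_series()], one per
#'   mapped column), `n_rows` (parseable data rows), and `n_skipped`.
#' @export
read_valve_log <- function(path, column_map = NULL, nominal_period_s = 5,
                           max_skip_fraction = 0.1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty valve log: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first_field <- vapply(parts, `[`, character(1), 1L)
  ts <- parse_clock_timestamp(first_field)
  # header = a first line whose timestamp field does not parse
  has_header <- is.na(ts[1])
  row0 <- if (has_header) 2L else 1L
  if (has_header && length(lines) == 1L) stop("empty valve log (header only): ", path)
  idx <- seq.int(row0, length(lines))
  ts <- ts[idx]; parts <- parts[idx]
  ncols <- vapply(parts, length, integer(1))
  n_sensors <- max(ncols) - 1L
  if (n_sensors < 1L) stop("no sensor columns found in ", path)
  vals <- matrix(NA_real_, nrow = length(parts), ncol = n_sensors)
  full <- ncols == n_sensors + 1L
  if (any(full)) {
    m <- do.call(rbind, parts[full])
    suppressWarnings(storage <- matrix(as.numeric(m[, -1, drop = FALSE]), ncol = n_sensors))
    vals[full, ] <- storage
  }
  ok <- !is.na(ts) & full & rowSums(is.na(vals) |
                                      vals < 0 | vals > 5000) == 0L
  n_skipped <- sum(!ok)
  n_rows <- sum(ok)
  if (n_rows == 0L) stop("no parseable rows in ", path)
  if (n_skipped / length(ok) > max_skip_fraction) {
    stop(sprintf("%d of %d rows unparseable (> %.0f%%): corrupted capture in %s",
                 n_skipped, length(ok), 100 * max_skip_fraction, path))
  }
  ts <- ts[ok]; vals <- vals[ok, , drop = FALSE]
  nondec <- which(diff(as.numeric(ts)) <= 0)
  if (length(nondec)) {
    stop("timestamps not strictly increasing at data row ", nondec[1] + 1L,
         " (", format(as_clock_time(ts[nondec[1] + 1L])), ")")
  }
  column_map <- column_map %||% seq_len(n_sensors)
  if (length(column_map) != n_sensors)
    stop("column_map has ", length(column_map), " entries for ", n_sensors, " sensor columns")
  series <- lapply(seq_len(n_sensors), function(j) {
    valve_series(clam_id = column_map[j], time = ts, mv = vals[, j],
                 nominal_period_s = nominal_period_s)
  })
  list(series = series, n_rows = n_rows, n_skipped = n_skipped)
}

parse_clock_timestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  out
}

#' Read an environmental logger CSV export
#'
#' Expects a header row, one timestamp column and one value column (named via
#' `time_col`/`value_col`, defaulting to the first and second columns).
#' Negative PAR or fluorescence readings are an instrument artifact near the
#' detection limit; they are clipped to zero and counted.
#'
#' @param path CSV path.
#' @param variable variable name, one of the [env_series()] set.
#' @param units optional unit override.
#' @param time_col,value_col column names (or `NULL` for positional).
#' @return an [env_series()]; attributes `n_clipped` (negative values clipped
#'   to 0 for PAR/RFU) and `n_missing` record what was altered or dropped.
#' @export
read_env_csv <- function(path, variable, units = NULL,
                         time_col = NULL, value_col = NULL) {
  variable <- match.arg(variable, .ENV_VARIABLES)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty environmental CSV: ", path)
  tcol <- if (is.null(time_col)) 1L else match(time_col, names(df))
  vcol <- if (is.null(value_col)) 2L else match(value_col, names(df))
  if (is.na(tcol) || is.na(vcol)) stop("requested columns not found in ", path)
  ts <- parse_clock_timestamp(as.character(df[[tcol]]))
  val <- suppressWarnings(as.numeric(df[[vcol]]))
  keep <- !is.na(ts)
  ts <- ts[keep]; val <- val[keep]
  if (all(is.na(val))) stop("value column is entirely missing in ", path)
  n_clipped <- 0L
  if (variable %in% c("PAR", "chlorophyll_a", "phycoerythrin")) {
    neg <- !is.na(val) & val < 0
    n_clipped <- sum(neg)
    val[neg] <- 0
  }
  out <- env_series(variable, ts, val, units = units)
  attr(out, "n_clipped") <- n_clipped
  attr(out, "n_missing") <- sum(is.na(val))
  out
}

window_mean <- function(time_s, value, grid_s, span) {
  # non-overlapping windows [t0 + k*grid, t0 + (k+1)*grid) inside span
  t0 <- ceiling(span[1] / grid_s) * grid_s
  K <- floor((span[2] - t0) / grid_s)
  if (K < 1) stop("no complete averaging window inside the common span")
  inside <- time_s >= t0 & time_s < t0 + K * grid_s & !is.na(value)
  idx <- floor((time_s[inside] - t0) / grid_s) + 1
  sums <- tabulate0(idx, K, value[inside])
  cnts <- tabulate0(idx, K, rep(1, sum(inside)))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_   # empty window -> explicit missing marker
  list(time = t0 + (seq_len(K) - 1) * grid_s + grid_s / 2, value = out,
       window_start = t0 + (seq_len(K) - 1) * grid_s)
}

tabulate0 <- function(idx, nbins, w) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Align valve and environmental series onto common time grids
#'
#' Averages every valve series into non-overlapping windows of
#' `valve_grid_s` seconds (the arithmetic mean of available ticks; a window
#' with no ticks becomes `NA`), every environmental series onto
#' `env_grid_s`, restricted to the closed time span common to all inputs.
#' Window timestamps are window centers. Averaging to minute resolution is
#' the usual configuration before rhythm analysis.
#'
#' @param valve list of [valve_series()].
#' @param env list of [env_series()] (may be empty).
#' @param valve_grid_s,env_grid_s target grids in seconds.
#' @return an `aligned_dataset`: list with `valve` (list of `valve_series` on
#'   the valve grid), `env` (named list of `env_series` on the env grid),
#'   `span` (POSIXct length 2), and the two grid steps.
#' @export
align_dataset <- function(valve, env = list(), valve_grid_s = 60, env_grid_s = 900) {
  if (length(valve) < 1L) stop("at least one valve series is required")
  # a sample at t covers [t, t + period), so each span ends one period
  # after its last sample
  spans <- lapply(c(valve, env), function(s) {
    series_span(s) + c(0, s$nominal_period_s)
  })
  span <- c(max(vapply(spans, `[`, numeric(1), 1L)),
            min(vapply(spans, `[`, numeric(1), 2L)))
  if (span[2] <= span[1]) stop("inputs have no temporal overlap")
  valve_out <- lapply(valve, function(s) {
    wm <- window_mean(as.numeric(s$time), ifelse(s$masked, NA, s$mv), valve_grid_s, span)
    valve_series(s$clam_id, wm$time, wm$value, nominal_period_s = valve_grid_s)
  })
  env_out <- lapply(env, function(s) {
    wm <- window_mean(as.numeric(s$time), s$value, env_grid_s, span)
    env_series(s$variable, wm$time, wm$value, units = s$units,
               nominal_period_s = env_grid_s)
  })
  names(env_out) <- vapply(env, `[[`, character(1), "variable")
  structure(
    list(valve = valve_out, env = env_out,
         span = as_clock_time(span),
         valve_grid_s = valve_grid_s, env_grid_s = env_grid_s),
    class = "aligned_dataset"
  )
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset> %d clam(s) @ %gs, %d env series @ %gs, %s .. %s\n",
              length(x$valve), x$valve_grid_s, length(x$env), x$env_grid_s,
              format(x$span[1]), format(x$span[2])))
  invisible(x)
}
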