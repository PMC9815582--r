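#' Daily z-score normalization of a valve trace
#'
#' Hall-sensor voltages drift day to day (magnet geometry, neighboring
#' animals), so gape is standardized within each local calendar day:
#' `z_t = (mV_t - mu_day) / SD_day`, with the sample standard deviation
#' (`n - 1`) by default. Sign ("polarity") is installation-dependent: magnet
#' orientation decides whether closing raises or lowers the voltage.
#' `polarity = "auto"` chooses the orientation under which the dark-hours
#' median exceeds the bright-hours median (clams close in the dark), which
#' requires a [light_partition()]. After polarity is applied, larger z means
#' more closed.
#'
#' Days with less than `min_coverage` of their expected ticks valid, or with
#' zero variance, are dropped with a warning and reported in `dropped_days`.
#'
#' @param series a QC-masked [valve_series()] (any grid).
#' @param polarity `"closure_positive"`, `"closure_negative"`, or `"auto"`.
#' @param partition a [light_partition()] (required for `"auto"`).
#' @param min_coverage minimum fraction of a day's expected samples that must
#'   be valid (default 0.5).
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return a `gape_series`: list with `clam_id`, `time`, `z`, `pct_closure`
#'   (all `NA` until [percent_closure()]), `day_params` (per-day date, mu,
#'   sd, z_min, z_max, n_valid), `dropped_days`, and `polarity_flipped`.
#' @export
daily_zscore <- function(series, polarity = c("auto", "closure_positive", "closure_negative"),
                         partition = NULL, min_coverage = 0.5,
                         sd_type = c("sample", "population")) {
  polarity <- match.arg(polarity)
  sd_type <- match.arg(sd_type)
  ok <- valid_samples(series)
  day <- local_day(series$time)
  days <- sort(unique(day))
  expected <- .DAY_S / series$nominal_period_s
  mv <- ifelse(ok, series$mv, NA_real_)

  g <- factor(day, levels = days)
  n_valid <- as.integer(tapply(!is.na(mv), g, sum))
  mu <- as.numeric(tapply(mv, g, mean, na.rm = TRUE))
  ss <- as.numeric(tapply(mv, g, function(v) sum((v - mean(v, na.rm = TRUE))^2, na.rm = TRUE)))
  denom <- if (sd_type == "sample") pmax(n_valid - 1L, 0L) else n_valid
  sdv <- sqrt(ss / denom)

  low_cov <- n_valid < min_coverage * expected
  zero_sd <- !low_cov & (!is.finite(sdv) | sdv == 0)
  keep_day <- !low_cov & !zero_sd
  if (any(zero_sd)) {
    warning("constant-voltage day(s) dropped (SD = 0): ",
            paste(as.Date(days[zero_sd], origin = "1970-01-01"), collapse = ", "),
            call. = FALSE)
  }
  if (any(low_cov)) {
    warning(sum(low_cov), " day(s) dropped below ", 100 * min_coverage,
            "% coverage for clam ", series$clam_id, call. = FALSE)
  }
  di <- match(day, days)
  z <- (mv - mu[di]) / sdv[di]
  z[!keep_day[di]] <- NA_real_

  flipped <- polarity == "closure_negative"
  if (polarity == "auto") {
    if (is.null(partition)) stop("polarity = \"auto\" requires a light partition")
    reg <- partition_at(partition, series$time)
    dark_med <- median(z[reg == "dark"], na.rm = TRUE)
    bright_med <- median(z[reg == "bright"], na.rm = TRUE)
    if (!is.finite(dark_med) || !is.finite(bright_med))
      stop("auto polarity needs data in both dark and bright regimes")
    flipped <- dark_med < bright_med
  }
  if (flipped) z <- -z

  dp <- data.frame(
    date = as.Date(days[keep_day], origin = "1970-01-01"),
    mu = mu[keep_day], sd = sdv[keep_day],
    z_min = rep(NA_real_, sum(keep_day)), z_max = rep(NA_real_, sum(keep_day)),
    n_valid = n_valid[keep_day]
  )
  for (i in seq_len(nrow(dp))) {
    zi <- z[di == which(keep_day)[i]]
    dp$z_min[i] <- min(zi, na.rm = TRUE)
    dp$z_max[i] <- max(zi, na.rm = TRUE)
  }
  dropped <- data.frame(
    date = as.Date(days[!keep_day], origin = "1970-01-01"),
    reason = ifelse(zero_sd[!keep_day], "zero_sd", "low_coverage")
  )
  structure(
    list(clam_id = series$clam_id, time = series$time, z = z,
         pct_closure = rep(NA_real_, length(z)),
         day_params = dp, dropped_days = dropped,
         polarity_flipped = flipped),
    class = "gape_series"
  )
}

#' @export
print.gape_series <- function(x, ...) {
  cat(sprintf("<gape_series> clam %d: %d samples, %d complete day(s), %d dropped%s\n",
              x$clam_id, length(x$z), nrow(x$day_params), nrow(x$dropped_days),
              if (x$polarity_flipped) ", polarity flipped" else ""))
  invisible(x)
}

#' Percent closure from daily z-scores
#'
#' Rescales each day's z-scores to that day's observed range:
#' `pct_t = (z_t - z_dailymin) / (z_dailymax - z_dailymin) * 100`, so within
#' every retained day the most-open sample maps to 0% and the most-closed to
#' 100%. Days whose z range is degenerate are dropped with a warning.
#'
#' @param gape a `gape_series` from [daily_zscore()].
#' @return the `gape_series` with `pct_closure` filled.
#' @export
percent_closure <- function(gape) {
  dp <- gape$day_params
  degen <- dp$z_max <= dp$z_min
  if (any(degen)) {
    warning("day(s) with degenerate z range dropped: ",
            paste(dp$date[degen], collapse = ", "), call. = FALSE)
    gape$dropped_days <- rbind(gape$dropped_days,
                               data.frame(date = dp$date[degen], reason = "degenerate_range"))
  }
  day <- local_day(gape$time)
  di <- match(as.Date(day, origin = "1970-01-01"), dp$date)
  zmin <- dp$z_min[di]; zmax <- dp$z_max[di]
  pct <- (gape$z - zmin) / (zmax - zmin) * 100
  pct[!is.na(di) & degen[di]] <- NA_real_
  gape$pct_closure <- pct
  gape$day_params <- dp[!degen, , drop = FALSE]
  gape
}

#' Partition time by light regime
#'
#' Classifies instants into `dark` (hourly mean PAR below `dark_max`, i.e.
#' light virtually absent), `bright` (instantaneous PAR above `bright_min`,
#' full basking light), and `low_light` otherwise. Hourly means are computed
#' on clock-hour windows; `dark` takes precedence where the two rules could
#' disagree. Instants whose PAR is missing are labeled from the nearest
#' labeled hour and counted in `n_gap_filled`.
#'
#' @param par an [env_series()] of PAR.
#' @param dark_max hourly-mean threshold for darkness (default 5
#'   umol photons/m2s).
#' @param bright_min instantaneous threshold for full light (default 100).
#' @return a `light_partition`: list with `time`, `regime` (factor dark /
#'   low_light / bright), `hour_mean` (per clock hour), `thresholds`,
#'   `n_gap_filled`.
#' @export
light_partition <- function(par, dark_max = 5, bright_min = 100) {
  stopifnot(inherits(par, "env_series"), par$variable == "PAR")
  t_s <- as.numeric(par$time)
  hour <- floor(t_s / .HOUR_S)
  hours <- sort(unique(hour))
  hm <- as.numeric(tapply(par$value, factor(hour, levels = hours), mean, na.rm = TRUE))
  gap_hours <- !is.finite(hm)
  n_gap <- 0L
  if (any(gap_hours)) {
    # nearest labeled hour carries its label across the gap
    lab <- which(!gap_hours)
    if (length(lab) == 0L) stop("PAR series has no usable values")
    nearest <- lab[pmax(1L, findInterval(which(gap_hours), lab))]
    # findInterval gives the labeled hour at/before; choose the closer side
    for (k in seq_along(nearest)) {
      i <- which(gap_hours)[k]
      cand <- lab[order(abs(lab - i))][1]
      hm[i] <- hm[cand]
    }
    n_gap <- sum(gap_hours)
  }
  hi <- match(hour, hours)
  inst <- par$value
  if (anyNA(inst)) {
    missing_i <- which(is.na(inst))
    inst[missing_i] <- hm[hi[missing_i]]
    n_gap <- n_gap + length(missing_i)
  }
  regime <- ifelse(hm[hi] < dark_max, "dark",
                   ifelse(inst > bright_min, "bright", "low_light"))
  structure(
    list(time = par$time, regime = factor(regime, levels = c("dark", "low_light", "bright")),
         hour = hours, hour_mean = hm,
         thresholds = c(dark_max = dark_max, bright_min = bright_min),
         n_gap_filled = n_gap),
    class = "light_partition"
  )
}

#' Look up light regimes at arbitrary times
#'
#' Labels each requested instant with the regime of the nearest partition
#' sample (the partition grid is usually finer than or equal to the target
#' grid).
#'
#' @param partition a [light_partition()].
#' @param time POSIXct vector.
#' @return factor of regimes.
#' @export
partition_at <- function(partition, time) {
  pt <- as.numeric(partition$time)
  tt <- as.numeric(as_clock_time(time))
  i <- findInterval(tt, pt, all.inside = TRUE)
  right <- (pt[pmin(i + 1L, length(pt))] - tt) < (tt - pt[i])
  partition$regime[i + as.integer(right)]
}

#' Closure statistics by light regime
#'
#' Aggregates percent closure within each regime, per clam and pooled.
#'
#' @param gapes a `gape_series` or list of them (with `pct_closure` filled).
#' @param partition a [light_partition()].
#' @param statistic `"mean"` or `"median"`.
#' @param sd also report the standard deviation (default `TRUE`).
#' @return data.frame with columns `clam` ("pooled" or a clam id), `regime`,
#'   `n`, the statistic, and optionally `sd`. Empty regimes yield `NA`.
#' @export
closure_by_regime <- function(gapes, partition, statistic = c("mean", "median"), sd = TRUE) {
  statistic <- match.arg(statistic)
  if (inherits(gapes, "gape_series")) gapes <- list(gapes)
  fun <- if (statistic == "mean") function(v) mean(v, na.rm = TRUE) else function(v) median(v, na.rm = TRUE)
  per <- lapply(gapes, function(g) {
    reg <- partition_at(partition, g$time)
    data.frame(clam = as.character(g$clam_id), regime = reg, pct = g$pct_closure)
  })
  all <- do.call(rbind, per)
  all <- all[!is.na(all$pct), , drop = FALSE]
  groups <- rbind(
    data.frame(clam = all$clam, regime = all$regime, pct = all$pct),
    data.frame(clam = "pooled", regime = all$regime, pct = all$pct)
  )
  out <- expand.grid(clam = unique(groups$clam), regime = levels(all$regime),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out[[statistic]] <- NA_real_
  if (sd) out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- groups$pct[groups$clam == out$clam[i] & groups$regime == out$regime[i]]
    out$n[i] <- length(v)
    if (length(v)) {
      out[[statistic]][i] <- fun(v)
      if (sd) out$sd[i] <- stats::sd(v)
    }
  }
  out
}
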