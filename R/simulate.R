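#' Simulation configuration
#'
#' Defaults emulate the study tank the package was designed around: a glass-
#' roofed indoor reef with a mid-morning solar peak near 600 umol
#' photons/m2s, supplemental LEDs on a fixed 08:00--20:00 schedule, dusk-
#' peaking diurnal pH (8.1--8.25) and dissolved oxygen (6.89--9.94 mg/L),
#' near-constant 25 C water, episodic phytoplankton blooms, and three
#' juvenile clams that bask open in bright light (~12.7% closed), adopt a
#' partially closed posture in low light (~44.1% closed on average, with
#' strong inter-individual variation), clap their valves mostly at night
#' with long-tailed durations mostly under 100 s, occasionally hold long
#' daytime threat closures, and whose nightly clap rate couples to
#' chlorophyll with a 4-day lag. Sensors transduce closure to millivolts
#' around a 2500 mV working point with noise, slow drift, and optional
#' rail faults.
#'
#' @param seed integer RNG seed; fully determines the realization.
#' @param n_days simulated days (default 60).
#' @param n_clams number of clams (default 3).
#' @param grid_s valve sensor tick in seconds (default 5).
#' @param par_grid_s PAR grid in seconds (default 15).
#' @param env_grid_s other environmental grids in seconds (default 900).
#' @param light,behavior,coupling,sensor named lists overriding individual
#'   defaults (see the returned object for the full set).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_days = 60, n_clams = 3, grid_s = 5,
                       par_grid_s = 15, env_grid_s = 900,
                       light = list(), behavior = list(), coupling = list(),
                       sensor = list()) {
  merge_over <- function(defaults, user) { defaults[names(user)] <- user; defaults }
  cfg <- list(
    seed = as.integer(seed), n_days = n_days, n_clams = n_clams,
    grid_s = grid_s, par_grid_s = par_grid_s, env_grid_s = env_grid_s,
    origin_day = as.integer(as.Date("2021-05-03")),  # analysis span opens in early May
    light = merge_over(list(
      solar_peak_hour = 9,      # sun clears the east glass mid-morning
      solar_amp = 540,          # + LED ~ 600 at peak
      solar_sigma_rise_h = 1.5, # sharp sunrise
      solar_sigma_fall_h = 2.2, # slow decline behind trees; total drops past 100 ~14:00
      led_on_hour = 8, led_off_hour = 20, led_amp = 55,
      midnight_artifact = FALSE, artifact_amp = 300,
      noise_cv = 0.03,
      dark_span_hours = c(20, 4) # derived: hourly means < 5 inside this span
    ), light),
    behavior = merge_over(list(
      bright_mean_pct = 12.7, dark_mean_pct = 44.1,
      light_threshold = 100, light_logistic_width = 12,
      clam_gap_factors = c(0.6, 1.4, 1.0),  # per-clam dark-closure spread
      night_shift_sd_pct = 5,               # night-to-night posture variation
      jitter_sd_pct = 3, jitter_tau_s = 3600,
      clap_rate_dark_h = 0.6, clap_rate_bright_h = 0.25,
      clam_clap_factors = c(1.15, 1.15, 0.7),
      clap_meanlog = log(40), clap_sdlog = 0.715,  # median 40 s, ~90% < 100 s
      clap_peak_pct = c(94, 100),
      long_closure_rate_bright_h = 0.02,
      long_meanlog = log(240), long_sdlog = 0.6
    ), behavior),
    coupling = merge_over(list(
      chl_lag_days = 4, chl_gain = 0.8,
      ph_mid = 8.175, ph_amp = 0.055, ph_range = c(8.1, 8.25),
      do_mid = 8.4, do_amp = 1.2, do_range = c(6.89, 9.94),
      env_peak_hour = 20,   # dusk maxima at the end of the photoperiod (lights off 20:00)
      ph_noise = 0.005, do_noise = 0.05, temp_noise = 0.02,
      temp_mid = 25, temp_amp = 0.1,
      chl_baseline_rfu = 1, chl_ar_tau_days = 2, chl_ar_sd = 0.3,
      bloom_rate_per_day = 1 / 12, bloom_logamp = c(1.5, 2.5),
      bloom_rise_days = 0.5, bloom_decay_days = 1.5,
      # multi-day productivity level: sustained algal activity raises mean
      # pH/DO and food availability (hence clap rate) together, on top of
      # the acute lagged bloom channel
      productivity_tau_days = 3, productivity_sd = 1,
      ph_productivity_gain = 0.015, do_productivity_gain = 0.2,
      chl_productivity_gain = 0.15, clap_productivity_gain = 0.6
    ), coupling),
    sensor = merge_over(list(
      offset_mv = 2500, offset_jitter_mv = 100,
      gain_mv_per_pct = 8,
      noise_sd_mv = 4,
      drift_mv_per_day = 2, drift_rw_sd_mv = 0.05,
      round_mv = TRUE,
      faults = list()   # list of list(clam, start_s, end_s, kind = "rail_high"/"rail_low")
    ), sensor)
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_times <- function(config, step_s) {
  t0 <- config$origin_day * .DAY_S
  seq(t0, t0 + config$n_days * .DAY_S - step_s, by = step_s)
}

solar_led_curve <- function(hour, L) {
  sig <- ifelse(hour < L$solar_peak_hour, L$solar_sigma_rise_h, L$solar_sigma_fall_h)
  solar <- L$solar_amp * exp(-((hour - L$solar_peak_hour) / sig)^2 / 2)
  led <- ifelse(hour >= L$led_on_hour & hour < L$led_off_hour, L$led_amp, 0)
  solar + led
}

#' Simulate the light environment (PAR)
#'
#' Deterministic diurnal shape (asymmetric solar hump peaking mid-morning
#' plus an LED square wave on a fixed 08:00--20:00 program, optionally the
#' midnight logger artifact spike) with small multiplicative flicker, on
#' the PAR grid. Uses the caller's RNG stream.
#'
#' @param config a [sim_config()].
#' @return an [env_series()] of PAR.
#' @export
simulate_light <- function(config) {
  L <- config$light
  t_s <- sim_times(config, config$par_grid_s)
  h <- (t_s %% .DAY_S) / .HOUR_S
  par <- solar_led_curve(h, L)
  if (L$midnight_artifact) {
    par <- par + ifelse(h < config$par_grid_s / .HOUR_S, L$artifact_amp, 0)
  }
  par <- pmax(0, par * (1 + L$noise_cv * rnorm(length(par))))
  env_series("PAR", t_s, par, nominal_period_s = config$par_grid_s)
}

#' Simulate water chemistry and plankton series
#'
#' pH, DO and temperature follow clipped diurnal sinusoids peaking near
#' dusk (`env_peak_hour`), the signature of photosynthetic build-up through
#' the photoperiod and nighttime respiratory draw-down. Chlorophyll-a is a
#' slowly wandering log-baseline punctuated by episodic bloom bursts
#' (fast rise, slower exponential die-off); phycoerythrin gets independent
#' bursts. Bloom days are recorded for ground truth.
#'
#' @param config a [sim_config()].
#' @return list of [env_series()] (`pH`, `DO`, `temperature`,
#'   `chlorophyll_a`, `phycoerythrin`) with attribute `bloom_days`
#'   (chlorophyll bloom start times, in days from simulation start).
#' @export
simulate_env <- function(config) {
  C <- config$coupling
  t_s <- sim_times(config, config$env_grid_s)
  h <- (t_s %% .DAY_S) / .HOUR_S
  diurnal <- cos(2 * pi * (h - C$env_peak_hour) / 24)
  n <- length(t_s)
  clipv <- function(x, r) pmin(pmax(x, r[1]), r[2])
  # daily productivity level (AR(1) over days)
  phi_p <- exp(-1 / C$productivity_tau_days)
  prod_daily <- as.numeric(filter(rnorm(config$n_days,
                                        sd = C$productivity_sd * sqrt(1 - phi_p^2)),
                                  phi_p, method = "recursive"))
  di <- floor((t_s - t_s[1]) / .DAY_S) + 1L
  prod_t <- prod_daily[di]
  ph <- clipv(C$ph_mid + C$ph_productivity_gain * prod_t + C$ph_amp * diurnal +
                C$ph_noise * rnorm(n), C$ph_range)
  do <- clipv(C$do_mid + C$do_productivity_gain * prod_t + C$do_amp * diurnal +
                C$do_noise * rnorm(n), C$do_range)
  temp <- C$temp_mid + C$temp_amp * diurnal + C$temp_noise * rnorm(n)

  step_days <- config$env_grid_s / .DAY_S
  phi <- exp(-step_days / C$chl_ar_tau_days)
  base <- as.numeric(filter(rnorm(n, sd = C$chl_ar_sd * sqrt(1 - phi^2)),
                            phi, method = "recursive"))
  make_blooms <- function() {
    k <- rpois(1, C$bloom_rate_per_day * config$n_days)
    starts <- sort(runif(k, 0, config$n_days))
    amps <- runif(k, C$bloom_logamp[1], C$bloom_logamp[2])
    pulse <- numeric(n)
    td <- (t_s - t_s[1]) / .DAY_S
    for (i in seq_len(k)) {
      rel <- td - starts[i]
      up <- rel >= 0 & rel < C$bloom_rise_days
      down <- rel >= C$bloom_rise_days
      pulse[up] <- pulse[up] + amps[i] * rel[up] / C$bloom_rise_days
      pulse[down] <- pulse[down] +
        amps[i] * exp(-(rel[down] - C$bloom_rise_days) / C$bloom_decay_days)
    }
    list(pulse = pulse, starts = starts)
  }
  chl_b <- make_blooms()
  pe_b <- make_blooms()
  chl <- C$chl_baseline_rfu * exp(base + C$chl_productivity_gain * prod_t + chl_b$pulse)
  pe <- 0.5 * C$chl_baseline_rfu *
    exp(as.numeric(filter(rnorm(n, sd = C$chl_ar_sd * sqrt(1 - phi^2)),
                          phi, method = "recursive")) + pe_b$pulse)
  out <- list(
    pH = env_series("pH", t_s, ph, nominal_period_s = config$env_grid_s),
    DO = env_series("DO", t_s, do, nominal_period_s = config$env_grid_s),
    temperature = env_series("temperature", t_s, temp, nominal_period_s = config$env_grid_s),
    chlorophyll_a = structure(
      env_series("chlorophyll_a", t_s, chl, nominal_period_s = config$env_grid_s),
      productivity_daily = prod_daily),
    phycoerythrin = env_series("phycoerythrin", t_s, pe, nominal_period_s = config$env_grid_s)
  )
  attr(out, "bloom_days") <- chl_b$starts
  attr(out, "productivity_daily") <- prod_daily
  out
}

#' Simulate clam closure behavior with ground truth
#'
#' Baseline posture is a smooth logistic function of instantaneous PAR
#' crossing the basking threshold (bright mean to dark mean, per-clam gap
#' factors), plus a nightly level shift and AR(1) jitter with ~1 h
#' correlation. Valve claps are an inhomogeneous Poisson process whose rate
#' follows the same light logistic and whose nightly intensity is
#' multiplied by a factor driven by log chlorophyll lagged `chl_lag_days`;
#' clap shape is a rapid rise to near-full closure, a hold, and reopening,
#' with log-normal durations. Long daytime threat closures are a sparse
#' separate process. All true events are recorded.
#'
#' @param config a [sim_config()].
#' @param light PAR [env_series()] from [simulate_light()].
#' @param chl chlorophyll [env_series()] from [simulate_env()].
#' @return list with `closure` (matrix time x clam, percent closed),
#'   `time` (numeric seconds), and `truth` (list: `events` data.frame with
#'   clam_id/start_s/duration_s/kind, `lag_days`, `daily_clap_counts`
#'   matrix day x clam).
#' @export
simulate_behavior <- function(config, light, chl) {
  B <- config$behavior
  t_s <- sim_times(config, config$grid_s)
  n <- length(t_s)
  dt <- config$grid_s
  par_at <- approx(as.numeric(light$time), light$value, xout = t_s, rule = 2)$y
  open_frac <- plogis((par_at - B$light_threshold) / B$light_logistic_width)
  # chlorophyll modulation factor per day, lagged
  day_idx <- floor((t_s - t_s[1]) / .DAY_S) + 1L
  chl_day <- tapply(log(chl$value), floor((as.numeric(chl$time) - t_s[1]) / .DAY_S) + 1L, mean)
  chl_z <- (chl_day - mean(chl_day)) / max(sd(chl_day), 1e-12)
  lag <- config$coupling$chl_lag_days
  lagged_z <- rep(0, config$n_days)
  src <- seq_len(config$n_days) - lag
  ok <- src >= 1
  lagged_z[ok] <- chl_z[src[ok]]
  fac <- exp(config$coupling$chl_gain * lagged_z)
  # same-day productivity channel (raises pH/DO and clap rate together)
  prod_daily <- attr(chl, "productivity_daily")
  if (!is.null(prod_daily))
    fac <- fac * exp(config$coupling$clap_productivity_gain * prod_daily)
  fac <- fac / mean(fac)   # gains shape variation, not the mean rate
  phi <- exp(-dt / B$jitter_tau_s)
  gapf <- rep_len(B$clam_gap_factors, config$n_clams)
  clapf <- rep_len(B$clam_clap_factors, config$n_clams)
  closure <- matrix(NA_real_, n, config$n_clams)
  events <- list()
  daily_counts <- matrix(0L, config$n_days, config$n_clams)
  for (cl in seq_len(config$n_clams)) {
    gap <- (B$dark_mean_pct - B$bright_mean_pct) * gapf[cl]
    night_shift <- rnorm(config$n_days, 0, B$night_shift_sd_pct)
    base <- B$bright_mean_pct + gap * (1 - open_frac) + night_shift[day_idx] * (1 - open_frac)
    jitter <- as.numeric(filter(rnorm(n, sd = B$jitter_sd_pct * sqrt(1 - phi^2)),
                                phi, method = "recursive"))
    x <- base + jitter
    # claps: thinning of an inhomogeneous Poisson process on the tick grid
    rate_h <- (B$clap_rate_bright_h +
                 (B$clap_rate_dark_h - B$clap_rate_bright_h) * (1 - open_frac)) *
      clapf[cl] * fac[day_idx]
    p_tick <- rate_h * dt / .HOUR_S
    starts <- which(runif(n) < p_tick)
    if (length(starts)) {
      durs <- rlnorm(length(starts), B$clap_meanlog, B$clap_sdlog)
      keep <- !logical(length(starts))
      last_end <- -Inf
      for (i in seq_along(starts)) {   # refractory: no clap starts inside another
        if (t_s[starts[i]] < last_end) { keep[i] <- FALSE; next }
        last_end <- t_s[starts[i]] + durs[i]
      }
      starts <- starts[keep]; durs <- durs[keep]
      peaks <- runif(length(starts), B$clap_peak_pct[1], B$clap_peak_pct[2])
      ap <- add_closure_pulses(x, t_s, starts, durs, peaks, dt)
      x <- ap$x
      if (length(starts)) {
        events[[length(events) + 1L]] <- data.frame(
          clam_id = cl, start_s = t_s[starts], duration_s = durs,
          peak_pct = peaks, realized_peak_pct = ap$realized_peak_pct,
          baseline_pct = ap$baseline_pct, kind = "clap")
        dc <- tabulate(day_idx[starts], config$n_days)
        daily_counts[, cl] <- daily_counts[, cl] + dc
      }
    }
    # sparse long daytime closures (threat response)
    p_long <- ifelse(par_at > B$light_threshold,
                     B$long_closure_rate_bright_h * dt / .HOUR_S, 0)
    lstarts <- which(runif(n) < p_long)
    if (length(lstarts)) {
      ldurs <- rlnorm(length(lstarts), B$long_meanlog, B$long_sdlog)
      lpeaks <- runif(length(lstarts), B$clap_peak_pct[1], B$clap_peak_pct[2])
      ap <- add_closure_pulses(x, t_s, lstarts, ldurs, lpeaks, dt)
      x <- ap$x
      events[[length(events) + 1L]] <- data.frame(
        clam_id = cl, start_s = t_s[lstarts], duration_s = ldurs,
        peak_pct = lpeaks, realized_peak_pct = ap$realized_peak_pct,
        baseline_pct = ap$baseline_pct, kind = "long_closure")
      daily_counts[, cl] <- daily_counts[, cl] + tabulate(day_idx[lstarts], config$n_days)
    }
    closure[, cl] <- pmin(100, pmax(0, x))
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(clam_id = integer(0), start_s = numeric(0), duration_s = numeric(0),
               peak_pct = numeric(0), realized_peak_pct = numeric(0),
               baseline_pct = numeric(0), kind = character(0))
  events <- events[order(events$clam_id, events$start_s), ]
  rownames(events) <- NULL
  list(closure = closure, time = t_s,
       truth = list(events = events, lag_days = lag,
                    daily_clap_counts = daily_counts,
                    chl_day_logmean = as.numeric(chl_day)))
}

# superimpose trapezoidal closure pulses (rise ~10 s, hold, fall ~10 s) by
# taking the pointwise max of baseline and pulse; short pulses never reach
# full amplitude (the ramp truncates them), which is recorded as the
# realized peak so detectability can be judged from ground truth
add_closure_pulses <- function(x, t_s, starts, durs, peaks, dt) {
  n <- length(x)
  ramp_s <- 10
  realized <- baseline <- numeric(length(starts))
  for (i in seq_along(starts)) {
    k0 <- starts[i]
    len <- max(1L, ceiling(durs[i] / dt))
    ks <- k0:min(n, k0 + len - 1L)
    rel <- (t_s[ks] - t_s[k0])
    prof <- peaks[i] * pmin(1, pmin(rel + dt, durs[i] - rel) / ramp_s)
    prof <- pmax(prof, 0)
    baseline[i] <- x[k0]
    realized[i] <- max(prof)
    x[ks] <- pmax(x[ks], prof)
  }
  list(x = x, realized_peak_pct = realized, baseline_pct = baseline)
}

#' Transduce closure fractions to sensor millivolts
#'
#' `mV = offset + gain * closure_pct + noise + drift`, with drift a linear
#' trend plus a slow random walk, optional rail-fault injection (spans
#' replaced by near-rail voltages), clipping to the 0--5000 mV ADC range,
#' and integer rounding (the Arduino reports integers). A negative gain
#' models a flipped magnet.
#'
#' @param config a [sim_config()].
#' @param closure matrix time x clam of percent closure.
#' @param t_s numeric timestamps (seconds).
#' @return list of [valve_series()], with attribute `fault_spans` (the
#'   injected spans, a data.frame).
#' @export
transduce <- function(config, closure, t_s) {
  S <- config$sensor
  n <- nrow(closure)
  dt <- config$grid_s
  out <- vector("list", ncol(closure))
  fault_rows <- list()
  for (cl in seq_len(ncol(closure))) {
    offset <- S$offset_mv + runif(1, -1, 1) * S$offset_jitter_mv
    mv <- offset + S$gain_mv_per_pct * closure[, cl] +
      rnorm(n, sd = S$noise_sd_mv) +
      S$drift_mv_per_day * (t_s - t_s[1]) / .DAY_S +
      cumsum(rnorm(n, sd = S$drift_rw_sd_mv))
    for (f in S$faults) {
      if (f$clam != cl) next
      sel <- t_s >= f$start_s & t_s < f$end_s
      mv[sel] <- if (f$kind == "rail_high") 4990 + runif(sum(sel), 0, 10)
                 else runif(sum(sel), 0, 10)
      fault_rows[[length(fault_rows) + 1L]] <-
        data.frame(clam_id = cl, start_s = f$start_s, end_s = f$end_s, kind = f$kind)
    }
    mv <- pmin(5000, pmax(0, mv))
    if (S$round_mv) mv <- round(mv)
    out[[cl]] <- valve_series(cl, t_s, mv, nominal_period_s = dt)
  }
  attr(out, "fault_spans") <- if (length(fault_rows)) do.call(rbind, fault_rows) else
    data.frame(clam_id = integer(0), start_s = numeric(0), end_s = numeric(0),
               kind = character(0))
  out
}

#' Run the full simulator
#'
#' Seeds the RNG from the config and generates light, environment, behavior
#' and sensor transduction in a fixed order, so the whole realization is a
#' deterministic function of the config.
#'
#' @param config a [sim_config()].
#' @return list with `valve` (list of [valve_series()]), `par`
#'   ([env_series()]), `env` (list of the other series), `truth` (ground
#'   truth: events, daily clap counts, coupling lag, bloom days, fault
#'   spans, true closure matrix and its time grid), and `config`.
#' @export
simulate_valvometry <- function(config = sim_config()) {
  set.seed(config$seed)
  par <- simulate_light(config)
  env <- simulate_env(config)
  beh <- simulate_behavior(config, par, env$chlorophyll_a)
  valve <- transduce(config, beh$closure, beh$time)
  truth <- beh$truth
  truth$bloom_days <- attr(env, "bloom_days")
  truth$fault_spans <- attr(valve, "fault_spans")
  truth$closure <- beh$closure
  truth$time <- beh$time
  list(valve = valve, par = par, env = env, truth = truth, config = config)
}

#' Write simulator output as ingest-dialect fixture files
#'
#' Emits `valve_log.tsv` (timestamp + one integer mV column per clam,
#' tab-separated, header line), one CSV per environmental variable
#' (`par.csv`, `ph.csv`, ...), and `ground_truth.json`. Byte-identical for
#' a given config (the simulation itself is seeded; writing is
#' deterministic).
#'
#' @param sim output of [simulate_valvometry()].
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_fixtures <- function(sim, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  fmt_t <- function(t) format(as_clock_time(t), "%Y-%m-%d %H:%M:%S")
  paths <- character(0)
  vl <- file.path(out_dir, "valve_log.tsv")
  mvs <- lapply(sim$valve, function(s) format(s$mv, trim = TRUE, scientific = FALSE))
  header <- paste(c("timestamp", sprintf("mv_clam%d", vapply(sim$valve, `[[`, integer(1), "clam_id"))),
                  collapse = "\t")
  lines <- do.call(paste, c(list(fmt_t(sim$valve[[1]]$time)), mvs, sep = "\t"))
  writeLines(c(header, lines), vl)
  paths <- c(paths, vl)
  env_all <- c(list(PAR = sim$par), sim$env)
  fns <- c(PAR = "par.csv", pH = "ph.csv", DO = "do.csv",
           temperature = "temperature.csv", chlorophyll_a = "chlorophyll_a.csv",
           phycoerythrin = "phycoerythrin.csv")
  for (nm in names(env_all)) {
    s <- env_all[[nm]]
    p <- file.path(out_dir, fns[[s$variable]])
    df <- data.frame(timestamp = fmt_t(s$time),
                     value = format(round(s$value, 6), trim = TRUE, scientific = FALSE))
    names(df)[2] <- s$variable
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  gt <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = sim$config$seed, n_days = sim$config$n_days,
         lag_days = sim$truth$lag_days,
         events = sim$truth$events,
         daily_clap_counts = sim$truth$daily_clap_counts,
         bloom_days = sim$truth$bloom_days,
         fault_spans = sim$truth$fault_spans),
    gt, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, gt)
  invisible(paths)
}

#' Score event detection against simulator ground truth
#'
#' A true event counts as *detectable* when its realized amplitude above
#' the concurrent baseline is at least `min_prominence_z` of that clam-day's
#' closure standard deviation (very short claps are truncated by the
#' rise/fall ramp and may never rise above the detection scale; the
#' detector cannot be asked to find them). A detectable event is
#' *recovered* when some detected event of the same clam overlaps its span
#' within `slack_s`. A detected event is *spurious* when it overlaps no
#' true event at all (detectable or not).
#'
#' @param truth the `truth` element of [simulate_valvometry()] output.
#' @param detected event data.frame from [detect_events()] (any clams).
#' @param min_prominence_z detection threshold the detector was run with.
#' @param slack_s matching slack in seconds (default 10, two ticks).
#' @return list with `recovery` (fraction of detectable true events
#'   recovered), `spurious_fraction` (of detections), `n_true`,
#'   `n_detectable`, `n_detected`, `n_spurious`.
#' @export
score_event_detection <- function(truth, detected, min_prominence_z = 1, slack_s = 10) {
  tr <- truth$events
  day_of <- floor(tr$start_s / 86400)
  # per clam-day closure SD from the true closure matrix
  amp <- tr$realized_peak_pct - tr$baseline_pct
  sd_day <- numeric(nrow(tr))
  days_all <- floor(truth$time / 86400)
  for (cl in unique(tr$clam_id)) {
    x <- truth$closure[, cl]
    sds <- tapply(x, days_all, sd)
    sel <- tr$clam_id == cl
    sd_day[sel] <- as.numeric(sds[as.character(day_of[sel])])
  }
  detectable <- amp >= min_prominence_z * sd_day
  det_start <- as.numeric(detected$start)
  det_end <- as.numeric(detected$end)
  recovered <- logical(nrow(tr))
  spurious_hit <- logical(nrow(detected))
  for (cl in unique(c(tr$clam_id, detected$clam_id))) {
    ti <- which(tr$clam_id == cl)
    di <- which(detected$clam_id == cl)
    if (!length(ti) || !length(di)) next
    ts0 <- tr$start_s[ti] - slack_s
    ts1 <- tr$start_s[ti] + tr$duration_s[ti] + slack_s
    for (k in seq_along(ti)) {
      hit <- det_end[di] > ts0[k] & det_start[di] < ts1[k]
      if (any(hit)) { recovered[ti[k]] <- TRUE; spurious_hit[di[hit]] <- TRUE }
    }
  }
  list(recovery = mean(recovered[detectable]),
       spurious_fraction = if (nrow(detected)) mean(!spurious_hit) else NA_real_,
       n_true = nrow(tr), n_detectable = sum(detectable),
       n_detected = nrow(detected), n_spurious = sum(!spurious_hit))
}
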