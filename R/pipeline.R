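#' Run the full valvometric analysis pipeline
#'
#' Chains QC -> daily normalization -> event delineation -> light-partitioned
#' statistics -> environmental models -> (optionally) wavelet rhythm
#' analysis over a set of valve series plus environmental series, e.g. the
#' output of [simulate_valvometry()] or of [read_valve_log()] /
#' [read_env_csv()]. Deterministic given the input and `seed` (the seed
#' feeds the wavelet surrogate draws).
#'
#' @param valve list of [valve_series()].
#' @param par PAR [env_series()].
#' @param env named list of the remaining [env_series()] (`pH`, `DO`,
#'   `temperature`, `chlorophyll_a`, `phycoerythrin`).
#' @param min_prominence_z event-detector prominence threshold (default 1).
#' @param max_lag_days CCF window (default 14).
#' @param do_rhythms run the wavelet stage (default `TRUE`).
#' @param wavelet_dt_s grid for the wavelet power stage (default 300 s;
#'   gape is window-averaged onto it first).
#' @param coherence_dt_s grid for the coherence stage (default 900 s).
#' @param n_surrogates surrogate count for wavelet significance
#'   (default 30).
#' @param seed RNG seed for the surrogate draws (default 1).
#' @param qc_diurnal run the spectral diurnal-loss check (default `TRUE`
#'   when the span allows it).
#' @return a list of stage results: `qc`, `partition`, `gape` (per clam),
#'   `events`, `daily` (per-clam daily summaries, zero-filled),
#'   `regime_stats`, `regime_test`, `duration_test`, `duration_hist`,
#'   `daily_table`, `gam`, `ccf_chl`, `ccf_ph`, and (if `do_rhythms`)
#'   `wavelet`, `recon24`, `residual_wavelet`, `coherence` (vs pH, DO,
#'   light).
#' @export
run_pipeline <- function(valve, par, env,
                         min_prominence_z = 1, max_lag_days = 14,
                         do_rhythms = TRUE, wavelet_dt_s = 300,
                         coherence_dt_s = 900, n_surrogates = 30, seed = 1,
                         qc_diurnal = NULL) {
  span_days <- diff(series_span(valve[[1]])) / .DAY_S
  qc_diurnal <- qc_diurnal %||% (span_days >= 4)
  qc <- qc_report(valve, diurnal = qc_diurnal)
  valve <- lapply(valve, apply_qc_mask, flags = qc$flags)
  partition <- light_partition(par)

  gape <- lapply(valve, function(s) {
    percent_closure(daily_zscore(s, polarity = "auto", partition = partition))
  })
  events <- do.call(rbind, lapply(gape, detect_events,
                                  min_prominence_z = min_prominence_z,
                                  partition = partition))
  daily <- daily_counts(events, pooling = "per_clam")
  # zero-fill: a day a clam was observed but never clapped is a 0-count day
  obs_dates <- unique(do.call(c, lapply(gape, function(g) g$day_params$date)))
  full <- expand.grid(date = sort(obs_dates),
                      clam_id = vapply(valve, `[[`, integer(1), "clam_id"))
  daily <- merge(full, daily, by = c("date", "clam_id"), all.x = TRUE)
  daily$closure_count[is.na(daily$closure_count)] <- 0L
  daily$count_day[is.na(daily$count_day)] <- 0L
  daily$count_night[is.na(daily$count_night)] <- 0L

  regime_stats <- closure_by_regime(gape, partition, statistic = "mean", sd = TRUE)
  regime_med <- closure_by_regime(gape, partition, statistic = "median", sd = FALSE)
  regime_test <- regime_median_test(gape, partition)
  duration_test <- tryCatch(compare_durations(events), error = function(e) NULL)
  duration_hist <- if (nrow(events)) duration_histogram(events) else NULL

  daily_table <- build_daily_table(daily, c(list(par), unname(env)))
  gam <- tryCatch(fit_gam(daily_table), error = function(e) e)
  cnt <- tapply(daily$closure_count, daily$date, sum)
  cnt_dates <- as.Date(names(cnt))
  ccf_on <- function(col) {
    em <- daily_table[match(cnt_dates, daily_table$date), col]
    ok <- !is.na(em)
    ccf_lagged(em[ok], as.numeric(cnt)[ok], max_lag_days = max_lag_days)
  }
  ccf_chl <- ccf_on("mean_chl_rfu")
  ccf_ph <- ccf_on("mean_pH")

  out <- list(qc = qc, partition = partition, gape = gape, events = events,
              daily = daily, regime_stats = regime_stats,
              regime_medians = regime_med, regime_test = regime_test,
              duration_test = duration_test, duration_hist = duration_hist,
              daily_table = daily_table, gam = gam,
              ccf_chl = ccf_chl, ccf_ph = ccf_ph)
  if (do_rhythms) {
    set.seed(seed)
    g <- gape[[min(length(gape), 3L)]]   # rhythm exemplar: last clam by default
    sp <- c(as.numeric(g$time[1]), as.numeric(g$time[length(g$time)]))
    wm <- window_mean(as.numeric(g$time), g$pct_closure, wavelet_dt_s, sp)
    max_period_h <- min(168, floor(span_days / 2) * 24)
    wv <- cwt_power(wm$value, dt_s = wavelet_dt_s,
                    period_range_h = c(max(2, 2 * wavelet_dt_s / .HOUR_S), max_period_h),
                    n_surrogates = n_surrogates)
    rc <- reconstruct_band(wv, c(18, 30))
    rw <- cwt_power(rc$residual, dt_s = wavelet_dt_s,
                    period_range_h = c(max(2, 2 * wavelet_dt_s / .HOUR_S), 18),
                    n_surrogates = n_surrogates)
    gm <- window_mean(as.numeric(g$time), g$pct_closure, coherence_dt_s, sp)
    coh_against <- function(s) {
      em <- approx(as.numeric(s$time), s$value, xout = gm$time, rule = 2)$y
      wavelet_coherence(gm$value, em, dt_s = coherence_dt_s,
                        period_range_h = c(6, 48), n_surrogates = n_surrogates)
    }
    out$wavelet <- wv
    out$recon24 <- rc
    out$residual_wavelet <- rw
    out$coherence <- list(pH = coh_against(env$pH), DO = coh_against(env$DO),
                          light = coh_against(par))
  }
  out
}
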