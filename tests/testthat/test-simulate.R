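test_that("the simulator is fully deterministic under its seed", {
  s1 <- small_sim(seed = 61, n_days = 2, n_clams = 2, grid_s = 60)
  s2 <- small_sim(seed = 61, n_days = 2, n_clams = 2, grid_s = 60)
  expect_identical(s1$valve[[1]]$mv, s2$valve[[1]]$mv)
  expect_identical(s1$env$chlorophyll_a$value, s2$env$chlorophyll_a$value)
  expect_identical(s1$truth$events, s2$truth$events)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(s1, d1); write_fixtures(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  s3 <- small_sim(seed = 62, n_days = 2, n_clams = 2, grid_s = 60)
  expect_false(identical(s1$valve[[1]]$mv, s3$valve[[1]]$mv))
})

test_that("the light program matches its configured geometry", {
  cfg <- sim_config(seed = 63, n_days = 3, n_clams = 1)
  set.seed(cfg$seed)
  par <- simulate_light(cfg)
  h <- (as.numeric(par$time) %% 86400) / 3600
  # daily maximum occurs between 08:00 and 10:00
  day <- floor(as.numeric(par$time) / 86400)
  for (d in unique(day)) {
    hm <- h[day == d][which.max(par$value[day == d])]
    expect_gte(hm, 8); expect_lte(hm, 10)
  }
  # hourly means below the darkness threshold across the configured dark span
  hour_mean <- tapply(par$value, floor(as.numeric(par$time) / 3600), mean)
  hh <- (as.numeric(names(hour_mean)) %% 24)
  dark <- hh >= 20 | hh < 4
  expect_true(all(hour_mean[dark] < 5))
  # zero amplitudes -> identically zero PAR
  cfg0 <- sim_config(seed = 63, n_days = 1, light = list(solar_amp = 0, led_amp = 0))
  set.seed(1)
  expect_true(all(simulate_light(cfg0)$value == 0))
})

test_that("water chemistry respects printed ranges and the bloom ground truth", {
  cfg <- sim_config(seed = 64, n_days = 30)
  set.seed(cfg$seed)
  env <- simulate_env(cfg)
  expect_true(all(env$pH$value >= 8.1 & env$pH$value <= 8.25))
  expect_true(all(env$DO$value >= 6.89 & env$DO$value <= 9.94))
  expect_lt(diff(range(tapply(env$temperature$value,
                              format(env$temperature$time, "%H"), mean))), 0.25)
  # zero diurnal amplitude and noise -> constant at the midpoint
  cfg0 <- sim_config(seed = 64, n_days = 2,
                     coupling = list(ph_amp = 0, ph_noise = 0, do_amp = 0, do_noise = 0,
                                     ph_productivity_gain = 0, do_productivity_gain = 0))
  set.seed(1)
  env0 <- simulate_env(cfg0)
  expect_true(all(env0$pH$value == cfg0$coupling$ph_mid))
  expect_true(all(env0$DO$value == cfg0$coupling$do_mid))
  # recorded bloom days coincide with chlorophyll spikes
  blooms <- attr(env, "bloom_days")
  expect_gt(length(blooms), 0)
  td <- (as.numeric(env$chlorophyll_a$time) - as.numeric(env$chlorophyll_a$time[1])) / 86400
  for (b in blooms) {
    near <- abs(td - (b + cfg$coupling$bloom_rise_days)) < 0.5
    expect_gt(max(env$chlorophyll_a$value[near]), quantile(env$chlorophyll_a$value, 0.8))
  }
})

test_that("behavior honors clap-rate zeros, dark-mean calibration, and count conservation", {
  cfg <- sim_config(seed = 65, n_days = 14, n_clams = 3, grid_s = 60,
                    behavior = list(clap_rate_dark_h = 0, clap_rate_bright_h = 0,
                                    long_closure_rate_bright_h = 0))
  set.seed(cfg$seed)
  par <- simulate_light(cfg); env <- simulate_env(cfg)
  beh <- simulate_behavior(cfg, par, env$chlorophyll_a)
  expect_equal(nrow(beh$truth$events), 0)
  expect_true(all(beh$closure >= 0 & beh$closure <= 100))

  cfg2 <- sim_config(seed = 66, n_days = 14, n_clams = 3, grid_s = 60)
  set.seed(cfg2$seed)
  par2 <- simulate_light(cfg2); env2 <- simulate_env(cfg2)
  beh2 <- simulate_behavior(cfg2, par2, env2$chlorophyll_a)
  # dark-hours mean of true closure near the configured dark mean (pooled)
  part <- light_partition(par2)
  reg <- partition_at(part, beh2$time)
  dark_mean <- mean(beh2$closure[reg == "dark", ])
  expect_lt(abs(dark_mean - cfg2$behavior$dark_mean_pct), 5)
  # conservation: daily count matrix equals groupings of the event list
  for (cl in 1:3) {
    evc <- beh2$truth$events[beh2$truth$events$clam_id == cl, ]
    day <- floor((evc$start_s - beh2$time[1]) / 86400) + 1
    expect_equal(as.integer(tabulate(day, cfg2$n_days)),
                 beh2$truth$daily_clap_counts[, cl])
  }
})

test_that("ground-truth daily counts cross-correlate with chlorophyll at the injected lag", {
  for (seed in c(67, 68)) {
    cfg <- sim_config(seed = seed, n_days = 60, n_clams = 3, grid_s = 60)
    set.seed(cfg$seed)
    par <- simulate_light(cfg); env <- simulate_env(cfg)
    beh <- simulate_behavior(cfg, par, env$chlorophyll_a)
    counts <- rowSums(beh$truth$daily_clap_counts)
    chl_day <- tapply(env$chlorophyll_a$value,
                      floor(as.numeric(env$chlorophyll_a$time) / 86400), mean)
    cc <- ccf_lagged(as.numeric(chl_day), counts, max_lag_days = 10)
    pos <- cc$lag > 0
    expect_equal(cc$lag[pos][which.max(cc$r[pos])], beh$truth$lag_days)
  }
})

test_that("transduction is an exact affine map without noise and injects detectable faults", {
  cfg <- sim_config(seed = 69, n_days = 1, n_clams = 1, grid_s = 300,
                    sensor = list(noise_sd_mv = 0, drift_mv_per_day = 0,
                                  drift_rw_sd_mv = 0, offset_jitter_mv = 0,
                                  round_mv = FALSE))
  closure <- matrix(seq(0, 100, length.out = 288), ncol = 1)
  t_s <- cfg$origin_day * 86400 + 300 * (0:287)
  set.seed(1)
  v <- transduce(cfg, closure, t_s)
  expect_equal(v[[1]]$mv, 2500 + 8 * closure[, 1], tolerance = 1e-12)

  t0 <- as.integer(as.Date("2021-05-03")) * 86400
  sim <- small_sim(seed = 70, n_days = 2, n_clams = 1, grid_s = 30,
                   sensor = list(faults = list(list(clam = 1, start_s = t0 + 40000,
                                                    end_s = t0 + 41800, kind = "rail_high"))))
  expect_equal(nrow(sim$truth$fault_spans), 1)
  f <- detect_rail_fault(sim$valve[[1]])
  expect_equal(f$kind, "rail_high")
  expect_lte(abs(as.numeric(f$start) - (t0 + 40000)), 30)
})
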