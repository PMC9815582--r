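test_that("daily z-scores match the analytic example and drop degenerate days", {
  # three samples in one day: mu = 2500, sample SD = 100
  t_s <- as.numeric(as.POSIXct("2021-05-03 06:00:00", tz = "UTC")) + c(0, 14400, 28800)
  v <- valve_series(1, t_s, c(2400, 2500, 2600), nominal_period_s = 14400)
  g <- daily_zscore(v, polarity = "closure_positive")
  expect_equal(g$z, c(-1, 0, 1))
  expect_equal(g$day_params$mu, 2500)
  expect_equal(g$day_params$sd, 100)
  g <- percent_closure(g)
  expect_equal(g$pct_closure, c(0, 50, 100))

  # a constant day is dropped with a warning, not an error
  v2 <- valve_series(1, t_s, c(2500, 2500, 2500), nominal_period_s = 14400)
  expect_warning(g2 <- daily_zscore(v2, polarity = "closure_positive"), "constant")
  expect_equal(nrow(g2$day_params), 0)
  expect_true(all(is.na(g2$z)))

  # sparse days fall below the coverage floor
  v3 <- valve_series(1, t_s[1:2], c(2400, 2600), nominal_period_s = 14400,
                     masked = c(FALSE, TRUE))
  expect_warning(daily_zscore(v3, polarity = "closure_positive"), "coverage")
})

test_that("per-day normalization invariants hold and match a brute-force loop", {
  sim <- small_sim(seed = 9, n_days = 5, n_clams = 1, grid_s = 60)
  part <- light_partition(sim$par)
  g <- percent_closure(daily_zscore(sim$valve[[1]], "auto", part))
  day <- as.Date(floor(as.numeric(g$time) / 86400), origin = "1970-01-01")
  for (d in unique(day[!is.na(g$z)])) {
    zi <- g$z[day == d]
    expect_equal(mean(zi), 0, tolerance = 1e-9)
    expect_equal(sd(zi), 1, tolerance = 1e-9)
    pi <- g$pct_closure[day == d]
    expect_equal(min(pi), 0, tolerance = 1e-9)
    expect_equal(max(pi), 100, tolerance = 1e-9)
    # brute-force per-day standardization of the raw voltages
    mvi <- sim$valve[[1]]$mv[day == d]
    zb <- (mvi - mean(mvi)) / sd(mvi)
    if (g$polarity_flipped) zb <- -zb
    expect_equal(zi, zb, tolerance = 1e-12)
  }
})

test_that("percent closure is affine-invariant and polarity flips map pct to 100 - pct", {
  set.seed(4)
  t_s <- 60 * (0:(2 * 1440 - 1)) + 60
  mv <- 2500 + 200 * sin(2 * pi * t_s / 86400) + rnorm(length(t_s), 0, 30)
  v <- valve_series(1, t_s, mv, nominal_period_s = 60)
  g <- percent_closure(daily_zscore(v, "closure_positive"))
  # positive-gain affine transform of the day's voltages
  v2 <- valve_series(1, t_s, 0.5 * mv + 900, nominal_period_s = 60)
  g2 <- percent_closure(daily_zscore(v2, "closure_positive"))
  expect_equal(g$pct_closure, g2$pct_closure, tolerance = 1e-9)
  # polarity flip
  g3 <- percent_closure(daily_zscore(v, "closure_negative"))
  expect_equal(g3$pct_closure, 100 - g$pct_closure, tolerance = 1e-9)
})

test_that("light partition labels regimes from hourly means and instantaneous PAR", {
  t_s <- 900 * (0:(96 - 1)) + 900
  all0 <- env_series("PAR", t_s, rep(0, 96))
  expect_true(all(light_partition(all0)$regime == "dark"))
  all600 <- env_series("PAR", t_s, rep(600, 96))
  expect_true(all(light_partition(all600)$regime == "bright"))

  # simulated light: regime boundaries sit within an hour of the generator's
  # configured dark span (20:00 - 04:00)
  sim <- small_sim(seed = 2, n_days = 3, n_clams = 1, grid_s = 300)
  part <- light_partition(sim$par)
  h <- (as.numeric(part$time) %% 86400) / 3600
  core_dark <- h >= 21 & h < 3
  expect_true(all(part$regime[core_dark] == "dark"))
  midday <- h >= 9 & h < 13
  expect_true(all(part$regime[midday] == "bright"))
})

test_that("regime summaries aggregate like a brute-force subset", {
  mk_gape <- function(pct, t_s, clam = 1L) {
    structure(list(clam_id = clam, time = as.POSIXct(t_s, origin = "1970-01-01", tz = "UTC"),
                   z = pct, pct_closure = pct), class = "gape_series")
  }
  t_s <- c(3600, 7200, 10800)
  part <- light_partition(env_series("PAR", t_s, c(0, 0, 600)))
  g <- mk_gape(c(10, 20, 80), t_s)
  out <- closure_by_regime(g, part, statistic = "mean")
  pooled <- out[out$clam == "pooled", ]
  expect_equal(pooled$mean[pooled$regime == "dark"], 15)
  expect_equal(pooled$mean[pooled$regime == "bright"], 80)
  expect_true(is.na(pooled$mean[pooled$regime == "low_light"]))

  # identical value in every regime -> every summary equals it
  g2 <- mk_gape(c(40, 40, 40), t_s)
  out2 <- closure_by_regime(g2, part, statistic = "median", sd = FALSE)
  expect_true(all(out2$median[!is.na(out2$median)] == 40))

  # pooled statistics equal subset-then-aggregate over two clams
  set.seed(6)
  t_long <- 900 * (1:960)
  parv <- rep(c(0, 300), each = 480)
  part3 <- light_partition(env_series("PAR", t_long, parv))
  p1 <- runif(960, 0, 100); p2 <- runif(960, 0, 100)
  out3 <- closure_by_regime(list(mk_gape(p1, t_long, 1L), mk_gape(p2, t_long, 2L)),
                            part3, statistic = "mean")
  reg <- partition_at(part3, t_long)
  for (r in c("dark", "bright")) {
    expect_equal(out3$mean[out3$clam == "pooled" & out3$regime == r],
                 mean(c(p1[reg == r], p2[reg == r])))
  }
})

test_that("auto polarity recovers a flipped magnet installation", {
  sim <- small_sim(seed = 12, n_days = 4, n_clams = 1, grid_s = 60,
                   sensor = list(gain_mv_per_pct = -8))
  part <- light_partition(sim$par)
  g <- percent_closure(daily_zscore(sim$valve[[1]], "auto", part))
  expect_true(g$polarity_flipped)
  reg <- partition_at(part, g$time)
  expect_gt(median(g$pct_closure[reg == "dark"], na.rm = TRUE),
            median(g$pct_closure[reg == "bright"], na.rm = TRUE))
})
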