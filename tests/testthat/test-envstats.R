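mk_daily_cov <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    mean_light = rnorm(n, 200, 30), mean_pH = rnorm(n, 8.17, 0.03),
    mean_DO = rnorm(n, 8.4, 0.5), mean_chl_rfu = exp(rnorm(n, 0, 0.8)),
    mean_pe_rfu = exp(rnorm(n, -0.7, 0.8)))
}
add_logs <- function(d) {
  d$log_chl <- log(d$mean_chl_rfu); d$log_pe <- log(d$mean_pe_rfu); d
}

test_that("daily table joins counts to daily-mean covariates and drops incomplete days", {
  sim <- small_sim(seed = 13, n_days = 10, n_clams = 1, grid_s = 300)
  dates <- as.Date("2021-05-03") + 0:9
  summ <- data.frame(date = dates, clam_id = 1L, closure_count = rpois(10, 30),
                     count_day = 0L, count_night = 0L, median_duration_s = 40)
  env <- c(list(sim$par), unname(sim$env))
  tab <- build_daily_table(summ, env)
  expect_equal(nrow(tab), 10)
  expect_equal(attr(tab, "n_dropped"), 0)
  # joined means equal a brute-force per-day recomputation
  d0 <- as.numeric(as.Date("2021-05-03"))
  for (i in c(1, 5, 10)) {
    sel <- floor(as.numeric(sim$env$pH$time) / 86400) == d0 + i - 1
    expect_equal(tab$mean_pH[i], mean(sim$env$pH$value[sel]))
  }
  expect_equal(tab$log_chl, log(tab$mean_chl_rfu), tolerance = 1e-12)

  # covariate missing on two days -> those rows dropped and counted
  ph_short <- env_series("pH", sim$env$pH$time[1:(8 * 96)], sim$env$pH$value[1:(8 * 96)])
  env2 <- c(list(sim$par), list(ph_short), unname(sim$env[c("DO", "temperature",
                                                            "chlorophyll_a", "phycoerythrin")]))
  tab2 <- build_daily_table(summ, env2)
  expect_equal(nrow(tab2), 8)
  expect_equal(attr(tab2, "n_dropped"), 2)
})

test_that("additive model recovers a pH signal and flags degenerate inputs", {
  n <- 200
  d <- add_logs(mk_daily_cov(n, seed = 41))
  d$closure_count <- round(34 + 400 * (d$mean_pH - 8.17) + rnorm(n, 0, 5))
  g <- fit_gam(d)
  expect_lt(g$anova_table$p[g$anova_table$term == "s(mean_pH)"], 0.01)
  expect_equal(g$anova_table$term[6], "Residuals")
  expect_true(all(g$anova_table$df >= 1))

  # near-constant response: no term significant at this seed, F small
  d2 <- add_logs(mk_daily_cov(50, seed = 42))
  d2$closure_count <- 34 + round(rnorm(50, 0, 0.5))
  g2 <- fit_gam(d2)
  expect_true(all(g2$anova_table$p[1:5] > 0.05))

  d3 <- d2; d3$mean_DO <- 8.4
  expect_error(fit_gam(d3), "constant covariate: mean_DO")
  expect_error(fit_gam(d2[1:10, ]), "complete days")
})

test_that("a purely linear effect is recovered by the smooth within 5% of the lm slope", {
  n <- 120
  d <- add_logs(mk_daily_cov(n, seed = 43))
  slope <- 300
  d$closure_count <- 34 + slope * (d$mean_pH - 8.17) + rnorm(n, 0, 0.5)
  g <- fit_gam(d)
  # closed-form oracle: ordinary least squares
  lm_slope <- coef(lm(closure_count ~ mean_pH, data = d))["mean_pH"]
  fit_slope <- coef(lm(fitted(g$model) ~ d$mean_pH))[2]
  expect_equal(unname(fit_slope), unname(lm_slope), tolerance = 0.05)
  expect_equal(unname(fit_slope), slope, tolerance = 0.05)
})

test_that("lagged cross-correlation follows its stated conventions", {
  set.seed(44)
  x <- as.numeric(arima.sim(list(ar = 0.4), 100))
  self <- ccf_lagged(x, x, max_lag_days = 10)
  expect_equal(self$r[self$lag == 0], 1, tolerance = 1e-12)
  expect_equal(max(abs(self$r)), 1, tolerance = 1e-12)
  expect_equal(self$conf_bound, 0.196)

  # y lags x by 4 days -> argmax over positive lags at +4
  y <- c(rep(0, 4), x[1:96]) + rnorm(100, 0, 0.05)
  cc <- ccf_lagged(x, y, max_lag_days = 10)
  pos <- cc$lag > 0
  expect_equal(cc$lag[pos][which.max(cc$r[pos])], 4)
  expect_true(4 %in% cc$significant_lags)

  # antisymmetry: r_xy(k) = r_yx(-k)
  cc_rev <- ccf_lagged(y, x, max_lag_days = 10)
  expect_equal(cc$r, rev(cc_rev$r), tolerance = 1e-12)

  # cross-check against the classic estimator in stats::ccf
  ref <- ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$r, rev(as.numeric(ref$acf)), tolerance = 1e-10)

  expect_error(ccf_lagged(rep(1, 50), x[1:50]), "zero-variance")
  expect_warning(ccf_lagged(x[1:20], y[1:20], max_lag_days = 10), "noisy")
})

test_that("dark-vs-light rank-sum test matches the enumeration oracle", {
  t_s <- 3600 * (0:7) + 1800   # one sample per clock hour
  part <- light_partition(env_series("PAR", t_s, c(0, 0, 0, 0, 300, 300, 300, 300)))
  mk <- function(pct) structure(list(clam_id = 1L,
                                     time = as.POSIXct(t_s, origin = "1970-01-01", tz = "UTC"),
                                     z = pct, pct_closure = pct), class = "gape_series")
  g <- mk(c(60, 70, 80, 90, 10, 20, 30, 40))   # full separation
  out <- regime_median_test(g, part)
  expect_equal(out$W_ranksum, 5 + 6 + 7 + 8)    # dark holds the top ranks
  expect_equal(out$median_dark, 75)
  expect_equal(out$median_light, 25)
  set.seed(45)
  g2 <- mk(runif(8, 0, 100))
  out2 <- regime_median_test(g2, part)
  reg <- as.character(partition_at(part, g2$time))
  expect_equal(out2$p, enum_ranksum_p(g2$pct_closure[reg == "dark"],
                                      g2$pct_closure[reg != "dark"]))
})
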