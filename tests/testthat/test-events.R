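test_that("detector handles the canonical spike, monotone traces, and bad windows", {
  got <- detect_idx(c(0, 0, 2, 0, 0), min_prom = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$peak_idx, 3)
  expect_equal(got$peak_z, 2)
  # single-sample spike still has positive duration (half a tick each side)
  expect_equal(got$start_idx, 3)
  expect_equal(got$end_idx, 3)

  expect_null(detect_idx(seq(0, 5, length.out = 50)))
  expect_null(detect_idx(rep(1, 50)))
  g <- structure(list(clam_id = 1L, time = as.POSIXct(1:10 * 5, origin = "1970-01-01", tz = "UTC"),
                      z = rnorm(10), pct_closure = rep(NA_real_, 10)), class = "gape_series")
  expect_error(detect_events(g, window_points = 4), "odd")
  expect_error(detect_events(g, window_points = 1), "odd")
})

test_that("production detector agrees exactly with the exhaustive scan", {
  set.seed(21)
  for (rep in 1:25) {
    n <- 300
    z <- as.numeric(arima.sim(list(ar = 0.8), n)) + rnorm(n, 0, 0.3)
    if (rep %% 5 == 0) z[sample(n, 8)] <- NA      # gaps split runs
    if (rep %% 7 == 0) z <- round(z * 4) / 4       # ties / plateaus
    for (thr in c(0.5, 1.5)) {
      got <- detect_idx(z, min_prom = thr)
      want <- naive_detect(z, min_prom = thr)
      if (is.null(want)) expect_null(got) else {
        expect_equal(got$peak_idx, want$peak_idx)
        expect_equal(got$start_idx, want$start_idx)
        expect_equal(got$end_idx, want$end_idx)
        expect_equal(got$prominence, want$prominence)
      }
    }
  }
})

test_that("detection is invariant to time translation and z offset, monotone in threshold", {
  set.seed(22)
  z <- as.numeric(arima.sim(list(ar = 0.7), 400))
  base <- detect_idx(z, min_prom = 1)
  shifted <- detect_idx(z + 5, min_prom = 1)
  expect_equal(base$peak_idx, shifted$peak_idx)
  expect_equal(base$prominence, shifted$prominence)

  thrs <- seq(0.2, 3, by = 0.2)
  counts <- vapply(thrs, function(th) {
    got <- detect_idx(z, min_prom = th)
    if (is.null(got)) 0L else nrow(got)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))

  # every detected peak is a strict 3-point local maximum
  got <- detect_idx(z, min_prom = 0.5)
  expect_true(all(z[got$peak_idx] > z[got$peak_idx - 1] &
                    z[got$peak_idx] >= z[got$peak_idx + 1]))
})

test_that("daily counts split day and night and conserve totals", {
  mk_ev <- function(times, clam = 1L) {
    t <- as.POSIXct(times, tz = "UTC")
    data.frame(clam_id = clam, peak_time = t, start = t - 10, end = t + 10,
               duration_s = 20, peak_z = 3, prominence = 3, peak_pct = 90,
               regime_at_peak = factor("dark", levels = c("dark", "low_light", "bright")))
  }
  ev <- mk_ev(c("2021-06-01 15:00:00", "2021-06-01 09:00:00", "2021-06-01 23:00:00"))
  dc <- daily_counts(ev, dates = as.Date(c("2021-06-01", "2021-06-02")))
  expect_equal(dc$closure_count, c(3L, 0L))
  expect_equal(dc$count_night, c(2L, 0L))   # 15:00 and 23:00 in [14:00, 04:00)
  expect_equal(dc$count_day, c(1L, 0L))     # 09:00 in the day window
  expect_true(all(dc$count_day + dc$count_night == dc$closure_count))

  # pooled counts equal the sum of per-clam counts
  ev2 <- rbind(mk_ev(c("2021-06-01 15:00:00", "2021-06-02 01:00:00"), 1L),
               mk_ev("2021-06-01 16:00:00", 2L))
  per <- daily_counts(ev2, "per_clam")
  pool <- daily_counts(ev2, "pooled")
  per_sums <- tapply(per$closure_count, as.character(per$date), sum)
  expect_equal(unname(as.integer(per_sums[as.character(pool$date)])),
               pool$closure_count)
})

test_that("duration histograms and the below-100s fraction are conserved", {
  ev <- data.frame(clam_id = 1, peak_time = as.POSIXct("2021-06-01", tz = "UTC") + 1:3,
                   duration_s = c(10, 20, 150))
  h <- duration_histogram(ev, bin_edges_s = c(0, 100, 200))
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$frac_below_100s, 2 / 3)
  expect_equal(sum(h$counts), nrow(ev))
  h2 <- duration_histogram(ev, bin_edges_s = c(0, 1000))
  expect_equal(h2$counts, 3)
})

test_that("rank-sum tests match the analytic example and the enumeration oracle", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$W_ranksum, 6)   # complete separation: minimal rank sum
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 0.1)         # 2 / choose(6, 3)

  set.seed(30)
  v <- rnorm(300)
  same <- rank_sum_test(v, v)   # identical groups
  expect_gt(same$p, 0.99)

  for (i in 1:10) {
    x <- rnorm(sample(4:7, 1)); y <- rnorm(sample(4:7, 1))
    expect_equal(rank_sum_test(x, y)$p, enum_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("day/night duration comparison reports per-clam and pooled rows", {
  set.seed(31)
  t_day <- as.POSIXct("2021-06-01 09:00:00", tz = "UTC") + 86400 * (0:39)
  t_night <- as.POSIXct("2021-06-01 22:00:00", tz = "UTC") + 86400 * (0:39)
  ev <- data.frame(clam_id = rep(1:2, each = 40),
                   peak_time = rep(c(t_day[1:20], t_night[1:20]), 2),
                   duration_s = c(rlnorm(20, log(60), .4), rlnorm(20, log(30), .4),
                                  rlnorm(20, log(50), .4), rlnorm(20, log(45), .4)))
  out <- compare_durations(ev)
  expect_setequal(out$clam, c("1", "2", "pooled"))
  expect_true(all(out$n_day == c(20, 20, 40)))
  r1 <- out[out$clam == "1", ]
  expect_equal(r1$p, rank_sum_test(ev$duration_s[1:20], ev$duration_s[21:40])$p)
})
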