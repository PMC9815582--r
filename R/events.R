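#' Delineate rapid valve-closure events
#'
#' Valve claps show up as sudden peaks in the daily z-score. A sample is a
#' candidate peak iff it is the first-argmax of its centered window of
#' `window_points` samples (so with 3 points at a 5-s tick the window spans
#' more than 15 s, long enough to reject single-tick sensor noise while
#' still catching closures the animal reverses within ~15 s). Candidate
#' prominence is the peak height above the higher of its two flanking
#' minima, each taken between the peak and the nearest strictly higher
#' sample (or the end of the contiguous data run). Candidates below
#' `min_prominence_z` are discarded. Event start and end are the nearest
#' outward crossings of the reopening level
#' `peak_z - reopen_fraction * prominence` (placed half a grid step beyond
#' the last sample above the level, so a single-sample spike still has
#' positive duration). Events whose spans overlap are merged, keeping the
#' higher peak.
#'
#' QC-masked and missing samples split the series into independent runs;
#' no event crosses a gap.
#'
#' @param gape a `gape_series` (z required; `pct_closure` used if present).
#' @param min_prominence_z prominence threshold in daily-SD units
#'   (default 1).
#' @param reopen_fraction fraction of prominence that must be given back
#'   before the clam counts as reopened (default 0.5, the standard
#'   half-prominence width convention).
#' @param window_points odd integer >= 3 (default 3).
#' @param partition optional [light_partition()] used to label
#'   `regime_at_peak`.
#' @return data.frame of events: `clam_id`, `peak_time`, `start`, `end`,
#'   `duration_s`, `peak_z`, `peak_pct`, `regime_at_peak`.
#' @export
detect_events <- function(gape, min_prominence_z = 1, reopen_fraction = 0.5,
                          window_points = 3, partition = NULL) {
  if (window_points < 3 || window_points %% 2 == 0)
    stop("window_points must be an odd integer >= 3")
  z <- gape$z
  t_s <- as.numeric(gape$time)
  dt <- if (length(t_s) > 1) median(diff(t_s)) else 1
  runs <- na_runs(z)
  ev <- list()
  for (r in seq_len(nrow(runs))) {
    lo <- runs[r, 1]; hi <- runs[r, 2]
    if (hi - lo + 1 < window_points) next
    cand <- window_first_argmax(z, lo, hi, window_points)
    if (!length(cand)) next
    prom <- vapply(cand, function(i) peak_prominence(z, i, lo, hi), numeric(1))
    keep <- prom >= min_prominence_z
    cand <- cand[keep]; prom <- prom[keep]
    if (!length(cand)) next
    start_idx <- end_idx <- integer(length(cand))
    for (m in seq_along(cand)) {
      k <- cand[m]
      level <- z[k] - reopen_fraction * prom[m]
      j <- k - 1L
      while (j >= lo && z[j] >= level) j <- j - 1L
      start_idx[m] <- j + 1L
      j <- k + 1L
      while (j <= hi && z[j] >= level) j <- j + 1L
      end_idx[m] <- j - 1L
    }
    ev[[length(ev) + 1L]] <- data.frame(
      peak_idx = cand, start_idx = start_idx, end_idx = end_idx,
      peak_z = z[cand], prominence = prom
    )
  }
  if (!length(ev)) return(empty_events())
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$start_idx, ev$peak_idx), , drop = FALSE]
  ev <- merge_overlapping_events(ev)
  out <- data.frame(
    clam_id = gape$clam_id,
    peak_time = as_clock_time(t_s[ev$peak_idx]),
    start = as_clock_time(t_s[ev$start_idx] - dt / 2),
    end = as_clock_time(t_s[ev$end_idx] + dt / 2),
    peak_z = ev$peak_z,
    prominence = ev$prominence,
    peak_pct = if (all(is.na(gape$pct_closure))) NA_real_ else gape$pct_closure[ev$peak_idx],
    stringsAsFactors = FALSE
  )
  out$duration_s <- as.numeric(out$end) - as.numeric(out$start)
  out$regime_at_peak <- if (is.null(partition)) factor(NA, levels = c("dark", "low_light", "bright"))
                        else partition_at(partition, out$peak_time)
  rownames(out) <- NULL
  out[, c("clam_id", "peak_time", "start", "end", "duration_s",
          "peak_z", "prominence", "peak_pct", "regime_at_peak")]
}

empty_events <- function() {
  data.frame(clam_id = integer(0), peak_time = as_clock_time(numeric(0)),
             start = as_clock_time(numeric(0)), end = as_clock_time(numeric(0)),
             duration_s = numeric(0), peak_z = numeric(0), prominence = numeric(0),
             peak_pct = numeric(0),
             regime_at_peak = factor(character(0), levels = c("dark", "low_light", "bright")))
}

# maximal runs of non-NA values; matrix with columns start, end
na_runs <- function(z) {
  ok <- !is.na(z)
  if (!any(ok)) return(matrix(integer(0), ncol = 2))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# indices i in [lo+half, hi-half] that are the FIRST argmax of their
# centered window of w points (vectorized over offsets)
window_first_argmax <- function(z, lo, hi, w) {
  half <- (w - 1L) %/% 2L
  centers <- seq.int(lo + half, hi - half)
  if (!length(centers)) return(integer(0))
  best_val <- z[centers - half]
  best_off <- rep.int(-half, length(centers))
  for (d in seq.int(-half + 1L, half)) {
    v <- z[centers + d]
    upd <- v > best_val
    best_val[upd] <- v[upd]
    best_off[upd] <- d
  }
  centers[best_off == 0L]
}

# topographic prominence within a run: height above the higher of the two
# flanking minima, each taken between the peak and the nearest strictly
# higher sample (or the run boundary); the peak's own value seeds each min,
# so a peak adjacent to higher ground has zero prominence
peak_prominence <- function(z, i, lo, hi) {
  zi <- z[i]
  lmin <- zi; j <- i - 1L
  while (j >= lo && z[j] <= zi) { if (z[j] < lmin) lmin <- z[j]; j <- j - 1L }
  rmin <- zi; j <- i + 1L
  while (j <= hi && z[j] <= zi) { if (z[j] < rmin) rmin <- z[j]; j <- j + 1L }
  zi - max(lmin, rmin)
}

merge_overlapping_events <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    cur <- out[nrow(out), ]
    nxt <- ev[i, ]
    if (nxt$start_idx <= cur$end_idx) {       # spans share samples -> one event
      win <- if (nxt$peak_z > cur$peak_z) nxt else cur
      cur$peak_idx <- win$peak_idx
      cur$peak_z <- win$peak_z
      cur$prominence <- win$prominence
      cur$start_idx <- min(cur$start_idx, nxt$start_idx)
      cur$end_idx <- max(cur$end_idx, nxt$end_idx)
      out[nrow(out), ] <- cur
    } else {
      out <- rbind(out, nxt)
    }
  }
  out
}

#' Hour-of-day test for the nocturnal window
#'
#' The animals are partially closed and clap most between 2 PM and 4 AM;
#' this window is used for day/night event splits.
#'
#' @param time POSIXct vector.
#' @return logical, `TRUE` for hours in `[14:00, 04:00)`.
#' @export
is_night_window <- function(time) {
  h <- hour_of_day(time)
  h >= 14 | h < 4
}

#' Daily closure-event counts
#'
#' Counts events per local calendar day (of the event peak), split into the
#' night window `[14:00, 04:00)` and its daytime complement, per clam or
#' pooled.
#'
#' @param events event data.frame from [detect_events()] (possibly several
#'   clams row-bound).
#' @param pooling `"per_clam"` or `"pooled"`.
#' @param dates optional Date vector of observed days to report (days
#'   without events get zero counts); defaults to the full range of event
#'   dates.
#' @return data.frame `date`, `clam_id` (`NA` when pooled), `closure_count`,
#'   `count_day`, `count_night`, `median_duration_s` (`NA` on zero-count
#'   days).
#' @export
daily_counts <- function(events, pooling = c("per_clam", "pooled"), dates = NULL) {
  pooling <- match.arg(pooling)
  if (nrow(events) == 0L && is.null(dates)) {
    return(data.frame(date = as.Date(character(0)), clam_id = integer(0),
                      closure_count = integer(0), count_day = integer(0),
                      count_night = integer(0), median_duration_s = numeric(0)))
  }
  date <- local_date(events$peak_time)
  night <- is_night_window(events$peak_time)
  dates <- dates %||% seq(min(date), max(date), by = "day")
  clams <- if (pooling == "per_clam") sort(unique(events$clam_id)) else NA_integer_
  out <- expand.grid(date = dates, clam_id = clams)
  out$closure_count <- 0L; out$count_day <- 0L; out$count_night <- 0L
  out$median_duration_s <- NA_real_
  for (i in seq_len(nrow(out))) {
    ix <- which(date == out$date[i] &
                  (pooling == "pooled" | events$clam_id == out$clam_id[i]))
    if (!length(ix)) next
    out$closure_count[i] <- length(ix)
    out$count_day[i] <- sum(!night[ix])
    out$count_night[i] <- sum(night[ix])
    out$median_duration_s[i] <- median(events$duration_s[ix])
  }
  out[order(out$date), , drop = FALSE]
}

#' Histogram of closure-event durations
#'
#' @param events event data.frame.
#' @param bin_edges_s numeric bin edges in seconds (default 0 to the maximum
#'   in 20-s steps).
#' @return list with `breaks`, `counts`, and `frac_below_100s` (the fraction
#'   of events shorter than 100 s — most pseudofeces-expulsion claps are).
#' @export
duration_histogram <- function(events, bin_edges_s = NULL) {
  stopifnot(nrow(events) > 0)
  d <- events$duration_s
  if (is.null(bin_edges_s)) {
    top <- max(d)
    bin_edges_s <- seq(0, ceiling(top / 20) * 20, by = 20)
  }
  h <- hist(d, breaks = bin_edges_s, plot = FALSE, right = FALSE)
  list(breaks = h$breaks, counts = h$counts,
       frac_below_100s = mean(d < 100))
}

#' Two-sided rank-sum (Mann-Whitney Wilcoxon) test
#'
#' Reports the rank sum of the first group (the sum of its ranks in the
#' pooled sample) together with the Mann-Whitney U and the two-sided
#' p-value from [stats::wilcox.test()] (exact for small untied samples,
#' normal approximation otherwise).
#'
#' @param x,y numeric samples.
#' @return list with `W_ranksum`, `U`, `p`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  r <- rank(c(x, y))
  list(W_ranksum = sum(r[seq_along(x)]), U = unname(wt$statistic),
       p = wt$p.value, n_x = length(x), n_y = length(y))
}

#' Compare event durations between day and night
#'
#' Two-sided rank-sum test of durations in the day window vs the night
#' window (`[14:00, 04:00)`), per clam and pooled. The first-named group is
#' day, so `W_ranksum` is the rank sum of the daytime durations.
#'
#' @param events event data.frame (one or more clams).
#' @return data.frame with one row per clam plus a pooled row: `clam`,
#'   `n_day`, `n_night`, `median_day_s`, `median_night_s`, `W_ranksum`, `U`,
#'   `p`.
#' @export
compare_durations <- function(events) {
  night <- is_night_window(events$peak_time)
  groups <- c(as.list(split(seq_len(nrow(events)), events$clam_id)),
              list(pooled = seq_len(nrow(events))))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    ix <- groups[[g]]
    d_day <- events$duration_s[ix][!night[ix]]
    d_night <- events$duration_s[ix][night[ix]]
    if (!length(d_day) || !length(d_night))
      stop("empty day or night duration group for clam ", g)
    rs <- rank_sum_test(d_day, d_night)
    data.frame(clam = g, n_day = rs$n_x, n_night = rs$n_y,
               median_day_s = median(d_day), median_night_s = median(d_night),
               W_ranksum = rs$W_ranksum, U = rs$U, p = rs$p)
  }))
  rownames(out) <- NULL
  out
}
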