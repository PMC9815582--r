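# Independent oracles, written as plain loops so they share no code paths
# with the package implementations they check.

# exhaustive closure-event detector: scan every centered window, walk
# flanks sample by sample
naive_detect <- function(z, min_prom = 1, reopen = 0.5, w = 3) {
  n <- length(z)
  half <- (w - 1) / 2
  runs <- list(); s <- NA
  for (i in seq_len(n)) {
    if (!is.na(z[i]) && is.na(s)) s <- i
    if (is.na(z[i]) || i == n) {
      e <- if (is.na(z[i])) i - 1 else i
      if (!is.na(s) && e >= s) runs[[length(runs) + 1]] <- c(s, e)
      s <- NA
    }
  }
  cand <- NULL
  for (rn in runs) {
    lo <- rn[1]; hi <- rn[2]
    if (hi - lo + 1 < w) next
    for (i in (lo + half):(hi - half)) {
      win <- z[(i - half):(i + half)]
      if (!(z[i] == max(win) && which.max(win) == half + 1)) next
      lmin <- z[i]; j <- i - 1
      while (j >= lo && z[j] <= z[i]) { lmin <- min(lmin, z[j]); j <- j - 1 }
      rmin <- z[i]; j <- i + 1
      while (j <= hi && z[j] <= z[i]) { rmin <- min(rmin, z[j]); j <- j + 1 }
      prom <- z[i] - max(lmin, rmin)
      if (prom < min_prom) next
      level <- z[i] - reopen * prom
      a <- i; while (a - 1 >= lo && z[a - 1] >= level) a <- a - 1
      b <- i; while (b + 1 <= hi && z[b + 1] >= level) b <- b + 1
      cand <- rbind(cand, data.frame(peak_idx = i, start_idx = a, end_idx = b,
                                     peak_z = z[i], prominence = prom))
    }
  }
  if (is.null(cand)) return(cand)
  cand <- cand[order(cand$start_idx, cand$peak_idx), , drop = FALSE]
  # repeat-scan merging of overlapping spans, keeping the higher peak
  repeat {
    merged <- FALSE
    if (nrow(cand) < 2) break
    for (i in seq_len(nrow(cand) - 1)) {
      for (j in (i + 1):nrow(cand)) {
        if (cand$start_idx[j] <= cand$end_idx[i] && cand$end_idx[j] >= cand$start_idx[i]) {
          win <- if (cand$peak_z[j] > cand$peak_z[i]) j else i
          new <- cand[win, ]
          new$start_idx <- min(cand$start_idx[c(i, j)])
          new$end_idx <- max(cand$end_idx[c(i, j)])
          cand <- rbind(cand[-c(i, j), ], new)
          cand <- cand[order(cand$start_idx, cand$peak_idx), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  rownames(cand) <- NULL
  cand
}

# run the production detector on a bare z vector (wrapping it in a minimal
# gape series on a 5-s grid) and return comparable indices
detect_idx <- function(z, min_prom = 1, reopen = 0.5, w = 3, dt = 5) {
  g <- structure(list(clam_id = 1L, time = as.POSIXct(seq_along(z) * dt,
                                                      origin = "1970-01-01", tz = "UTC"),
                      z = z, pct_closure = rep(NA_real_, length(z))),
                 class = "gape_series")
  ev <- detect_events(g, min_prominence_z = min_prom, reopen_fraction = reopen,
                      window_points = w)
  if (nrow(ev) == 0) return(NULL)
  data.frame(peak_idx = round(as.numeric(ev$peak_time) / dt),
             start_idx = round((as.numeric(ev$start) + dt / 2) / dt),
             end_idx = round((as.numeric(ev$end) - dt / 2) / dt),
             peak_z = ev$peak_z, prominence = ev$prominence)
}

# exact two-sided rank-sum p-value by full enumeration of assignments
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  W <- apply(combos, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(W <= wobs), mean(W >= wobs)))
}

# brute-force window averaging for align oracle
naive_window_mean <- function(t_s, v, grid, t0, K) {
  out <- numeric(K)
  for (k in seq_len(K)) {
    sel <- t_s >= t0 + (k - 1) * grid & t_s < t0 + k * grid & !is.na(v)
    out[k] <- if (any(sel)) mean(v[sel]) else NA_real_
  }
  out
}

# small simulated dataset shared by several tests
small_sim <- function(seed = 42, n_days = 7, n_clams = 2, grid_s = 30, ...) {
  simulate_valvometry(sim_config(seed = seed, n_days = n_days,
                                 n_clams = n_clams, grid_s = grid_s, ...))
}

make_valve <- function(mv, dt = 5, t0 = 0, clam = 1L) {
  valve_series(clam, t0 + seq_along(mv) * dt, mv, nominal_period_s = dt)
}
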