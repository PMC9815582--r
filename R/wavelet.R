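# Morlet continuous wavelet machinery. Conventions follow the standard
# FFT-based formulation for the analytic Morlet mother (central frequency
# omega0, default 6): the daughter at scale s has Fourier transform
#   psihat(s w) = pi^(-1/4) * sqrt(2 pi s / dt) * exp(-(s w - omega0)^2 / 2)
# for w > 0, and the Fourier period of scale s is
#   lambda = 4 pi s / (omega0 + sqrt(2 + omega0^2))   (~1.033 s at omega0 = 6).

fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

# core transform: x (numeric, no NA), dt in seconds, scales in seconds
morlet_transform <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))          # zero padding limits wraparound
  xhat <- fft(c(x - mean(x), numeric(npad - n)))
  w <- 2 * pi * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / (npad * dt)
  wave <- matrix(0 + 0i, nrow = n, ncol = length(scales))
  pos <- w > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    daughter <- numeric(npad)
    daughter[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) * exp(-(s * w[pos] - omega0)^2 / 2)
    wj <- fft(xhat * daughter, inverse = TRUE) / npad
    wave[, j] <- wj[1:n]
  }
  wave
}

period_grid <- function(period_range_h, dj) {
  lo <- period_range_h[1]; hi <- period_range_h[2]
  stopifnot(hi > lo, lo > 0)
  J <- floor(log2(hi / lo) / dj)
  lo * 2^(dj * (0:J))
}

# cone of influence: periods longer than coi_h(t) suffer edge effects
coi_hours <- function(n, dt, omega0) {
  d <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt    # distance to nearest edge, s
  (fourier_factor(omega0) / sqrt(2)) * d / .HOUR_S
}

# per-period pooled null sample: each surrogate contributes a thinned set of
# in-cone values, so the (1 - alpha) threshold is a marginal quantile of the
# pooled null rather than an average of noisy per-surrogate quantiles
surrogate_pool <- function(n_surrogates, n_periods, draw, inside, per_surrogate = 400) {
  acc <- vector("list", n_periods)
  for (b in seq_len(n_surrogates)) {
    ps <- draw()
    for (j in seq_len(n_periods)) {
      v <- ps[inside[, j], j]
      if (!length(v)) next
      if (length(v) > per_surrogate)
        v <- v[seq(1L, length(v), length.out = per_surrogate)]
      acc[[j]] <- c(acc[[j]], v)
    }
  }
  lapply(acc, function(v) if (is.null(v)) NA_real_ else v)
}

fit_ar1 <- function(x) {
  x <- x - mean(x)
  phi <- sum(x[-1] * x[-length(x)]) / sum(x^2)
  max(min(phi, 0.99), 0)
}

ar1_surrogate <- function(n, phi, sd_x) {
  innov_sd <- sd_x * sqrt(1 - phi^2)
  as.numeric(filter(rnorm(n, sd = innov_sd), phi, method = "recursive"))
}

interpolate_gaps <- function(x, max_gap_fraction = 0.2) {
  miss <- is.na(x)
  frac <- mean(miss)
  if (frac > max_gap_fraction)
    stop(sprintf("gap fraction %.1f%% exceeds %.0f%%: span unusable for wavelet analysis",
                 100 * frac, 100 * max_gap_fraction))
  if (any(miss)) {
    idx <- seq_along(x)
    x <- approx(idx[!miss], x[!miss], xout = idx, rule = 2)$y
  }
  attr(x, "gap_fraction") <- frac
  x
}

#' Morlet wavelet power spectrum with AR(1) significance
#'
#' Computes the continuous Morlet wavelet transform of an evenly gridded
#' series on a log-spaced period grid, returning power relative to the
#' series variance, a cone of influence, and a significance mask obtained
#' from seeded AR(1) surrogates: an AR(1) process is fitted to the series,
#' `n_surrogates` realizations are transformed, and for each period the
#' (1 - alpha) quantile of surrogate relative power (pooled over time) is
#' the threshold. Cells outside the cone of influence are never significant.
#'
#' Interior gaps are filled by linear interpolation (wavelets need an even
#' grid); a gap fraction above 20% aborts, as significance would be
#' meaningless.
#'
#' @param x numeric series (NA = gap) or a `gape_series` (its
#'   `pct_closure`).
#' @param dt_s grid step in seconds.
#' @param dj period-grid resolution in octaves (default 1/20).
#' @param period_range_h analyzed periods in hours (default 2 h -- 7 d;
#'   the series must span at least twice the longest period).
#' @param omega0 Morlet central frequency (default 6).
#' @param n_surrogates surrogate count (default 100; 0 skips significance).
#' @param alpha significance level (default 0.05).
#' @return a `wavelet_result`: `power` (time x period, relative to series
#'   variance), `periods_h`, `scales_s`, `coi_h`, `signif_mask`,
#'   `signif_level` (per-period threshold), `x_used` (gap-filled series),
#'   `dt_s`, `params`.
#' @export
cwt_power <- function(x, dt_s, dj = 1 / 20, period_range_h = c(2, 168),
                      omega0 = 6, n_surrogates = 100, alpha = 0.05) {
  if (inherits(x, "gape_series")) x <- x$pct_closure
  x <- as.numeric(x)
  n <- length(x)
  if (n * dt_s < 2 * period_range_h[2] * .HOUR_S)
    stop("series shorter than twice the longest requested period")
  x <- interpolate_gaps(x)
  periods <- period_grid(period_range_h, dj)
  scales <- periods * .HOUR_S / fourier_factor(omega0)
  wave <- morlet_transform(x, dt_s, scales, omega0)
  v <- var(x)
  if (v == 0) v <- 1           # degenerate flat series: power is identically zero
  power <- Mod(wave)^2 / v
  coi <- coi_hours(n, dt_s, omega0)
  inside <- outer(coi, periods, `>=`)
  signif_level <- rep(NA_real_, length(periods))
  mask <- matrix(FALSE, n, length(periods))
  if (n_surrogates > 0 && sd(x) > 0) {
    phi <- fit_ar1(x)
    sdx <- sd(x)
    pool <- surrogate_pool(n_surrogates, length(periods), function() {
      xs <- ar1_surrogate(n, phi, sdx)
      Mod(morlet_transform(xs, dt_s, scales, omega0))^2 / var(xs)
    }, inside)
    signif_level <- vapply(pool, function(v) {
      if (all(is.na(v))) NA_real_ else quantile(v, probs = 1 - alpha, names = FALSE)
    }, numeric(1))
    mask <- sweep(power, 2, ifelse(is.na(signif_level), Inf, signif_level), `>`) & inside
  }
  structure(list(power = power, periods_h = periods, scales_s = scales,
                 coi_h = coi, signif_mask = mask, signif_level = signif_level,
                 x_used = as.numeric(x), dt_s = dt_s,
                 params = list(mother = "morlet", omega0 = omega0, dj = dj,
                               alpha = alpha, n_surrogates = n_surrogates,
                               gap_fraction = attr(x, "gap_fraction"))),
            class = "wavelet_result")
}

#' @export
print.wavelet_result <- function(x, ...) {
  avg <- colMeans(x$power)
  cat(sprintf("<wavelet_result> %d samples @ %gs x %d periods (%.2g-%.3g h); peak mean power at %.1f h\n",
              nrow(x$power), x$dt_s, length(x$periods_h),
              min(x$periods_h), max(x$periods_h),
              x$periods_h[which.max(avg)]))
  invisible(x)
}

#' Period of maximal time-averaged wavelet power
#'
#' @param result a `wavelet_result`.
#' @param within_coi restrict the average to cells inside the cone of
#'   influence (default `TRUE`).
#' @return period in hours.
#' @export
peak_period <- function(result, within_coi = TRUE) {
  p <- result$power
  if (within_coi) p[!outer(result$coi_h, result$periods_h, `>=`)] <- NA
  result$periods_h[which.max(colMeans(p, na.rm = TRUE))]
}

#' Reconstruct a period band and obtain residuals
#'
#' Inverse-transforms the contribution of periods inside `band_hours` using
#' the standard delta-reconstruction for the Morlet mother
#' (`C_delta = 0.776` at `omega0 = 6`), and returns
#' `residual = series - reconstruction` (so the two sum to the original
#' exactly, by construction). Subtracting the 24-h band isolates ultradian
#' structure for a second wavelet pass.
#'
#' @param result a `wavelet_result` from [cwt_power()].
#' @param band_hours numeric length-2 `(lo, hi)` in hours, inside the
#'   analyzed range.
#' @return a `band_reconstruction`: `band_h`, `reconstructed`, `residual`,
#'   `dt_s`.
#' @export
reconstruct_band <- function(result, band_hours) {
  p <- result$periods_h
  sel <- p >= band_hours[1] & p <= band_hours[2]
  if (!any(sel)) stop("no analyzed periods inside the requested band")
  omega0 <- result$params$omega0
  if (abs(omega0 - 6) > 1e-9)
    warning("reconstruction constant C_delta = 0.776 is calibrated for omega0 = 6")
  dj <- result$params$dj
  dt <- result$dt_s
  # power = |W|^2 / var; reconstruction needs Re(W), so recompute the waves
  wave <- morlet_transform(result$x_used, dt, result$scales_s[sel], omega0)
  x <- result$x_used
  # the transform works on the demeaned series; the series mean is carried
  # with the reconstruction so that reconstructed + residual == x exactly
  recon <- mean(x) + (dj * sqrt(dt) / (0.776 * pi^(-0.25))) *
    rowSums(sweep(Re(wave), 2, sqrt(result$scales_s[sel]), `/`))
  structure(list(band_h = band_hours, reconstructed = recon,
                 residual = x - recon, dt_s = dt),
            class = "band_reconstruction")
}

#' Wavelet power of the residual after band removal
#'
#' Runs [cwt_power()] on the residual of [reconstruct_band()]; used to look
#' for ultradian (6 h, 12 h) ridges once the dominant circadian band is
#' subtracted.
#'
#' @param recon a `band_reconstruction`.
#' @param ... passed to [cwt_power()] (`dj`, `period_range_h`, `omega0`,
#'   `n_surrogates`, `alpha`).
#' @return a `wavelet_result`.
#' @export
residual_periodicity <- function(recon, ...) {
  cwt_power(recon$residual, dt_s = recon$dt_s, ...)
}

# boxcar smoothing along time (width ~ one scale length per column) and
# along scale (+/- `octaves` octaves); partial windows at the edges
# renormalize by the samples actually present (cumsum-based running mean)
smooth_time_by_scale <- function(mat, scales_s, dt) {
  n <- nrow(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    half <- as.integer(round(scales_s[j] / dt)) %/% 2L
    if (half < 1L) next
    cs <- c(0, cumsum(mat[, j]))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

smooth_scale <- function(mat, dj, octaves = 0.6) {
  h <- as.integer(round(octaves / dj))
  if (h < 1L) return(mat)
  n <- ncol(mat)
  out <- mat
  for (j in seq_len(n)) {
    cols <- max(1L, j - h):min(n, j + h)
    out[, j] <- rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

#' Wavelet coherence with phase
#'
#' Time- and period-resolved squared coherence between two series on one
#' grid: the cross-wavelet spectrum and the two power spectra are
#' scale-normalized and smoothed with a boxcar over times (one scale
#' length) and over scales (plus/minus 0.6 octave), then
#' `R2 = |S(Wxy / s)|^2 / (S(|Wx|^2 / s) S(|Wy|^2 / s))`. Phase is the
#' argument of the smoothed cross spectrum; **positive phase means the
#' first series leads** (an in-phase pair reads 0, an anti-phased pair
#' pi). Significance uses AR(1) surrogate pairs fitted to each series, with
#' per-period pooled thresholds as in [cwt_power()].
#'
#' @param a,b numeric series on a common even grid (NA gaps interpolated as
#'   in [cwt_power()]).
#' @param dt_s grid step in seconds.
#' @param dj,period_range_h,omega0 as in [cwt_power()].
#' @param n_surrogates surrogate pair count (default 30; 0 skips).
#' @param alpha significance level (default 0.05).
#' @return a `coherence_result`: `coherence` (time x period, in `[0, 1]`),
#'   `phase` (radians in `(-pi, pi]`), `periods_h`, `coi_h`, `signif_mask`,
#'   `params`.
#' @export
wavelet_coherence <- function(a, b, dt_s, dj = 1 / 20, period_range_h = c(2, 48),
                              omega0 = 6, n_surrogates = 30, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("series lengths differ: grids must match")
  a <- interpolate_gaps(a); b <- interpolate_gaps(b)
  n <- length(a)
  periods <- period_grid(period_range_h, dj)
  scales <- periods * .HOUR_S / fourier_factor(omega0)
  coh_of <- function(x, y) {
    wx <- morlet_transform(x, dt_s, scales, omega0)
    wy <- morlet_transform(y, dt_s, scales, omega0)
    inv_s <- 1 / scales
    cross <- sweep(wx * Conj(wy), 2, inv_s, `*`)
    px <- sweep(Mod(wx)^2, 2, inv_s, `*`)
    py <- sweep(Mod(wy)^2, 2, inv_s, `*`)
    s_re <- smooth_scale(smooth_time_by_scale(Re(cross), scales, dt_s), dj)
    s_im <- smooth_scale(smooth_time_by_scale(Im(cross), scales, dt_s), dj)
    s_px <- smooth_scale(smooth_time_by_scale(px, scales, dt_s), dj)
    s_py <- smooth_scale(smooth_time_by_scale(py, scales, dt_s), dj)
    list(coh = (s_re^2 + s_im^2) / (s_px * s_py), phase = atan2(s_im, s_re))
  }
  main <- coh_of(a, b)
  coi <- coi_hours(n, dt_s, omega0)
  inside <- outer(coi, periods, `>=`)
  mask <- matrix(FALSE, n, length(periods))
  if (n_surrogates > 0) {
    pa <- fit_ar1(a); pb <- fit_ar1(b)
    sa <- sd(a); sb <- sd(b)
    pool <- surrogate_pool(n_surrogates, length(periods), function() {
      coh_of(ar1_surrogate(n, pa, sa), ar1_surrogate(n, pb, sb))$coh
    }, inside)
    thr <- vapply(pool, function(v) {
      if (all(is.na(v))) NA_real_ else quantile(v, probs = 1 - alpha, names = FALSE)
    }, numeric(1))
    mask <- sweep(main$coh, 2, ifelse(is.na(thr), Inf, thr), `>`) & inside
  }
  structure(list(coherence = main$coh, phase = main$phase,
                 periods_h = periods, coi_h = coi, signif_mask = mask,
                 params = list(omega0 = omega0, dj = dj, alpha = alpha,
                               n_surrogates = n_surrogates,
                               phase_convention = "positive = first series leads")),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d samples x %d periods (%.2g-%.3g h); %s\n",
              nrow(x$coherence), length(x$periods_h),
              min(x$periods_h), max(x$periods_h), x$params$phase_convention))
  invisible(x)
}

#' Circular-mean phase at a target period
#'
#' Summarizes the phase of a [wavelet_coherence()] result at the period bin
#' nearest `period_h`, as the circular mean over times inside the cone of
#' influence (optionally only where coherence is significant).
#'
#' @param result a `coherence_result`.
#' @param period_h target period in hours (e.g. 24).
#' @param significant_only restrict to significant cells when any exist
#'   (default `TRUE`).
#' @return phase in radians, `(-pi, pi]`.
#' @export
phase_at_period <- function(result, period_h, significant_only = TRUE) {
  j <- which.min(abs(result$periods_h - period_h))
  inside <- result$coi_h >= result$periods_h[j]
  use <- inside
  if (significant_only && any(result$signif_mask[, j] & inside))
    use <- result$signif_mask[, j] & inside
  ph <- result$phase[use, j]
  atan2(mean(sin(ph)), mean(cos(ph)))
}
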