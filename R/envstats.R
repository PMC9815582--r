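#' Join daily closure counts to daily-mean environmental covariates
#'
#' Computes per-calendar-day means of each environmental series, log
#' transforms the fluorescence channels (floored at the smallest positive
#' observed value so detection-limit zeros do not blow up the log), and
#' inner-joins to the pooled daily closure counts. Rows with any missing
#' covariate are dropped and counted in attribute `n_dropped`.
#'
#' @param summaries daily summary data.frame from [daily_counts()] (pooled
#'   or per-clam; counts are summed per date).
#' @param env list of [env_series()] (PAR, pH, DO, chlorophyll_a,
#'   phycoerythrin at minimum; temperature tolerated).
#' @param log_base `"natural"` (default) or `"log10"` for the fluorescence
#'   transform; the base rescales the smooth's axis, not its test.
#' @return data.frame with `date`, `closure_count`, `mean_light`, `mean_pH`,
#'   `mean_DO`, `mean_chl_rfu`, `mean_pe_rfu`, `log_chl`, `log_pe`.
#' @export
build_daily_table <- function(summaries, env, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  lg <- if (log_base == "natural") log else log10
  counts <- tapply(summaries$closure_count, summaries$date, sum)
  tab <- data.frame(date = as.Date(names(counts)), closure_count = as.integer(counts))
  cols <- c(PAR = "mean_light", pH = "mean_pH", DO = "mean_DO",
            chlorophyll_a = "mean_chl_rfu", phycoerythrin = "mean_pe_rfu")
  for (s in env) {
    if (!s$variable %in% names(cols)) next
    dm <- tapply(s$value, local_date(s$time), mean, na.rm = TRUE)
    tab[[cols[[s$variable]]]] <- as.numeric(dm[as.character(tab$date)])
  }
  missing_cols <- setdiff(unname(cols), names(tab))
  if (length(missing_cols)) stop("missing environmental variables: ",
                                 paste(missing_cols, collapse = ", "))
  for (nm in c("mean_chl_rfu", "mean_pe_rfu")) {
    v <- tab[[nm]]
    eps <- suppressWarnings(min(v[v > 0], na.rm = TRUE))
    if (!is.finite(eps)) stop("no positive values to anchor log transform of ", nm)
    tab[[sub("mean_(.*)_rfu", "log_\\1", nm)]] <- lg(pmax(v, eps))
  }
  keep <- complete.cases(tab)
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no dates with complete covariates after the join")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Additive spline model of daily closure frequency
#'
#' Fits a Gaussian additive model of daily closure counts: penalized
#' cubic-regression-spline smooths of log chlorophyll-a, log phycoerythrin,
#' pH and DO (smoothness selected by REML, at most `k` basis functions per
#' term), with daily mean light entered linearly (its seasonal range is too
#' small to warrant a smooth).
#'
#' Two summaries are returned. `anova_table` is the classic *ANOVA for
#' parametric effects*: sequential (type-I) F-tests of each covariate's
#' linear component in the order given, each on 1 df, with the residual row
#' from the same linear projection — the layout traditionally reported for
#' additive models of behavioral counts, and exactly calibrated under a
#' Gaussian null. `smooth_table` carries the penalized-smooth tests from
#' the REML fit (edf, reference df, F, p), which assess nonlinear structure
#' beyond the linear component.
#'
#' @param table daily table from [build_daily_table()].
#' @param response response column name (default `"closure_count"`).
#' @param smooth_terms columns to smooth (default the four above).
#' @param linear_terms columns entered linearly (default `"mean_light"`).
#' @param k maximum basis dimension per smooth (default 9).
#' @param min_rows minimum rows to attempt the fit (default 20).
#' @return a `gam_result`: list with `anova_table` (parametric effects:
#'   term, df, sum_sq, mean_sq, F, p, plus residuals), `smooth_table`,
#'   `edf`, and `model` (the fitted [mgcv::gam] object).
#' @export
fit_gam <- function(table, response = "closure_count",
                    smooth_terms = c("log_chl", "log_pe", "mean_pH", "mean_DO"),
                    linear_terms = "mean_light", k = 9, min_rows = 20) {
  if (nrow(table) < min_rows)
    stop("need >= ", min_rows, " complete days to fit the additive model; have ", nrow(table))
  for (term in c(smooth_terms, linear_terms)) {
    if (!term %in% names(table)) stop("term not in table: ", term)
    if (var(table[[term]]) == 0) stop("constant covariate: ", term)
  }
  rhs <- c(sprintf("s(%s, bs = \"cr\", k = %d)", smooth_terms, k), linear_terms)
  fml <- reformulate(rhs, response = response)
  fit <- mgcv::gam(fml, data = table, method = "REML")
  sm <- summary(fit)
  st <- sm$s.table
  smooth_table <- data.frame(term = sprintf("s(%s)", smooth_terms),
                             edf = st[, "edf"], ref_df = st[, "Ref.df"],
                             F = st[, "F"], p = st[, "p-value"])
  rownames(smooth_table) <- NULL
  # parametric-effects ANOVA: sequential F-tests of the linear components
  lm_fit <- lm(reformulate(c(smooth_terms, linear_terms), response = response),
               data = table)
  av <- anova(lm_fit)
  tab <- data.frame(term = rownames(av),
                    df = av$Df, sum_sq = av$`Sum Sq`, mean_sq = av$`Mean Sq`,
                    F = av$`F value`, p = av$`Pr(>F)`)
  tab$term <- ifelse(tab$term %in% smooth_terms, sprintf("s(%s)", tab$term), tab$term)
  rownames(tab) <- NULL
  structure(list(anova_table = tab, smooth_table = smooth_table,
                 edf = setNames(st[, "edf"], sprintf("s(%s)", smooth_terms)),
                 model = fit),
            class = "gam_result")
}

#' @export
print.gam_result <- function(x, ...) {
  cat("Additive model of daily closure frequency\n\nAnova for parametric effects:\n")
  tab <- x$anova_table
  tab$F <- round(tab$F, 3)
  tab$sum_sq <- round(tab$sum_sq, 1); tab$mean_sq <- round(tab$mean_sq, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("\nPenalized smooth terms (REML):\n")
  st <- x$smooth_table
  st$edf <- round(st$edf, 2); st$ref_df <- round(st$ref_df, 2)
  st$F <- round(st$F, 3); st$p <- signif(st$p, 3)
  print(st, row.names = FALSE)
  invisible(x)
}

#' Lead/lag cross-correlation of a covariate with closure counts
#'
#' Classic CCF estimator: `r(k)` is the lag-`k` sample cross-covariance of
#' `x_t` with `y_(t+k)` (sum over the overlap, divided by `N`), normalized
#' by the lag-0 standard deviations. **Positive lag means the response `y`
#' (closure frequency) lags the covariate `x`** — e.g. a peak at +4 days
#' means closures follow the covariate by four days. The approximate 95%
#' significance bound is `1.96 / sqrt(N)`.
#'
#' @param x covariate series (numeric, daily).
#' @param y response series (numeric, daily, same dates).
#' @param max_lag_days maximum |lag| (default 14).
#' @return a `ccf_result`: list with `lag` (days), `r`, `conf_bound`,
#'   `significant_lags`, `n`, and the convention string.
#' @export
ccf_lagged <- function(x, y, max_lag_days = 14) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (max_lag_days > n - 2) {
    max_lag_days <- n - 2
    warning("max lag clipped to ", max_lag_days, " (series has only ", n, " points)")
  }
  if (n < 3 * max_lag_days)
    warning("series length ", n, " < 3 x max lag; CCF estimates will be noisy")
  if (var(x) == 0 || var(y) == 0) stop("zero-variance series in CCF")
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- n * sqrt(mean(xc^2) * mean(yc^2))
  lags <- seq.int(-max_lag_days, max_lag_days)
  r <- vapply(lags, function(k) {
    if (k >= 0) sum(xc[1:(n - k)] * yc[(1 + k):n]) / denom
    else sum(xc[(1 - k):n] * yc[1:(n + k)]) / denom
  }, numeric(1))
  conf <- 1.96 / sqrt(n)
  structure(list(lag = lags, r = r, conf_bound = conf,
                 significant_lags = lags[abs(r) > conf], n = n,
                 convention = "positive lag = response (y) lags covariate (x)"),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> N = %d, 95%% bound = %.3f (%s)\n",
              x$n, x$conf_bound, x$convention))
  best <- x$lag[which.max(abs(x$r))]
  cat(sprintf("  max |r| = %.3f at lag %+d d; significant lags: %s\n",
              max(abs(x$r)), best,
              if (length(x$significant_lags)) paste(x$significant_lags, collapse = ", ") else "none"))
  invisible(x)
}

#' Rank-sum comparison of closure percentage between dark and lit hours
#'
#' Pools per-observation percent closure across clams and compares dark
#' hours (hourly mean PAR below the darkness threshold) against all hours
#' when light was present. Dark is the first-named group, so `W_ranksum` is
#' the rank sum of the dark observations.
#'
#' @param gapes a `gape_series` or list of them (with `pct_closure`).
#' @param partition a [light_partition()].
#' @return list with `median_dark`, `median_light`, `W_ranksum`, `U`, `p`,
#'   `n_dark`, `n_light`.
#' @export
regime_median_test <- function(gapes, partition) {
  if (inherits(gapes, "gape_series")) gapes <- list(gapes)
  pct <- unlist(lapply(gapes, `[[`, "pct_closure"))
  reg <- unlist(lapply(gapes, function(g) as.character(partition_at(partition, g$time))))
  ok <- !is.na(pct)
  pct <- pct[ok]; reg <- reg[ok]
  dark <- pct[reg == "dark"]
  light <- pct[reg != "dark"]
  if (!length(dark) || !length(light)) stop("dark or lit regime is empty")
  rs <- rank_sum_test(dark, light)
  list(median_dark = median(dark), median_light = median(light),
       W_ranksum = rs$W_ranksum, U = rs$U, p = rs$p,
       n_dark = rs$n_x, n_light = rs$n_y)
}
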