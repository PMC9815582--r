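#!/usr/bin/env Rscript
# Stage 3: normalize raw voltages to daily z-scores and percent closure, and
# summarize posture by light regime (dark / low light / bright).

suppressPackageStartupMessages(library(valvometry))

fx <- "results/fixtures"
log <- read_valve_log(file.path(fx, "valve_log.tsv"))
par <- read_env_csv(file.path(fx, "par.csv"), "PAR")
qc <- qc_report(log$series)
valve <- lapply(log$series, apply_qc_mask, flags = qc$flags)
partition <- light_partition(par)

gape <- lapply(valve, function(v)
  percent_closure(daily_zscore(v, polarity = "auto", partition = partition)))

day_params <- do.call(rbind, lapply(gape, function(g)
  cbind(clam_id = g$clam_id, g$day_params)))
utils::write.csv(day_params, "results/day_params.csv", row.names = FALSE)

stats_mean <- closure_by_regime(gape, partition, statistic = "mean", sd = TRUE)
stats_med <- closure_by_regime(gape, partition, statistic = "median", sd = FALSE)
utils::write.csv(stats_mean, "results/regime_means.csv", row.names = FALSE)
utils::write.csv(stats_med, "results/regime_medians.csv", row.names = FALSE)

mt <- regime_median_test(gape, partition)
message(sprintf("pooled closure: dark median %.1f%% vs light-present %.1f%% (rank-sum W = %.3g, p = %.2g)",
                mt$median_dark, mt$median_light, mt$W_ranksum, mt$p))
pool <- stats_mean[stats_mean$clam == "pooled", ]
message(sprintf("pooled means: bright %.1f%%, low light %.1f%%, dark %.1f%%",
                pool$mean[pool$regime == "bright"],
                pool$mean[pool$regime == "low_light"],
                pool$mean[pool$regime == "dark"]))
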