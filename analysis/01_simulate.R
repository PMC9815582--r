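#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — 14 days of three clams at 5-s ticks
# with the full environmental suite — and write it in the raw-file dialects
# the rest of the workflow ingests (tab-delimited valve log, one CSV per
# environmental variable, ground-truth JSON).

suppressPackageStartupMessages(library(valvometry))

out_dir <- "results/fixtures"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 42, n_days = 14, n_clams = 3, grid_s = 5)
sim <- simulate_valvometry(cfg)
paths <- write_fixtures(sim, out_dir)

message("wrote ", length(paths), " files under ", out_dir)
message(sprintf("  %d valve ticks per clam, %d true events (%d claps, %d long closures)",
                length(sim$valve[[1]]$mv), nrow(sim$truth$events),
                sum(sim$truth$events$kind == "clap"),
                sum(sim$truth$events$kind == "long_closure")))
message(sprintf("  mean true closures/day pooled over clams: %.1f",
                mean(rowSums(sim$truth$daily_clap_counts))))
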