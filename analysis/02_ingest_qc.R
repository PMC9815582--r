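#!/usr/bin/env Rscript
# Stage 2: read the raw files back through the ingest layer and screen the
# sensors — rail faults (saltwater intrusion / shorting pins the voltage near
# 0 or 5000 mV) and spectral loss of the diurnal cycle.

suppressPackageStartupMessages(library(valvometry))

fx <- "results/fixtures"
log <- read_valve_log(file.path(fx, "valve_log.tsv"))
message(sprintf("valve log: %d rows, %d skipped, %d sensors",
                log$n_rows, log$n_skipped, length(log$series)))

qc <- qc_report(log$series)
utils::write.csv(
  within(qc$flags, { start <- format(start); end <- format(end) }),
  "results/qc_flags.csv", row.names = FALSE)
jsonlite::write_json(as.list(qc$masked_fraction), "results/qc_masked_fraction.json",
                     auto_unbox = TRUE, digits = NA)
message(sprintf("%d QC flag(s); masked fractions: %s", nrow(qc$flags),
                paste(sprintf("%.2f%%", 100 * qc$masked_fraction), collapse = ", ")))
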