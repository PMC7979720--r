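#!/usr/bin/env Rscript
# Condition each stored recording and export its per-bin feature table:
# 2 ms bins / 1 ms hop, zero-phase filtering (0.1 kHz HP sound, 2 kHz LP
# pressures and flow), RMS sound pressure, mean pressures and flow, p_t,
# gated YIN f_o with aperiodicity, SL, WE and ME.

suppressPackageStartupMessages(library(syrinxspace))

rec_dir <- "results/recordings"
out_dir <- "results/features"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

paths <- list.files(rec_dir, pattern = "\\.wav$", full.names = TRUE)
if (!length(paths)) stop("no recordings found; run analysis/01_simulate.R")

for (p in paths) {
  rec <- read_recording(p)
  f <- assemble_features(rec)
  out <- file.path(out_dir, sub("\\.wav$", "_features.csv", basename(p)))
  write_features(f, out)
  voiced <- sum(!is.na(f$f_o))
  cat(sprintf("%-25s %6d bins, %5d voiced, f_o %5.0f-%4.0f Hz -> %s\n",
              basename(p), nrow(f), voiced,
              min(f$f_o, na.rm = TRUE), max(f$f_o, na.rm = TRUE), out))
}
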