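#!/usr/bin/env Rscript
# Map the pressure control space per recording: segment the p_b ramps,
# detect per-ramp phonation threshold pressures, summarize each run
# (minimal f_o, minimal SL, mean WE/ME, boundary PTPs) and grid f_o and SL
# over the p_b x p_icas plane. Writes the PTP table, the run-summary table
# and one map CSV per feature.

suppressPackageStartupMessages(library(syrinxspace))

rec_dir <- "results/recordings"
out_dir <- "results/control_space"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

paths <- list.files(rec_dir, pattern = "\\.wav$", full.names = TRUE)
if (!length(paths)) stop("no recordings found; run analysis/01_simulate.R")

summaries <- list()
ptp_all <- list()
for (p in paths) {
  id <- sub("\\.wav$", "", basename(p))
  a <- analyze_recording(read_recording(p))
  s <- a$summary
  cat(sprintf(
    "%-19s PTP_b %.2f kPa | min f_o %.0f Hz | min SL %.1f dB | WE %.2f | ME %.1f dB\n",
    id, s$ptp_b, s$minimal_f0, s$minimal_SL, s$mean_WE, s$mean_ME))
  ptp_all[[id]] <- cbind(run = id, a$ptp)
  summaries[[id]] <- data.frame(
    run = id, n_phonating_ramps = s$n_phonating_ramps,
    minimal_f0 = s$minimal_f0, minimal_SL = s$minimal_SL,
    mean_WE = s$mean_WE, mean_ME = s$mean_ME, ptp_b = s$ptp_b,
    ptp_icas_min = s$ptp_icas_min, ptp_t_min = s$ptp_t_min)
  for (feat in c("f_o", "SL")) {
    m <- a$maps[[feat]]
    grid <- expand.grid(
      pb_center = (head(m$pb_edges, -1) + tail(m$pb_edges, -1)) / 2,
      picas_center = (head(m$picas_edges, -1) + tail(m$picas_edges, -1)) / 2)
    grid$mean <- as.vector(m$mean)
    grid$sd <- as.vector(m$sd)
    grid$count <- as.vector(m$count)
    utils::write.csv(grid[grid$count > 0, ],
                     file.path(out_dir, paste0(id, "_map_", feat, ".csv")),
                     row.names = FALSE, na = "")
  }
}
utils::write.csv(do.call(rbind, ptp_all),
                 file.path(out_dir, "ptp_per_ramp.csv"),
                 row.names = FALSE, na = "")
utils::write.csv(do.call(rbind, summaries),
                 file.path(out_dir, "run_summaries.csv"),
                 row.names = FALSE, na = "")
cat("wrote", file.path(out_dir, "run_summaries.csv"), "\n")
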