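#!/usr/bin/env Rscript
# Regression stage: per run, the piecewise f_o-p_t fit (regions S1
# [0, 0.75) and S2 [0.75, 2] kPa), the linear SL-p_b fit, and delta-BIC
# selection of the driving pressure for both responses. Also exports the
# tidy long-format summary table that external mixed-model tooling
# (side/sex/age fixed effects, animal random effect) consumes directly.

suppressPackageStartupMessages(library(syrinxspace))

rec_dir <- "results/recordings"
out_dir <- "results/fits"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

paths <- list.files(rec_dir, pattern = "\\.wav$", full.names = TRUE)
if (!length(paths)) stop("no recordings found; run analysis/01_simulate.R")

rows <- list()
analyses <- list()
meta <- list()
for (p in paths) {
  id <- sub("\\.wav$", "", basename(p))
  rec <- read_recording(p)
  a <- analyze_recording(rec)
  analyses[[id]] <- a
  meta[[id]] <- data.frame(subject_id = rec$meta$subject_id,
                           side = rec$meta$side, sex = rec$meta$sex,
                           age_dph = rec$meta$age_dph)
  pw <- a$fits$f0_piecewise
  sl <- a$fits$sl_linear
  cat(sprintf(
    "%-19s S1 %5.1f Hz/kPa (r2 %.3f) | S2 %5.1f | SL %4.2f dB/kPa | f_o best: %s | SL best: %s\n",
    id, pw$s1_slope, pw$r2_1, pw$s2_slope, sl$slope,
    attr(a$fits$bic_f0, "best"), attr(a$fits$bic_sl, "best")))
  rows[[id]] <- data.frame(
    run = id, s1_slope = pw$s1_slope, s2_slope = pw$s2_slope,
    s1_r2 = pw$r2_1, s2_r2 = pw$r2_2, sl_slope = sl$slope,
    sl_r2 = sl$r2,
    dbic_f0_pt = a$fits$bic_f0$delta_bic[a$fits$bic_f0$model == "p_t"],
    dbic_sl_pb = a$fits$bic_sl$delta_bic[a$fits$bic_sl$model == "p_b"],
    f0_best = attr(a$fits$bic_f0, "best"),
    sl_best = attr(a$fits$bic_sl, "best"))
}
utils::write.csv(do.call(rbind, rows), file.path(out_dir, "fits.csv"),
                 row.names = FALSE, na = "")
tidy <- report_table(analyses, do.call(rbind, meta))
utils::write.csv(tidy, file.path(out_dir, "summary_long.csv"),
                 row.names = FALSE, na = "")
cat("wrote", file.path(out_dir, "fits.csv"), "and",
    file.path(out_dir, "summary_long.csv"), "\n")
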