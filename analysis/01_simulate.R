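#!/usr/bin/env Rscript
# Generate one synthetic run per hemi-syrinx preset (adult male/female,
# left/right) under the standard 13-level ramp protocol and store them as
# float32 WAV + JSON sidecar pairs under results/recordings/.
# The 20 kHz fast profile keeps the files small; every later script reads
# these files rather than re-simulating.

suppressPackageStartupMessages(library(syrinxspace))

out_dir <- "results/recordings"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

presets <- c("adult-male-left", "adult-male-right",
             "adult-female-left", "adult-female-right")

for (i in seq_along(presets)) {
  prot <- make_protocol(sample_rate = 20000, seed = 100 + i)
  rec <- simulate_run(syrinx_preset(presets[i]), prot, seed = 100 + i)
  path <- file.path(out_dir, paste0(presets[i], ".wav"))
  write_recording(rec, path)
  gt <- ground_truth(syrinx_preset(presets[i]), prot)
  cat(sprintf(
    "%-19s -> %s (%.0f s, %d phonating ramps expected, f_min %d Hz)\n",
    presets[i], path, length(rec$sound) / rec$sample_rate,
    gt$n_phonating_ramps, syrinx_preset(presets[i])$f_min))
}
cat("done; protocols: 13 p_icas levels 0-3 kPa, p_b ramps 0-3 kPa at 1 kPa/s\n")
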