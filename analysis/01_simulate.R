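#!/usr/bin/env Rscript
# Stage 1: generate the synthetic mapping experiment used by the later
# stages — continuous EMG with TMS triggers plus a small factorial dataset
# with known ground truth — and write them in the package's exchange
# formats. Everything downstream reads only these files or regenerates
# from the same seed.

library(mepmap)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(sampling_rate = 1000, seed = 1)

# one continuous pegboard-task record, 60 pulses at 2 Hz equivalent pacing
cont <- generate_continuous("dynamic", n_triggers = 60,
                            inter_trigger_s = 0.5, cfg,
                            intensity = 1.1 * cfg$rmt_drive, seed = 101)
message(sprintf("continuous record: %.1f s, %d triggers, RMS %.3f mV",
                nrow(cont$record$samples) / cfg$sampling_rate,
                length(cont$record$trigger_s),
                sqrt(mean(cont$record$samples^2))))

# small factorial dataset: 5-site line from M1 toward SMG, 3 tasks,
# 8 orientations, 10 pulses, 6 participants (a scaled-down session)
line <- make_layout("line5", list(from = c(0, 0), to = c(39, -39)))
design <- list(participants = 6, tasks = c("rest", "isotonic", "dynamic"),
               locations = line, orientations = seq(0, 315, 45),
               intensities = 110, n_trials = 10)
exp <- generate_experiment(design, cfg, intensity_unit = "pct_rmt",
                           locations_relative = TRUE)

write_epochs(exp$epochs, "results/data/line5")
write.csv(exp$ground_truth, "results/data/line5_ground_truth.csv",
          row.names = FALSE)
write.csv(exp$participants, "results/data/line5_participants.csv",
          row.names = FALSE)
message(sprintf("factorial dataset: %d epochs (%d cells), ground truth for %d pulses",
                nrow(exp$epochs$data),
                nrow(unique(exp$epochs$meta[c("participant", "task",
                                              "location", "orientation")])),
                nrow(exp$ground_truth)))
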