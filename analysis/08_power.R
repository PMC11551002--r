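#!/usr/bin/env Rscript
# Stage 8: effect sizes across the simulated experiments, their
# fixed-effect combination, the replication sample size, and the
# RMT-vs-effect correlation.

library(mepmap)
dir.create("results", showWarnings = FALSE)

# per-"experiment" effect sizes for detecting MEPs at the distal site
# during movement (post vs pre amplitude contrast), across 5 seeds
effects <- do.call(rbind, lapply(1:5, function(s) {
  cv <- study_recruitment(s, site_offset_mm = c(-39, -39),
                          intensities = seq(120, 160, 20))
  top <- cv$points[which.max(cv$points$intensity), ]
  data.frame(experiment = sprintf("sim%02d", s),
             d = top$t / sqrt(top$n), n = top$n, t = top$t)
}))
write.csv(effects, "results/effect_sizes.csv", row.names = FALSE)
comb <- combine_effects(effects)
message(sprintf("effects d = %s; combined (fixed-effect) d = %.2f",
                paste(sprintf("%.2f", effects$d), collapse = ", "),
                comb$d))
message(sprintf("sample size to replicate at 80%% power, alpha 0.05: combined d -> n = %d; at the published d = 0.76 -> n = %d",
                sample_size(comb$d), sample_size(0.76)))

# RMT vs effect size across simulated participants (no relation expected:
# the generator couples neither)
set.seed(8)
th <- suppressWarnings(study_threshold_recovery(seed = 8))
cv <- study_recruitment(8, intensities = seq(80, 140, 20))
rc <- rmt_effect_correlation(th$per_participant$rmt,
                             th$per_participant$ratio)
message(sprintf("RMT vs per-participant threshold ratio: r(%d) = %.3f, p = %.3f",
                rc$df, rc$r, rc$p))
write.csv(data.frame(r = rc$r, df = rc$df, p = rc$p),
          "results/rmt_effect_correlation.csv", row.names = FALSE)
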