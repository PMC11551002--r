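#!/usr/bin/env Rscript
# Stage 4: coil-orientation preference along the M1-to-SMG line — the
# amplitude-weighted mean resultant vector per participant, site and task,
# baseline-corrected by the pre-TMS resultant, using the stricter
# per-condition normalization.

library(mepmap)
dir.create("results", showWarnings = FALSE)

es <- read_epochs("results/data/line5")
tab <- mep_table(es, latency = FALSE)
tab <- normalize_meps(tab, "participant_muscle_condition")

prefs <- do.call(rbind, lapply(
  split(tab, tab[c("participant", "task", "location")], drop = TRUE),
  function(p) {
    p <- p[order(p$orientation), ]
    pref <- baseline_corrected_preference(p$orientation, p$amplitude_norm,
                                          p$amplitude_pre_norm)
    data.frame(participant = p$participant[1], task = p$task[1],
               location = p$location[1],
               corrected_length = pref$corrected_length,
               preferred_angle = pref$preferred_angle,
               compass = if (is.na(pref$preferred_angle)) NA
                         else compass_label(pref$preferred_angle))
  }))
write.csv(prefs, "results/orientation_preferences.csv", row.names = FALSE)

# group summary: preference strength by task and site
summ <- aggregate(corrected_length ~ task + location, prefs, mean)
write.csv(summ, "results/orientation_summary.csv", row.names = FALSE)
for (task in unique(summ$task)) {
  s <- summ[summ$task == task, ]
  message(sprintf("%-8s corrected resultant length by site: %s", task,
                  paste(sprintf("%s=%.3f", s$location, s$corrected_length),
                        collapse = " ")))
}
m1_dyn <- prefs$task == "dynamic" & prefs$location == "pos1"
tt <- paired_t(prefs$corrected_length[m1_dyn])
message(sprintf("movement task at M1: corrected length > 0, t(%d) = %.2f, p = %.4f; modal compass label %s",
                tt$df, tt$t, tt$p,
                names(sort(table(prefs$compass[m1_dyn]),
                           decreasing = TRUE))[1]))
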