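#!/usr/bin/env Rscript
# Build the two synthetic cohorts of the step-down-hop study:
#   Part 1 — cross-over: 30 participants x {uninjured-unsleeved,
#            injured-unsleeved, injured-sleeved} x 5 trials, baseline only.
#   Part 2 — randomised trial: 18 participants (9 Sleeve, 9 Control),
#            injured side, baseline and 6-week follow-up, 5 trials each.
# Trials are dual-rate records (2400 Hz forces, 120 Hz knee moment/angular
# velocity) with injected condition and group effects. The cohorts are fully
# reproducible from the seed, so downstream scripts regenerate them instead
# of reading bulk intermediates; this script records the manifests and one
# example trial.

library(hopspm)

seed <- 20180628
out <- "results"
dir.create(out, showWarnings = FALSE)

part1 <- simulate_crossover_study(study_design(seed = seed))
part2 <- simulate_rct_study(seed = seed + 1)

write.csv(part1$manifest, file.path(out, "part1_manifest.csv"),
          row.names = FALSE)
write.csv(part2$manifest, file.path(out, "part2_manifest.csv"),
          row.names = FALSE)

# illustrative record only, decimated to 600 Hz to keep the table small;
# write_study() emits the full-rate interchange format
tr <- part1$trials[[1]]
dec <- seq(1, length(tr$t_force), by = 4)
write.csv(data.frame(time_s = round(tr$t_force[dec], 6),
                     fx_n = round(tr$fx[dec], 3),
                     fy_n = round(tr$fy[dec], 3),
                     fz_n = round(tr$fz[dec], 3)),
          file.path(out, "example_trial_force.csv"), row.names = FALSE)
write.csv(data.frame(time_s = round(tr$t_kin, 6),
                     mx_norm = round(tr$mx, 5),
                     omega_x_rad_s = round(tr$omega_x, 5)),
          file.path(out, "example_trial_kin.csv"), row.names = FALSE)

cat("Part 1 cohort:", length(part1$trials), "trials,",
    length(unique(part1$manifest$participant)), "participants\n")
cat("Part 2 cohort:", length(part2$trials), "trials,",
    length(unique(part2$manifest$participant)), "participants (",
    paste(capture.output(print(table(unique(part2$manifest[,
      c("participant", "group")])$group))), collapse = " "), ")\n")
cat("Example trial: stance", tr$effect$stance_dur_s, "s, first Fz peak",
    round(tr$truth$peak_fz1_bw, 2), "BW at",
    round(tr$truth$peak1_time_frac * 100), "% of stance\n")
cat("Manifests and example trial written under", out, "\n")
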