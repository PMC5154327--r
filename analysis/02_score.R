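#!/usr/bin/env Rscript

# Stage 2: score skin conductance responses.
#
# Re-generates the stage-1 cohort from its seed and applies the
# trough-to-peak scorer per trial: onset (trough) must fall 0-7 s after CS
# onset, amplitude is the trough-to-peak rise of the smoothed signal with a
# 0.03 µS minimum, the first trial of each phase is excluded, motion
# artifacts require distortion in both the electrodermal and pulse
# channels, amplitudes are square-root transformed and averaged (zeros
# included) into condition x time magnitude cells.

suppressMessages(library(fearext))

seed <- 20240801L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cohort <- simulate_cohort(n_subjects = 38, seed = seed)
sc <- score_cohort(cohort)

write.csv(sc$scored, file.path(out_dir, "scored_trials.csv"),
          row.names = FALSE)
write.csv(sc$magnitudes, file.path(out_dir, "magnitudes.csv"),
          row.names = FALSE)

usable <- sc$scored[!sc$scored$artifact & !sc$scored$excluded_first_trial, ]
z_acq <- mean(usable$is_zero[usable$phase == "acquisition"])
z_ext <- mean(usable$is_zero[usable$phase == "extinction"])
cat("Scored", nrow(sc$scored), "trials from", length(cohort$subjects),
    "subjects.\n")
cat(sprintf("Zero-response trials: acquisition %.0f%%, extinction %.0f%%\n",
            100 * z_acq, 100 * z_ext))

cells <- aggregate(magnitude ~ phase + condition + time, sc$magnitudes, mean)
cat("Grand mean sqrt-magnitudes by cell:\n")
print(cells, row.names = FALSE)
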