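#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# 38 subjects run a two-block differential conditioning task (24 acquisition
# trials at 100% reinforcement, 32 unreinforced extinction trials). Each
# subject gets a pseudo-randomized trial order (max run of 3), a
# counterbalanced cue colour, questionnaire scores (IU/STAIX-2/PSWQ), a
# continuous electrodermal recording built from a bi-exponential SCR kernel
# whose per-trial amplitudes follow the IU-moderated cell-mean model, and
# per-trial uneasiness ratings. Ground truth (injected amplitude, latency,
# artifact labels) is kept for the recovery checks in later stages.
#
# Continuous signals are held in memory by later stages (stage 2 rescores
# them from the same seed); this stage persists the tabular artefacts:
# events, questionnaire panel, ratings and the truth sidecar.

suppressMessages(library(fearext))

seed <- 20240801L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cohort <- simulate_cohort(n_subjects = 38, seed = seed)

events <- dplyr::bind_rows(lapply(cohort$subjects, `[[`, "events"))
ratings <- dplyr::bind_rows(lapply(cohort$subjects, `[[`, "ratings"))
truth <- dplyr::bind_rows(lapply(cohort$subjects, function(s) {
  tr <- s$recording$truth
  tr[, c("subject_id", "phase", "index_in_phase", "condition",
         "true_amplitude_uS", "true_latency_s", "artifact")]
}))

write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
write.csv(cohort$panel, file.path(out_dir, "questionnaires.csv"),
          row.names = FALSE)
write.csv(cohort$counterbalance, file.path(out_dir, "counterbalance.csv"),
          row.names = FALSE)
write.csv(ratings[, c("subject_id", "phase", "index_in_phase", "condition",
                      "time", "rating")],
          file.path(out_dir, "ratings.csv"), row.names = FALSE)
write.csv(truth, file.path(out_dir, "truth_sidecar.csv"), row.names = FALSE)

cat("Simulated", length(cohort$subjects), "subjects,",
    nrow(events), "trials.\n")
cat("IU: mean", round(mean(cohort$panel$iu), 1),
    "SD", round(sd(cohort$panel$iu), 1), "\n")
cat("Truth zero-response rate (extinction):",
    round(100 * mean(truth$true_amplitude_uS[truth$phase == "extinction"] == 0)),
    "%\n")
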