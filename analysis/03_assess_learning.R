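#!/usr/bin/env Rscript

# Stage 3: conditioned-response scores and learner status.
#
# The CR score is the mean of the first two usable CS+ extinction trials
# minus the first two CS- trials, separately for SCR sqrt-magnitude and
# uneasiness ratings; a subject is a non-learner only if BOTH scores are
# <= 0. Non-learners are flagged, not dropped (the downstream analyses keep
# them by default).

suppressMessages(library(fearext))

seed <- 20240801L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cohort <- simulate_cohort(n_subjects = 38, seed = seed)
sc <- score_cohort(cohort)
ratings <- dplyr::bind_rows(lapply(cohort$subjects, `[[`, "ratings"))

learning <- assess_learning(sc$scored, ratings)
write.csv(learning, file.path(out_dir, "learning.csv"), row.names = FALSE)

n_non <- sum(learning$learner_status == "non_learner", na.rm = TRUE)
cat("Learner status for", nrow(learning), "subjects:",
    nrow(learning) - n_non, "learners,", n_non, "non-learners.\n")
cat(sprintf("Mean CR score: SCR %.3f sqrt-µS, ratings %.2f scale points\n",
            mean(learning$cr_scr, na.rm = TRUE),
            mean(learning$cr_rating, na.rm = TRUE)))
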