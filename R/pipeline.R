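#' Simulate a full cohort
#'
#' Draws per-subject questionnaire panels, trial sequences, ground-truth SCR
#' amplitudes (IU-moderated), continuous recordings and uneasiness ratings.
#' One master seed spawns deterministic per-subject child streams, so
#' subject i's physiology and ratings do not depend on cohort size. The
#' amplitude model standardizes IU against the instrument's calibration
#' mean/SD (63.92 / 19.56), not the sample's.
#'
#' @param n_subjects cohort size (38 emulates the study).
#' @param seed master integer seed.
#' @param config a [design_config()].
#' @param model an [effect_model()].
#' @param rmodel a [rating_model()].
#' @param kernel a [kernel_params()].
#' @param fs sampling rate, Hz.
#' @param shared_order if `TRUE` all subjects receive the same
#'   pseudo-random trial order (the source design is ambiguous; default is
#'   per-subject orders).
#' @param noise_sd,drift_sd,tonic_level recording noise parameters (µS).
#' @param artifact_rate proportion of trials receiving an injected motion
#'   artifact (ground-truth labelled).
#' @return List of class `cohort`: `$subjects` (each with `events`,
#'   `recording`, `ratings`, `z_iu`), `$panel`, `$counterbalance`, `$seed`.
#' @export
simulate_cohort <- function(n_subjects = 38, seed = 1L,
                            config = design_config(),
                            model = effect_model(),
                            rmodel = rating_model(),
                            kernel = kernel_params(),
                            fs = 50, shared_order = FALSE,
                            noise_sd = 0.005, drift_sd = 0.005,
                            tonic_level = 2, artifact_rate = 0) {
  qd <- questionnaire_defaults()
  panel <- dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    p <- sample_questionnaires(1, seed = child_seed(seed, i, 1L))
    p$subject_id <- i
    p
  }))
  cb <- assign_counterbalance(n_subjects, seed = child_seed(seed, 0L, 2L))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    ev <- generate_session(
      config,
      order_seed = if (shared_order) child_seed(seed, 0L, 3L)
                   else child_seed(seed, i, 3L),
      timing_seed = child_seed(seed, i, 4L))
    ev$subject_id <- i
    z_iu <- (panel$iu[i] - qd$means["iu"]) / qd$sds["iu"]
    rec <- simulate_recording(ev, z_iu = z_iu, model = model,
                              kernel = kernel, fs = fs,
                              tonic_level = tonic_level,
                              drift_sd = drift_sd, noise_sd = noise_sd,
                              seed = child_seed(seed, i, 5L))
    if (artifact_rate > 0) {
      n_art <- with_seed(child_seed(seed, i, 6L),
                         rbinom(1, nrow(ev), artifact_rate))
      if (n_art > 0) {
        idx <- with_seed(child_seed(seed, i, 7L),
                         sample(nrow(ev), n_art))
        rec <- inject_artifacts(rec, idx, seed = child_seed(seed, i, 8L))
      }
    }
    rat <- simulate_ratings(ev, rmodel, seed = child_seed(seed, i, 9L))
    list(subject_id = i, events = ev, recording = rec, ratings = rat,
         z_iu = unname(z_iu))
  })
  structure(list(subjects = subjects, panel = panel, counterbalance = cb,
                 seed = seed),
            class = "cohort")
}

#' Score every subject of a cohort
#'
#' Runs [score_session()] and [compute_cell_magnitudes()] per subject.
#' Subjects with an empty magnitude cell are dropped with a log entry
#' rather than silently.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config a [scoring_config()].
#' @return List with `scored` (all trials), `magnitudes` (subject x cell),
#'   `dropped` (subject ids) and `log` (character).
#' @export
score_cohort <- function(cohort, config = scoring_config()) {
  scored_all <- list(); mags_all <- list(); dropped <- integer(); log <- character()
  for (s in cohort$subjects) {
    sc <- score_session(s$recording, s$events, config)
    scored_all[[length(scored_all) + 1L]] <- sc
    m <- tryCatch(compute_cell_magnitudes(sc), missing_cell = function(e) e)
    if (inherits(m, "missing_cell")) {
      dropped <- c(dropped, s$subject_id)
      log <- c(log, paste0("score: subject ", s$subject_id,
                           " dropped (missing cell): ", conditionMessage(m)))
    } else {
      m$subject_id <- s$subject_id
      mags_all[[length(mags_all) + 1L]] <- m
    }
  }
  list(scored = dplyr::bind_rows(scored_all),
       magnitudes = dplyr::bind_rows(mags_all),
       dropped = dropped, log = log)
}

#' Conditioned-response scores and learner status for a cohort
#'
#' @param scored all scored SCR trials (with `subject_id`).
#' @param ratings all rating trials (with `subject_id`), or `NULL`.
#' @return Tibble `subject_id`, `cr_scr`, `cr_rating`, `learner_status`.
#' @export
assess_learning <- function(scored, ratings = NULL) {
  ids <- sort(unique(scored$subject_id))
  rows <- lapply(ids, function(id) {
    cr_s <- tryCatch(
      conditioned_response_score(scored[scored$subject_id == id, ],
                                 "scr_magnitude")$value,
      insufficient_data = function(e) NA_real_)
    cr_r <- if (is.null(ratings)) NA_real_ else tryCatch(
      conditioned_response_score(ratings[ratings$subject_id == id, ],
                                 "rating")$value,
      insufficient_data = function(e) NA_real_)
    status <- tryCatch(classify_learner(cr_s, cr_r),
                       insufficient_data = function(e) NA_character_)
    tibble::tibble(subject_id = id, cr_scr = cr_s, cr_rating = cr_r,
                   learner_status = status)
  })
  dplyr::bind_rows(rows)
}

# SCR-analysis exclusion screen mirroring the study's taxonomy:
# non-responders (no non-zero usable extinction SCR), excessive movement
# (artifact fraction above `movement_max`), and optionally a +/-6 SD outlier
# screen on the early CS+ - CS- difference score.
scr_exclusions <- function(scored, magnitudes, movement_max = 0.25,
                           outlier_screen = FALSE, outlier_z = 6) {
  log <- character(); drop <- integer()
  for (id in sort(unique(scored$subject_id))) {
    tr <- scored[scored$subject_id == id & scored$phase == "extinction", ]
    usable <- tr[!tr$artifact & !tr$excluded_first_trial, ]
    if (nrow(usable) > 0L && all(usable$amplitude_uS == 0)) {
      drop <- c(drop, id)
      log <- c(log, paste0("exclude: subject ", id, " non-responder"))
      next
    }
    if (mean(tr$artifact) > movement_max) {
      drop <- c(drop, id)
      log <- c(log, paste0("exclude: subject ", id, " excessive movement"))
    }
  }
  if (outlier_screen) {
    keep <- magnitudes[!magnitudes$subject_id %in% drop &
                         magnitudes$phase == "extinction", ]
    if (nrow(keep) > 0L) {
      ds <- build_difference_scores(keep)
      z <- (ds$csp_minus_csm_early - mean(ds$csp_minus_csm_early)) /
        sd(ds$csp_minus_csm_early)
      out <- ds$subject_id[abs(z) > outlier_z]
      for (id in out)
        log <- c(log, paste0("exclude: subject ", id,
                             " outlier (|z| > ", outlier_z,
                             ") on early CS+ - CS- difference"))
      drop <- c(drop, out)
    }
  }
  list(drop = sort(unique(drop)), log = log)
}

#' Run the full simulate - score - assess - analyze pipeline
#'
#' Simulates a cohort, scores SCRs, computes conditioned-response scores and
#' learner status, applies the SCR exclusion screen, and fits the extinction
#' Condition x Time x IU and acquisition Condition x IU ANCOVAs for both
#' measures, simple-slopes contrasts at IU +/- 1 SD for the SCR extinction
#' model, and the four hierarchical regressions of extinction difference
#' scores on STAIX-2/PSWQ (step 1) and IU (step 2). Deterministic under
#' `seed`; optionally persists every table as CSV plus a plain-text log.
#'
#' @inheritParams simulate_cohort
#' @param scoring a [scoring_config()].
#' @param covariate moderator for the ANCOVAs: `"iu"`, `"stai"` or `"pswq"`.
#' @param drop_non_learners drop subjects classified non-learner (kept by
#'   default, flagged).
#' @param outlier_screen apply the |z| > 6 early-difference outlier screen.
#' @param out_dir optional directory for CSV outputs and `run_log.txt`.
#' @return List of class `fearext_run` with the cohort, scored trials,
#'   magnitudes, learning table, analysis results and log.
#' @export
run_pipeline <- function(n_subjects = 38, seed = 1L,
                         config = design_config(),
                         model = effect_model(),
                         rmodel = rating_model(),
                         kernel = kernel_params(),
                         scoring = scoring_config(),
                         fs = 50,
                         covariate = c("iu", "stai", "pswq"),
                         drop_non_learners = FALSE,
                         outlier_screen = FALSE,
                         artifact_rate = 0,
                         out_dir = NULL) {
  covariate <- match.arg(covariate)
  log <- c(paste0("run: seed=", seed, " n_subjects=", n_subjects,
                  " covariate=", covariate))
  cohort <- simulate_cohort(n_subjects, seed, config, model, rmodel, kernel,
                            fs = fs, artifact_rate = artifact_rate)
  sc <- score_cohort(cohort, scoring)
  log <- c(log, sc$log)
  ratings_all <- dplyr::bind_rows(lapply(cohort$subjects, `[[`, "ratings"))
  learning <- assess_learning(sc$scored, ratings_all)
  excl <- scr_exclusions(sc$scored, sc$magnitudes,
                         outlier_screen = outlier_screen)
  log <- c(log, excl$log)
  drop_ids <- union(sc$dropped, excl$drop)
  if (drop_non_learners) {
    nl <- learning$subject_id[learning$learner_status %in% "non_learner"]
    log <- c(log, paste0("exclude: subject ", nl, " non-learner"))
    drop_ids <- union(drop_ids, nl)
  }
  cov_tbl <- cohort$panel[, c("subject_id", covariate)]
  scr_mags <- sc$magnitudes[!sc$magnitudes$subject_id %in% drop_ids, ]
  rat_cells <- ratings_all |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ reduce_ratings(.x)) |>
    dplyr::ungroup()
  fit_one <- function(cells, phase, design) {
    fit_rm_ancova(cells[cells$phase == phase, ], cov_tbl, design)
  }
  analyses <- list(
    scr_extinction = fit_one(scr_mags, "extinction", "condition_by_time"),
    scr_acquisition = fit_one(scr_mags, "acquisition", "condition_only"),
    ratings_extinction = fit_one(rat_cells, "extinction", "condition_by_time"),
    ratings_acquisition = fit_one(rat_cells, "acquisition", "condition_only")
  )
  log <- c(log, paste0("analyze: SCR n=", analyses$scr_extinction$n,
                       " (", length(drop_ids), " excluded); ratings n=",
                       analyses$ratings_extinction$n))
  slopes <- simple_slope_contrasts(analyses$scr_extinction)
  emms <- emm_table(analyses$scr_extinction)
  ds <- build_difference_scores(scr_mags[scr_mags$phase == "extinction", ])
  reg_dat <- dplyr::inner_join(ds, cohort$panel, by = "subject_id")
  hier <- lapply(setNames(nm = names(ds)[-1]), function(y) {
    hierarchical_regression(reg_dat, y, c("stai", "pswq"), "iu")
  })
  res <- structure(list(cohort = cohort, scored = sc$scored,
                        magnitudes = sc$magnitudes, learning = learning,
                        excluded = drop_ids, analyses = analyses,
                        simple_slopes = slopes, emms = emms,
                        difference_scores = ds, hier_reg = hier,
                        log = log, seed = seed),
                   class = "fearext_run")
  if (!is.null(out_dir)) write_run(res, ratings_all, out_dir)
  res
}

# persist a pipeline run as plain CSV tables + a text log
write_run <- function(res, ratings_all, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, nm)
    utils::write.csv(x, file.path(out_dir, nm), row.names = FALSE)
  events <- dplyr::bind_rows(lapply(res$cohort$subjects, `[[`, "events"))
  wcsv(events, "events.csv")
  wcsv(res$scored, "scored_trials.csv")
  wcsv(res$magnitudes, "magnitudes.csv")
  wcsv(res$learning, "learning.csv")
  wcsv(ratings_all, "ratings.csv")
  effects <- dplyr::bind_rows(lapply(names(res$analyses), function(nm) {
    e <- res$analyses[[nm]]$effects
    e$analysis <- nm
    e
  }))
  wcsv(effects, "ancova_effects.csv")
  wcsv(res$simple_slopes, "simple_slopes.csv")
  wcsv(res$emms, "emm.csv")
  reg_rows <- dplyr::bind_rows(lapply(names(res$hier_reg), function(y) {
    h <- res$hier_reg[[y]]
    dplyr::bind_rows(lapply(names(h$steps), function(st) {
      s <- h$steps[[st]]
      co <- s$coefficients
      co$step <- st; co$response <- y
      co$r_squared <- s$r_squared; co$f <- s$f
      co$delta_r_sq <- s$delta_r_sq
      co
    }))
  }))
  wcsv(reg_rows, "hierarchical_regression.csv")
  writeLines(c(res$log, paste0("versions: R ", getRversion())),
             file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' Fast cell-level magnitude simulation
#'
#' Draws per-trial raw amplitudes from the effect model (truncation at zero,
#' zero-inflation, sqrt transform) and averages them into subject x cell
#' magnitudes directly, bypassing waveform rendering and trough-to-peak
#' scoring. Used for the repeated-fit calibration studies where the
#' inferential machinery, not the scorer, is under test.
#'
#' @param z_iu vector of standardized IU scores (one per subject).
#' @param model an [effect_model()].
#' @param phase which phase's cells to generate.
#' @param trials_per_cell usable trials per cell (8 for extinction halves).
#' @param seed integer seed.
#' @return Long cell tibble usable by [fit_rm_ancova()].
#' @export
simulate_cell_magnitudes <- function(z_iu, model = effect_model(),
                                     phase = "extinction",
                                     trials_per_cell = 8L, seed = 1L) {
  cells <- model$cells[model$cells$phase == phase, ]
  p0 <- model$zero_prob[[phase]]
  n <- length(z_iu)
  with_seed(seed, {
    out <- list()
    for (ci in seq_len(nrow(cells))) {
      m <- cells$raw_mean[ci] + cells$raw_slope[ci] * z_iu
      amp <- pmax(0, rep(m, each = trials_per_cell) +
                    rnorm(n * trials_per_cell, 0, model$amplitude_noise_sd))
      amp[runif(n * trials_per_cell) < p0] <- 0
      mags <- colMeans(matrix(sqrt(amp), nrow = trials_per_cell))
      out[[ci]] <- tibble::tibble(
        subject_id = seq_len(n), phase = phase,
        condition = cells$condition[ci], time = cells$time[ci],
        magnitude = mags)
    }
    dplyr::bind_rows(out)
  })
}

# sign-based recovery of the IU-moderated extinction pattern from a set of
# simple-slope contrasts (levels -1 and +1 SD)
pattern_recovered <- function(slopes) {
  g <- function(contrast, at) slopes$estimate[slopes$contrast == contrast &
                                                slopes$at_sd == at]
  e_lo <- g("CSplus - CSminus (early)", -1)
  l_lo <- g("CSplus - CSminus (late)", -1)
  e_hi <- g("CSplus - CSminus (early)", 1)
  l_hi <- g("CSplus - CSminus (late)", 1)
  cm_hi <- g("early - late (CSminus)", 1)
  e_lo > 0 && e_lo > l_lo && l_hi > 0 && l_hi > e_hi && cm_hi > 0
}

#' Calibration study: type-I error and pattern recovery by simulation
#'
#' Repeatedly simulates cohorts at the cell level
#' ([simulate_cell_magnitudes()]), fits the extinction Condition x Time x IU
#' ANCOVA, and aggregates (a) the rejection rate of each effect at `alpha`
#' and (b) the recovery rate of the qualitative IU-moderated simple-slopes
#' sign pattern, with normal-approximation binomial confidence intervals.
#' With the default effect model this measures pattern recovery; with a
#' null model (`null_slopes = TRUE`, all IU slopes zeroed) the
#' Condition x Time x IU rejection rate estimates the type-I error.
#'
#' @param n_replicates number of simulated cohorts (>= 1).
#' @param n_subjects subjects per cohort (34 emulates the analyzed sample).
#' @param model an [effect_model()].
#' @param null_slopes zero all IU slopes (type-I error regime).
#' @param alpha nominal test level.
#' @param seed master seed.
#' @return Tibble `metric`, `rate`, `ci_lo`, `ci_hi`, `n_replicates`
#'   (CIs `NA` when `n_replicates = 1`).
#' @export
run_calibration_study <- function(n_replicates = 500, n_subjects = 34,
                                  model = effect_model(),
                                  null_slopes = FALSE, alpha = 0.05,
                                  seed = 1L) {
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  if (null_slopes) model$cells$raw_slope <- 0
  qd <- questionnaire_defaults()
  rej_3way <- logical(n_replicates)
  recovered <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    z <- with_seed(child_seed(seed, r, 21L), rnorm(n_subjects))
    cells <- simulate_cell_magnitudes(z, model,
                                      seed = child_seed(seed, r, 22L))
    cov_tbl <- tibble::tibble(subject_id = seq_len(n_subjects),
                              iu = qd$means["iu"] + qd$sds["iu"] * z)
    fit <- fit_rm_ancova(cells, cov_tbl, "condition_by_time")
    p3 <- fit$effects$p[fit$effects$effect == "Condition x Time x IU"]
    rej_3way[r] <- p3 < alpha
    recovered[r] <- pattern_recovered(simple_slope_contrasts(fit))
  }
  ci <- function(p) {
    if (n_replicates < 2) return(c(NA_real_, NA_real_))
    se <- sqrt(p * (1 - p) / n_replicates)
    c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
  }
  rows <- list(
    c(metric = "three_way_interaction_rejection", rate = mean(rej_3way)),
    c(metric = "pattern_recovery", rate = mean(recovered))
  )
  dplyr::bind_rows(lapply(rows, function(r) {
    p <- as.numeric(r["rate"]); bounds <- ci(p)
    tibble::tibble(metric = r[["metric"]], rate = p,
                   ci_lo = bounds[1], ci_hi = bounds[2],
                   n_replicates = n_replicates)
  }))
}
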