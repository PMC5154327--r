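#' Conditioning-task design configuration
#'
#' Defaults describe a differential fear conditioning task with a 24-trial
#' acquisition phase (12 CS+, 12 CS-, 100% reinforcement), a 32-trial
#' extinction phase (16/16, unreinforced) and an optional partial
#' reacquisition phase (16 CS+ of which 4 unpaired, 14 CS-) that is generated
#' but never analysed. Trial timing: 1.5 s cue, aversive sound starting 0.5 s
#' after CS+ onset for 1 s, 3.0-6.45 s blank, 4 s uneasiness rating,
#' 1.0-2.5 s blank before the next cue.
#'
#' @param n_acquisition_csplus,n_acquisition_csminus trials per condition in
#'   acquisition.
#' @param n_extinction_csplus,n_extinction_csminus trials per condition in
#'   extinction.
#' @param include_reacquisition generate the (unanalysed) reacquisition phase.
#' @param n_reacquisition_csplus,n_reacquisition_unpaired_csplus,n_reacquisition_csminus
#'   reacquisition composition; of the CS+ trials, `n_reacquisition_unpaired_csplus`
#'   carry no US (partial reinforcement).
#' @param reinforcement_rate_acquisition proportion of acquisition CS+ trials
#'   followed by the US.
#' @param max_run_length maximum allowed run of one condition in the
#'   pseudo-randomized order.
#' @param cs_duration_s,us_onset_offset_s,us_duration_s,rating_duration_s
#'   stimulus timings in seconds.
#' @param iti_blank_range_s,post_rating_blank_range_s jitter intervals
#'   (length-2 numeric, seconds) for the blank screens before and after the
#'   rating scale.
#' @param lead_in_s quiet recording time before the first cue.
#' @param inter_phase_gap_s quiet gap between phase blocks.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_acquisition_csplus = 12L,
                          n_acquisition_csminus = 12L,
                          n_extinction_csplus = 16L,
                          n_extinction_csminus = 16L,
                          include_reacquisition = FALSE,
                          n_reacquisition_csplus = 16L,
                          n_reacquisition_unpaired_csplus = 4L,
                          n_reacquisition_csminus = 14L,
                          reinforcement_rate_acquisition = 1.0,
                          max_run_length = 3L,
                          cs_duration_s = 1.5,
                          us_onset_offset_s = 0.5,
                          us_duration_s = 1.0,
                          iti_blank_range_s = c(3.0, 6.45),
                          rating_duration_s = 4.0,
                          post_rating_blank_range_s = c(1.0, 2.5),
                          lead_in_s = 10,
                          inter_phase_gap_s = 20) {
  cfg <- list(
    n_acquisition_csplus = as.integer(n_acquisition_csplus),
    n_acquisition_csminus = as.integer(n_acquisition_csminus),
    n_extinction_csplus = as.integer(n_extinction_csplus),
    n_extinction_csminus = as.integer(n_extinction_csminus),
    include_reacquisition = isTRUE(include_reacquisition),
    n_reacquisition_csplus = as.integer(n_reacquisition_csplus),
    n_reacquisition_unpaired_csplus = as.integer(n_reacquisition_unpaired_csplus),
    n_reacquisition_csminus = as.integer(n_reacquisition_csminus),
    reinforcement_rate_acquisition = reinforcement_rate_acquisition,
    max_run_length = as.integer(max_run_length),
    cs_duration_s = cs_duration_s,
    us_onset_offset_s = us_onset_offset_s,
    us_duration_s = us_duration_s,
    iti_blank_range_s = as.numeric(iti_blank_range_s),
    rating_duration_s = rating_duration_s,
    post_rating_blank_range_s = as.numeric(post_rating_blank_range_s),
    lead_in_s = lead_in_s,
    inter_phase_gap_s = inter_phase_gap_s
  )
  validate_design_config(cfg)
  class(cfg) <- "design_config"
  cfg
}

validate_design_config <- function(cfg) {
  counts <- c(cfg$n_acquisition_csplus, cfg$n_acquisition_csminus,
              cfg$n_extinction_csplus, cfg$n_extinction_csminus)
  if (any(counts <= 0L)) stop_invalid("all per-phase condition counts must be > 0")
  if (cfg$max_run_length < 1L) stop_invalid("max_run_length must be >= 1")
  for (nm in c("iti_blank_range_s", "post_rating_blank_range_s")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop_invalid(nm, " must be an interval with lower <= upper")
  }
  if (cfg$reinforcement_rate_acquisition < 0 || cfg$reinforcement_rate_acquisition > 1)
    stop_invalid("reinforcement_rate_acquisition must be in [0, 1]")
  invisible(cfg)
}

# Pseudo-randomize condition labels: rejection-sample permutations until no
# run of identical conditions exceeds max_run; uniform over admissible orders.
pseudo_randomize <- function(labels, max_run, max_tries = 10000L) {
  if (max_run >= length(labels)) return(sample(labels))
  for (i in seq_len(max_tries)) {
    perm <- sample(labels)
    if (max_run_length(perm) <= max_run) return(perm)
  }
  stop_invalid("run-length constraint infeasible: no admissible order found in ",
               max_tries, " attempts (max_run_length = ", max_run, ")")
}

phase_trials <- function(phase, cfg) {
  switch(phase,
    acquisition = {
      cond <- pseudo_randomize(
        rep(c("CSplus", "CSminus"),
            c(cfg$n_acquisition_csplus, cfg$n_acquisition_csminus)),
        cfg$max_run_length)
      us <- cond == "CSplus" &
        runif(length(cond)) <= cfg$reinforcement_rate_acquisition
      list(condition = cond, us = us)
    },
    extinction = {
      cond <- pseudo_randomize(
        rep(c("CSplus", "CSminus"),
            c(cfg$n_extinction_csplus, cfg$n_extinction_csminus)),
        cfg$max_run_length)
      list(condition = cond, us = rep(FALSE, length(cond)))
    },
    reacquisition = {
      cond <- pseudo_randomize(
        rep(c("CSplus", "CSminus"),
            c(cfg$n_reacquisition_csplus, cfg$n_reacquisition_csminus)),
        cfg$max_run_length)
      us <- cond == "CSplus"
      unpaired <- sample(which(cond == "CSplus"),
                         cfg$n_reacquisition_unpaired_csplus)
      us[unpaired] <- FALSE
      list(condition = cond, us = us)
    },
    stop_invalid("unknown phase: ", phase))
}

#' Generate a pseudo-randomized trial sequence
#'
#' Draws a per-phase condition order by rejection sampling of random
#' permutations until no more than `max_run_length` identical conditions
#' occur in a row, assigns the US to CS+ trials at the configured
#' reinforcement rate, and returns one row per trial. Onset columns are `NA`
#' until [schedule_timings()] fills them.
#'
#' @param config a [design_config()].
#' @param seed integer seed; the same seed reproduces the sequence exactly.
#' @return A tibble with columns `phase`, `index_in_phase`, `condition`,
#'   `us_present`, `cs_onset_s`, `rating_onset_s`.
#' @export
generate_trial_sequence <- function(config = design_config(), seed = 1L) {
  validate_design_config(config)
  phases <- c("acquisition", "extinction",
              if (config$include_reacquisition) "reacquisition")
  with_seed(seed, {
    rows <- lapply(phases, function(ph) {
      tr <- phase_trials(ph, config)
      tibble::tibble(
        phase = ph,
        index_in_phase = seq_along(tr$condition),
        condition = tr$condition,
        us_present = tr$us
      )
    })
    out <- dplyr::bind_rows(rows)
    out$cs_onset_s <- NA_real_
    out$rating_onset_s <- NA_real_
    out
  })
}

#' Counterbalance cue colour across subjects
#'
#' Assigns the CS+ role to the blue square for half of the subjects and to
#' the yellow square for the other half (counts differ by at most one for odd
#' `n_subjects`), in randomized order.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed.
#' @return A tibble with columns `subject_id` and `csplus_color`.
#' @export
assign_counterbalance <- function(n_subjects, seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_invalid("n_subjects must be >= 1")
  n_subjects <- as.integer(n_subjects)
  with_seed(seed, {
    colors <- rep(c("blue", "yellow"), length.out = n_subjects)
    tibble::tibble(
      subject_id = seq_len(n_subjects),
      csplus_color = sample(colors)
    )
  })
}

#' Fill in stimulus onset times
#'
#' Walks the trial sequence in order, drawing the two jittered blank
#' durations uniformly from their configured ranges. Within a trial the
#' timeline is cue (`cs_duration_s`), blank (`iti_blank_range_s`), rating
#' scale (`rating_duration_s`), blank (`post_rating_blank_range_s`); phases
#' are separated by `inter_phase_gap_s`.
#'
#' @param sequence tibble from [generate_trial_sequence()].
#' @param config a [design_config()].
#' @param seed integer seed for the jitter draws.
#' @return The sequence with `cs_onset_s` and `rating_onset_s` filled;
#'   `cs_onset_s` is strictly increasing.
#' @export
schedule_timings <- function(sequence, config = design_config(), seed = 1L) {
  validate_design_config(config)
  n <- nrow(sequence)
  with_seed(seed, {
    blank1 <- runif(n, config$iti_blank_range_s[1], config$iti_blank_range_s[2])
    blank2 <- runif(n, config$post_rating_blank_range_s[1],
                    config$post_rating_blank_range_s[2])
    cs_onset <- numeric(n)
    rating_onset <- numeric(n)
    t <- config$lead_in_s
    prev_phase <- sequence$phase[1]
    for (i in seq_len(n)) {
      if (sequence$phase[i] != prev_phase) {
        t <- t + config$inter_phase_gap_s
        prev_phase <- sequence$phase[i]
      }
      cs_onset[i] <- t
      rating_onset[i] <- t + config$cs_duration_s + blank1[i]
      t <- rating_onset[i] + config$rating_duration_s + blank2[i]
    }
    sequence$cs_onset_s <- cs_onset
    sequence$rating_onset_s <- rating_onset
    sequence
  })
}

#' Convenience: generate and schedule one subject's session
#' @inheritParams generate_trial_sequence
#' @param order_seed,timing_seed separate seeds for the condition order and
#'   the timing jitter; by default both derive from `seed`.
#' @return A scheduled trial tibble.
#' @export
generate_session <- function(config = design_config(), seed = 1L,
                             order_seed = seed, timing_seed = seed + 1L) {
  seqn <- generate_trial_sequence(config, seed = order_seed)
  schedule_timings(seqn, config, seed = timing_seed)
}
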