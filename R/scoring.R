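#' SCR scoring configuration
#'
#' Rules for event-related trough-to-peak scoring: a response is counted
#' when its onset (trough) lies within `onset_window_s` after the CS onset
#' and its trough-to-peak rise exceeds `min_amplitude_uS` (0.03 µS default);
#' the peak may fall after the window. The signal is low-pass filtered at
#' `smoothing_cutoff_hz` before differentiation; the peak is the point where
#' the smoothed derivative turns negative or stays below
#' `peak_flatten_eps_uS_per_s` for `flatten_sustain_s` ("flattening out"),
#' searched up to `peak_search_limit_s` after the SCR onset or the next CS
#' onset, whichever is earlier.
#'
#' @param min_amplitude_uS minimum trough-to-peak rise, µS.
#' @param onset_window_s length-2 window (seconds after CS onset) in which
#'   the SCR onset must fall.
#' @param smoothing_cutoff_hz low-pass cutoff for the smoothing filter.
#' @param peak_flatten_eps_uS_per_s derivative tolerance for "flat".
#' @param flatten_sustain_s how long the derivative must stay flat.
#' @param peak_search_limit_s cap on the trough-to-peak search.
#' @param artifact_z_threshold robust-z threshold for motion artifacts
#'   (applied to the high-pass residual of both channels).
#' @param pulse_lowpass_hz low-pass cutoff used to form the pulse channel's
#'   residual; higher than the electrodermal cutoff because the pulse wave
#'   itself carries faster physiological content.
#' @param response_selection `"first"` (default) scores the first qualifying
#'   SCR whose onset is in-window; `"largest"` the biggest.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(min_amplitude_uS = 0.03,
                           onset_window_s = c(0, 7),
                           smoothing_cutoff_hz = 2,
                           peak_flatten_eps_uS_per_s = 0.001,
                           flatten_sustain_s = 0.2,
                           peak_search_limit_s = 10,
                           artifact_z_threshold = 6,
                           pulse_lowpass_hz = 4,
                           response_selection = c("first", "largest")) {
  if (min_amplitude_uS <= 0) stop_invalid("min_amplitude_uS must be > 0")
  if (length(onset_window_s) != 2L || onset_window_s[1] >= onset_window_s[2])
    stop_invalid("onset_window_s must be an interval with lower < upper")
  if (peak_search_limit_s <= 0) stop_invalid("peak_search_limit_s must be > 0")
  structure(list(min_amplitude_uS = min_amplitude_uS,
                 onset_window_s = onset_window_s,
                 smoothing_cutoff_hz = smoothing_cutoff_hz,
                 peak_flatten_eps_uS_per_s = peak_flatten_eps_uS_per_s,
                 flatten_sustain_s = flatten_sustain_s,
                 peak_search_limit_s = peak_search_limit_s,
                 artifact_z_threshold = artifact_z_threshold,
                 pulse_lowpass_hz = pulse_lowpass_hz,
                 response_selection = match.arg(response_selection)),
            class = "scoring_config")
}

#' Square-root transform of an SCR amplitude
#'
#' Applied to reduce the right skew of raw amplitudes; zero responses map
#' to zero.
#'
#' @param amplitude_uS amplitude(s) in µS, >= 0.
#' @return sqrt(µS) values.
#' @export
sqrt_transform <- function(amplitude_uS) {
  if (any(amplitude_uS < 0)) stop_invalid("amplitudes must be >= 0")
  sqrt(amplitude_uS)
}

#' Coerce a long-format signals table to a physio recording
#'
#' Validates uniform sampling (within 1e-6 s jitter) and infers the rate.
#'
#' @param df data frame with `time_s`, `eda_uS` and optionally `pulse`.
#' @param truth optional ground-truth trial table.
#' @return A `physio_recording`.
#' @export
as_physio_recording <- function(df, truth = NULL) {
  stopifnot(all(c("time_s", "eda_uS") %in% names(df)))
  dt <- diff(df$time_s)
  if (length(dt) < 1L) stop_invalid("recording needs at least 2 samples")
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6)
    stop_invalid("non-uniform sampling: time_s must advance in equal steps")
  structure(list(fs_hz = 1 / mean(dt), eda = df$eda_uS,
                 pulse = if ("pulse" %in% names(df)) df$pulse else NULL,
                 truth = truth),
            class = "physio_recording")
}

# Zero-phase low-pass smoothing; identity when the cutoff is at/above Nyquist.
lowpass <- function(x, fs, cutoff) {
  if (cutoff >= fs / 2) return(x)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Trough-to-peak detection on a pre-smoothed series. Returns amplitude 0
# when no qualifying response begins inside the onset window.
detect_scr_series <- function(y_s, fs, cs_onset_s, config,
                              next_cs_onset_s = Inf) {
  n <- length(y_s)
  w_lo <- cs_onset_s + config$onset_window_s[1]
  w_hi <- cs_onset_s + config$onset_window_s[2]
  if (w_lo < 0 || floor(w_hi * fs) + 1L > n)
    stop_invalid("scoring window [", w_lo, ", ", w_hi,
                 "] falls outside the recording")
  dy <- diff(y_s) * fs                      # dy[i]: slope from sample i to i+1
  i_lo <- max(2L, floor(w_lo * fs) + 1L)
  i_hi <- min(n - 1L, floor(w_hi * fs) + 1L)
  idx <- i_lo:i_hi
  troughs <- idx[dy[idx - 1L] <= 0 & dy[idx] > 0]  # local minima in-window
  if (length(troughs) == 0L)
    return(list(amplitude_uS = 0, latency_s = NA_real_))
  k_sustain <- max(1L, round(config$flatten_sustain_s * fs))
  best <- NULL
  for (i in troughs) {
    t_trough <- (i - 1L) / fs
    cap_t <- min(t_trough + config$peak_search_limit_s, next_cs_onset_s)
    cap <- min(n - 1L, floor(cap_t * fs) + 1L)
    if (cap <= i) next
    s <- (i + 1L):cap
    seg <- dy[s]
    j_dec <- s[match(TRUE, seg < 0)]
    flat <- seg <= config$peak_flatten_eps_uS_per_s
    j_flat <- NA_integer_
    r <- rle(flat)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= k_sustain)
    if (length(hit) > 0L) j_flat <- s[starts[hit[1L]]]
    peak <- suppressWarnings(min(j_dec, j_flat, na.rm = TRUE))
    if (!is.finite(peak)) peak <- s[which.max(y_s[s])]
    amp <- y_s[peak] - y_s[i]
    if (amp >= config$min_amplitude_uS) {
      # onset refinement: zero-phase smoothing smears the rise backwards, so
      # the trough sample precedes the physiological onset; report latency at
      # the 5%-of-amplitude upward crossing instead
      ons <- i + match(TRUE, y_s[i:peak] - y_s[i] > 0.05 * amp) - 2L
      if (is.na(ons)) ons <- i
      cand <- list(amplitude_uS = amp,
                   latency_s = (ons - 1L) / fs - cs_onset_s)
      if (config$response_selection == "first") return(cand)
      if (is.null(best) || amp > best$amplitude_uS) best <- cand
    }
  }
  if (is.null(best)) list(amplitude_uS = 0, latency_s = NA_real_) else best
}

#' Detect the event-related SCR for one trial
#'
#' Smooths the electrodermal channel, finds candidate rises (local minimum
#' followed by a rise) whose onset lies in the scoring window after the CS,
#' walks each rise to its peak ("maximum deflection prior to the signal
#' flattening out or decreasing") and scores the trough-to-peak difference.
#' Responses below the minimum amplitude, or with no onset in-window, score
#' zero.
#'
#' @param recording a `physio_recording`.
#' @param cs_onset_s CS onset, seconds from recording start.
#' @param config a [scoring_config()].
#' @param next_cs_onset_s onset of the following trial (caps the peak
#'   search); `Inf` for the last trial.
#' @return List with `amplitude_uS` and `latency_s` (`NA` when zero).
#' @export
detect_scr <- function(recording, cs_onset_s, config = scoring_config(),
                       next_cs_onset_s = Inf) {
  y_s <- lowpass(recording$eda, recording$fs_hz, config$smoothing_cutoff_hz)
  detect_scr_series(y_s, recording$fs_hz, cs_onset_s, config, next_cs_onset_s)
}

#' Flag a motion artifact in one trial window
#'
#' Computes the high-pass residual (signal minus its low-pass component) of
#' both the electrodermal and pulse channels, standardizes each by its
#' recording-wide robust z (median/MAD), and flags the trial only when the
#' residual exceeds the threshold in BOTH channels inside the trial window
#' (conjunctive rule). With no pulse channel the rule cannot apply: never
#' flags, with a warning.
#'
#' @param recording a `physio_recording`.
#' @param cs_onset_s trial CS onset, seconds.
#' @param config a [scoring_config()].
#' @return Logical flag.
#' @export
flag_artifact <- function(recording, cs_onset_s, config = scoring_config()) {
  flag_artifacts(recording, cs_onset_s, config)
}

# vectorized over trial onsets; residuals computed once per recording
flag_artifacts <- function(recording, cs_onsets_s, config = scoring_config()) {
  if (is.null(recording$pulse)) {
    warning("no pulse channel: conjunctive artifact rule disabled, no trials flagged")
    return(rep(FALSE, length(cs_onsets_s)))
  }
  fs <- recording$fs_hz
  robust_z <- function(x, cutoff) {
    res <- x - lowpass(x, fs, cutoff)
    scale <- mad(res)
    if (scale < 1e-12) scale <- sd(res)
    if (!is.finite(scale) || scale < 1e-12) return(rep(0, length(res)))
    abs(res - median(res)) / scale
  }
  z_eda <- robust_z(recording$eda, config$smoothing_cutoff_hz)
  z_pulse <- robust_z(recording$pulse, config$pulse_lowpass_hz)
  n <- length(z_eda)
  vapply(cs_onsets_s, function(on) {
    j <- (floor((on + config$onset_window_s[1]) * fs) + 1L):
      min(n, floor((on + config$onset_window_s[2]) * fs) + 1L)
    max(z_eda[j]) > config$artifact_z_threshold &&
      max(z_pulse[j]) > config$artifact_z_threshold
  }, logical(1))
}

#' Score every trial of a session
#'
#' Applies [detect_scr()] per trial (peak search capped at the next CS
#' onset), flags motion artifacts with the conjunctive two-channel rule,
#' marks the first trial of each phase excluded, and square-root transforms
#' amplitudes.
#'
#' @param recording a `physio_recording`.
#' @param events scheduled trial tibble aligned with the recording;
#'   defaults to the recording's ground-truth table when present.
#' @param config a [scoring_config()].
#' @return A tibble of scored trials: `phase`, `trial_index`, `condition`,
#'   `time`, `amplitude_uS`, `amplitude_sqrt`, `onset_latency_s`, `is_zero`,
#'   `artifact`, `excluded_first_trial` (plus `subject_id` if present in
#'   `events`).
#' @export
score_session <- function(recording, events = recording$truth,
                          config = scoring_config()) {
  if (is.null(events)) stop_invalid("no events supplied and recording has no truth table")
  ev <- label_trial_cells(events)
  fs <- recording$fs_hz
  y_s <- lowpass(recording$eda, fs, config$smoothing_cutoff_hz)
  n_tr <- nrow(ev)
  next_on <- c(ev$cs_onset_s[-1L], Inf)
  amp <- numeric(n_tr); lat <- rep(NA_real_, n_tr)
  for (i in seq_len(n_tr)) {
    d <- detect_scr_series(y_s, fs, ev$cs_onset_s[i], config, next_on[i])
    amp[i] <- d$amplitude_uS; lat[i] <- d$latency_s
  }
  art <- flag_artifacts(recording, ev$cs_onset_s, config)
  out <- tibble::tibble(
    phase = ev$phase,
    trial_index = ev$index_in_phase,
    condition = ev$condition,
    time = ev$time,
    amplitude_uS = amp,
    amplitude_sqrt = sqrt_transform(amp),
    onset_latency_s = lat,
    is_zero = amp == 0,
    artifact = art,
    excluded_first_trial = ev$index_in_phase == 1L
  )
  if ("subject_id" %in% names(ev))
    out <- dplyr::bind_cols(tibble::tibble(subject_id = ev$subject_id), out)
  out
}

#' Reduce scored trials to condition x time magnitude cells
#'
#' Cell magnitude = mean of square-root transformed amplitudes INCLUDING
#' zero responses, over usable trials (artifact-flagged and first-of-phase
#' trials are dropped). Extinction cells are the first 8 vs last 8 trials
#' per condition by presentation order (the `time` labels carried by the
#' scored table); acquisition has one cell per condition.
#'
#' @param scored scored-trial tibble from [score_session()] (one subject).
#' @return A tibble `phase`, `condition`, `time`, `magnitude`, `n_trials`.
#' @export
compute_cell_magnitudes <- function(scored) {
  expected <- dplyr::distinct(scored, .data$phase, .data$condition, .data$time)
  usable <- dplyr::filter(scored, !.data$artifact, !.data$excluded_first_trial)
  cells <- usable |>
    dplyr::group_by(.data$phase, .data$condition, .data$time) |>
    dplyr::summarise(magnitude = mean(.data$amplitude_sqrt),
                     n_trials = dplyr::n(), .groups = "drop")
  missing <- dplyr::anti_join(expected, cells,
                              by = c("phase", "condition", "time"))
  if (nrow(missing) > 0L) {
    stop(structure(class = c("missing_cell", "error", "condition"),
                   list(message = paste0(
                     "no usable trials in cell(s): ",
                     paste(missing$phase, missing$condition, missing$time,
                           collapse = "; ")),
                     call = NULL)))
  }
  cells
}

#' Reduce per-trial ratings to condition (x time) means
#'
#' Arithmetic means per phase x condition x time cell; no first-trial
#' exclusion (that rule applies to SCR scoring only).
#'
#' @param ratings tibble from [simulate_ratings()] (one subject), or any
#'   trial table with `phase`, `condition`, `time`, `rating`.
#' @return A tibble `phase`, `condition`, `time`, `mean_rating`, `n_trials`.
#' @export
reduce_ratings <- function(ratings) {
  expected <- dplyr::distinct(ratings, .data$phase, .data$condition, .data$time)
  if (any(is.na(ratings$rating)))
    ratings <- dplyr::filter(ratings, !is.na(.data$rating))
  cells <- ratings |>
    dplyr::group_by(.data$phase, .data$condition, .data$time) |>
    dplyr::summarise(mean_rating = mean(.data$rating),
                     n_trials = dplyr::n(), .groups = "drop")
  missing <- dplyr::anti_join(expected, cells,
                              by = c("phase", "condition", "time"))
  if (nrow(missing) > 0L)
    stop(structure(class = c("missing_cell", "error", "condition"),
                   list(message = "rating cell with no observations", call = NULL)))
  cells
}
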