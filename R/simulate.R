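#' Canonical skin-conductance response kernel parameters
#'
#' Bi-exponential (Bateman-type) SCR shape with a rise and decay time
#' constant, plus the latency distribution of response onset after the CS.
#' Defaults: tau_rise 0.75 s, tau_decay 2.5 s, latency mean 1.5 s, SD 0.3 s.
#'
#' @param tau_rise,tau_decay rise/decay time constants, seconds
#'   (0 < tau_rise < tau_decay).
#' @param latency_mean_s,latency_sd_s onset latency distribution, seconds.
#' @return A list of class `kernel_params`.
#' @export
kernel_params <- function(tau_rise = 0.75, tau_decay = 2.5,
                          latency_mean_s = 1.5, latency_sd_s = 0.3) {
  if (tau_rise <= 0 || tau_rise >= tau_decay)
    stop_invalid("need 0 < tau_rise < tau_decay")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 latency_mean_s = latency_mean_s,
                 latency_sd_s = latency_sd_s),
            class = "kernel_params")
}

#' Evaluate the unit SCR kernel
#'
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / c`, rescaled by the
#' analytic peak value `c` so the maximum is exactly 1; zero at `t = 0` and
#' for `t < 0`, decaying to zero as `t` grows. The peak occurs at
#' `t* = log(tau_decay/tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)`.
#'
#' @param t time since response onset, seconds (vectorized).
#' @param params a [kernel_params()].
#' @return Unit response values in `[0, 1]`.
#' @export
scr_kernel <- function(t, params = kernel_params()) {
  tr <- params$tau_rise; td <- params$tau_decay
  tstar <- log(td / tr) * tr * td / (td - tr)
  peak <- exp(-tstar / td) - exp(-tstar / tr)
  v <- ifelse(t < 0, 0, (exp(-t / td) - exp(-t / tr)) / peak)
  pmax(v, 0)
}

#' @rdname scr_kernel
#' @export
scr_kernel_peak_time <- function(params = kernel_params()) {
  with(params, log(tau_decay / tau_rise) * tau_rise * tau_decay /
         (tau_decay - tau_rise))
}

# Label each trial with its analysis cell: acquisition collapses over time
# ("all"); extinction splits each condition into its first half ("early")
# and last half ("late") by presentation order.
label_trial_cells <- function(events, n_early = 8L) {
  events |>
    dplyr::group_by(.data$phase, .data$condition) |>
    dplyr::mutate(
      time = dplyr::case_when(
        phase != "extinction" ~ "all",
        rank(.data$index_in_phase) <= n_early ~ "early",
        TRUE ~ "late"
      )
    ) |>
    dplyr::ungroup()
}

#' Draw ground-truth per-trial SCR amplitudes and latencies
#'
#' For each trial the raw amplitude is
#' `max(0, raw_mean + raw_slope * z_iu + Normal(0, noise_sd))`, set to zero
#' with the phase's zero-response probability; onset latency is normal,
#' floored at 0.2 s. This truth table is what the trough-to-peak scorer is
#' tested against.
#'
#' @param events scheduled trial tibble (see [generate_session()]).
#' @param z_iu the subject's standardized IU score.
#' @param model an [effect_model()].
#' @param kernel a [kernel_params()] (latency distribution).
#' @param seed integer seed.
#' @return `events` plus `time`, `true_amplitude_uS`, `true_latency_s`,
#'   `artifact` columns.
#' @export
draw_trial_truth <- function(events, z_iu, model = effect_model(),
                             kernel = kernel_params(), seed = 1L) {
  ev <- label_trial_cells(events)
  key <- paste(ev$phase, ev$condition, ev$time)
  cells <- model$cells
  ckey <- paste(cells$phase, cells$condition, cells$time)
  idx <- match(key, ckey)
  if (anyNA(idx))
    stop_invalid("effect model lacks cells for: ",
                 paste(unique(key[is.na(idx)]), collapse = ", "))
  n <- nrow(ev)
  with_seed(seed, {
    amp <- pmax(0, cells$raw_mean[idx] + cells$raw_slope[idx] * z_iu +
                  rnorm(n, 0, model$amplitude_noise_sd))
    zero <- runif(n) < model$zero_prob[ev$phase]
    amp[zero] <- 0
    lat <- pmax(0.2, rnorm(n, kernel$latency_mean_s, kernel$latency_sd_s))
    ev$true_amplitude_uS <- amp
    ev$true_latency_s <- lat
    ev$artifact <- FALSE
    ev
  })
}

#' Render a continuous physiological recording from trial truth
#'
#' Electrodermal channel = tonic level + slow random-walk drift + the sum of
#' per-trial `amplitude x kernel(t - cs_onset - latency)` responses + white
#' noise, floored at zero µS. The pulse channel is a schematic periodic wave
#' (~1.2 Hz) used only to corroborate motion artifacts, not analysed.
#'
#' @param truth tibble from [draw_trial_truth()].
#' @param kernel a [kernel_params()].
#' @param fs sampling rate, Hz (>= 20).
#' @param tonic_level baseline skin conductance, µS.
#' @param drift_sd random-walk innovation SD per sqrt-second, µS.
#' @param noise_sd white measurement noise SD, µS.
#' @param tail_s recording time after the last CS onset.
#' @param seed integer seed (noise and drift only; amplitudes live in
#'   `truth`).
#' @return A list of class `physio_recording` with `fs_hz`, `eda`, `pulse`
#'   and the `truth` table.
#' @export
render_recording <- function(truth, kernel = kernel_params(), fs = 50,
                             tonic_level = 2, drift_sd = 0.005,
                             noise_sd = 0.005, tail_s = 20, seed = 1L) {
  if (fs < 20) stop_invalid("fs must be >= 20 Hz to resolve the SCR kernel")
  dur <- max(truth$cs_onset_s) + tail_s
  n <- ceiling(dur * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  # kernel support: truncate where the tail is negligible
  supp_s <- kernel$tau_decay * 12
  kvec <- scr_kernel(seq(0, supp_s, by = 1 / fs), kernel)
  eda <- rep(tonic_level, n)
  for (i in seq_len(nrow(truth))) {
    a <- truth$true_amplitude_uS[i]
    if (a <= 0) next
    i0 <- floor((truth$cs_onset_s[i] + truth$true_latency_s[i]) * fs) + 1L
    i1 <- min(n, i0 + length(kvec) - 1L)
    if (i0 > n) next
    eda[i0:i1] <- eda[i0:i1] + a * kvec[seq_len(i1 - i0 + 1L)]
  }
  with_seed(seed, {
    if (drift_sd > 0)
      eda <- eda + cumsum(rnorm(n, 0, drift_sd / sqrt(fs)))
    if (noise_sd > 0)
      eda <- eda + rnorm(n, 0, noise_sd)
    pulse <- sin(2 * pi * 1.2 * tt) + rnorm(n, 0, 0.02)
  })
  structure(list(fs_hz = fs, eda = pmax(eda, 0), pulse = pulse,
                 truth = truth),
            class = "physio_recording")
}

#' Simulate one subject's recording
#'
#' Composes [draw_trial_truth()] and [render_recording()].
#'
#' @inheritParams draw_trial_truth
#' @inheritParams render_recording
#' @param events scheduled trial tibble.
#' @return A `physio_recording`.
#' @export
simulate_recording <- function(events, z_iu = 0, model = effect_model(),
                               kernel = kernel_params(), fs = 50,
                               tonic_level = 2, drift_sd = 0.005,
                               noise_sd = 0.005, seed = 1L) {
  truth <- draw_trial_truth(events, z_iu, model, kernel, seed = seed)
  render_recording(truth, kernel, fs, tonic_level, drift_sd, noise_sd,
                   seed = seed + 1L)
}

#' Simulate per-trial uneasiness ratings
#'
#' Latent normal draw (cell mean + subject intercept + noise), rounded to the
#' nearest integer and clamped to the 1-9 scale.
#'
#' @param events scheduled trial tibble.
#' @param model a [rating_model()].
#' @param seed integer seed.
#' @return `events` plus `time` and integer `rating` columns.
#' @export
simulate_ratings <- function(events, model = rating_model(), seed = 1L) {
  ev <- label_trial_cells(events)
  key <- paste(ev$phase, ev$condition, ev$time)
  cells <- model$cells
  idx <- match(key, paste(cells$phase, cells$condition, cells$time))
  if (anyNA(idx))
    stop_invalid("rating model lacks cells for: ",
                 paste(unique(key[is.na(idx)]), collapse = ", "))
  with_seed(seed, {
    intercept <- rnorm(1, 0, model$subject_sd)
    latent <- cells$latent_mean[idx] + intercept +
      rnorm(nrow(ev), 0, model$noise_sd)
    ev$rating <- as.integer(pmin(9, pmax(1, round(latent))))
    ev
  })
}

#' Inject motion artifacts into a recording
#'
#' Adds a sharp 0.1 s triangular transient to BOTH the electrodermal and
#' pulse channels inside the scoring window (0-7 s post CS onset) of the
#' selected trials, and marks those trials in the ground-truth table.
#'
#' @param recording a `physio_recording`.
#' @param trial_indices row indices into `recording$truth`.
#' @param magnitude transient height, µS (and pulse units).
#' @param seed integer seed for the transient's placement.
#' @return The modified `physio_recording`.
#' @export
inject_artifacts <- function(recording, trial_indices, magnitude = 1.0,
                             seed = 1L) {
  truth <- recording$truth
  if (length(trial_indices) == 0L) return(recording)
  if (any(trial_indices < 1L | trial_indices > nrow(truth)))
    stop_invalid("trial index out of range")
  fs <- recording$fs_hz
  n <- length(recording$eda)
  half <- max(1L, round(0.05 * fs))
  shape <- c(seq_len(half), rev(seq_len(half))) / half
  with_seed(seed, {
    for (i in trial_indices) {
      t0 <- truth$cs_onset_s[i] + runif(1, 0.5, 6.5)
      j0 <- floor(t0 * fs) + 1L
      j <- j0:min(n, j0 + length(shape) - 1L)
      recording$eda[j] <- recording$eda[j] + magnitude * shape[seq_along(j)]
      recording$pulse[j] <- recording$pulse[j] + magnitude * shape[seq_along(j)]
    }
  })
  recording$truth$artifact[trial_indices] <- TRUE
  recording
}
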