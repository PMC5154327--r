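# Amplitude effect model: per-cell raw amplitude means/IU-slopes calibrated
# so that sqrt-scale magnitudes (zeros included) hit their targets.

# E[sqrt(max(0, X))] for X ~ N(m, sd); the scored amplitude of a responsive
# trial is truncated at zero before the square-root transform.
expected_sqrt_amplitude <- function(m, sd) {
  if (sd <= 0) return(sqrt(max(0, m)))
  integrate(function(x) sqrt(x) * dnorm(x, m, sd),
            lower = 0, upper = m + 12 * sd,
            rel.tol = 1e-10)$value
}

#' Calibrate a raw amplitude cell mean to a sqrt-scale magnitude target
#'
#' Finds the raw (microSiemens) mean `m` such that a trial drawn as
#' `max(0, Normal(m, noise_sd))`, zeroed with probability `zero_prob`, has
#' expected square-root amplitude (zeros included) equal to `target_sqrt`.
#'
#' @param target_sqrt target mean magnitude on the sqrt(µS) scale.
#' @param zero_prob probability a trial yields no response.
#' @param noise_sd trial-to-trial amplitude SD in µS.
#' @return Raw mean amplitude in µS.
#' @export
calibrate_raw_mean <- function(target_sqrt, zero_prob, noise_sd) {
  if (target_sqrt < 0) stop_invalid("target_sqrt must be >= 0")
  if (zero_prob < 0 || zero_prob > 1)
    stop_invalid("zero_prob must be in [0, 1]")
  # with certain zero-response the raw mean is unidentified (and unused)
  if (target_sqrt == 0 || zero_prob == 1) return(0)
  want <- target_sqrt / (1 - zero_prob)
  f <- function(m) expected_sqrt_amplitude(m, noise_sd) - want
  upper <- max(1, want^2 * 4)
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, lower = -10 * max(noise_sd, 0.01), upper = upper,
          tol = 1e-10)$root
}

#' IU-moderated amplitude effect model
#'
#' Defines, for every phase x condition x time cell, the sqrt-scale magnitude
#' the cell should show at average IU (`sqrt_target`) and its change per 1 SD
#' of IU (`sqrt_slope`), together with per-phase zero-response probabilities
#' and the trial-level amplitude noise. Raw-amplitude means and slopes are
#' solved numerically so that the generative model
#' `amplitude = max(0, raw_mean + raw_slope * z_iu + Normal(0, noise_sd))`,
#' zeroed with probability `zero_prob[phase]`, reproduces the sqrt-scale
#' targets at z_iu in {-1, 0, +1}.
#'
#' The default cells reproduce the observed magnitude table (acquisition
#' CS+ 0.79 / CS- 0.32; extinction early CS+ 0.32 / CS- 0.29, late CS+ 0.29 /
#' CS- 0.22 sqrt-µS) and the default slopes encode the IU-moderated
#' extinction pattern: at low IU (-1 SD) early CS+ > CS- with equal late
#' cells; at high IU (+1 SD) equal early cells, late CS+ > CS-, and CS-
#' early > CS- late. Acquisition slopes are zero (no IU moderation there).
#'
#' @param cells tibble with columns `phase`, `condition`, `time`,
#'   `sqrt_target`, `sqrt_slope`.
#' @param zero_prob named per-phase zero-response probabilities.
#' @param amplitude_noise_sd trial-level amplitude SD, µS.
#' @return A list of class `effect_model`; `$cells` gains `raw_mean` and
#'   `raw_slope` columns.
#' @export
effect_model <- function(cells = default_effect_cells(),
                         zero_prob = c(acquisition = 0.33, extinction = 0.53),
                         amplitude_noise_sd = 0.15) {
  stopifnot(all(c("phase", "condition", "time", "sqrt_target", "sqrt_slope")
                %in% names(cells)))
  if (any(cells$sqrt_target < 0)) stop_invalid("cell targets must be >= 0")
  if (any(zero_prob < 0 | zero_prob > 1))
    stop_invalid("zero probabilities must be in [0, 1]")
  cal <- function(target, p0) calibrate_raw_mean(target, p0, amplitude_noise_sd)
  p0 <- zero_prob[cells$phase]
  m0 <- mapply(cal, cells$sqrt_target, p0)
  mp <- mapply(cal, pmax(0, cells$sqrt_target + cells$sqrt_slope), p0)
  mm <- mapply(cal, pmax(0, cells$sqrt_target - cells$sqrt_slope), p0)
  cells$raw_mean <- m0
  cells$raw_slope <- (mp - mm) / 2
  structure(list(cells = cells, zero_prob = zero_prob,
                 amplitude_noise_sd = amplitude_noise_sd),
            class = "effect_model")
}

#' @rdname effect_model
#' @export
default_effect_cells <- function() {
  tibble::tribble(
    ~phase, ~condition, ~time, ~sqrt_target, ~sqrt_slope,
    "acquisition", "CSplus", "all", 0.79, 0,
    "acquisition", "CSminus", "all", 0.32, 0,
    "extinction", "CSplus", "early", 0.32, 0,
    "extinction", "CSminus", "early", 0.29, 0.03,
    "extinction", "CSplus", "late", 0.29, 0.05,
    "extinction", "CSminus", "late", 0.22, -0.03
  )
}

#' Model-implied sqrt-scale cell means at a given IU z-score
#'
#' Evaluates the generative model's expected magnitude (zeros included) per
#' cell at standardized IU `z`, by the same truncation/zero-inflation
#' arithmetic used for calibration.
#'
#' @param model an [effect_model()].
#' @param z standardized IU value.
#' @return The model's `cells` tibble with an `expected_sqrt` column.
#' @export
model_cell_means <- function(model, z = 0) {
  cells <- model$cells
  p0 <- model$zero_prob[cells$phase]
  m <- cells$raw_mean + cells$raw_slope * z
  cells$expected_sqrt <- mapply(function(mi, pi) {
    (1 - pi) * expected_sqrt_amplitude(mi, model$amplitude_noise_sd)
  }, m, p0)
  cells
}

# ---- ratings -----------------------------------------------------------

# E[clamp(round(X), 1, 9)] for X ~ N(mu, sd)
expected_clamped_rating <- function(mu, sd) {
  if (sd <= 0) return(min(9, max(1, round(mu))))
  k <- 1:9
  lo <- c(-Inf, k[-9] + 0.5)
  hi <- c(k[-9] + 0.5, Inf)
  p <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
  sum(k * p)
}

calibrate_rating_latent <- function(target, sd) {
  if (target < 1 || target > 9) stop_invalid("rating cell mean must be in [1, 9]")
  if (sd <= 0) return(target)
  f <- function(mu) expected_clamped_rating(mu, sd) - target
  uniroot(f, lower = -5, upper = 15, tol = 1e-10)$root
}

#' Uneasiness rating generative model
#'
#' Per-cell means on the 1-9 rating scale plus a subject-level intercept and
#' trial noise. Ratings are produced as a latent normal draw, rounded and
#' clamped to 1..9; with `calibrate = TRUE` (default) the latent cell means
#' are adjusted so the post-rounding expectation matches `cell_means`
#' exactly. Defaults follow the observed rating table (acquisition CS+ 6.14 /
#' CS- 3.10; extinction early CS+ 3.12 / CS- 2.41, late CS+ 2.28 / CS- 1.86)
#' with no IU moderation of ratings.
#'
#' @param cell_means tibble with `phase`, `condition`, `time`, `mean`.
#' @param subject_sd SD of the per-subject intercept.
#' @param noise_sd trial-level latent noise SD.
#' @param calibrate adjust latent means for rounding/clamping bias.
#' @return A list of class `rating_model`.
#' @export
rating_model <- function(cell_means = default_rating_cells(),
                         subject_sd = 0.7, noise_sd = 0.8,
                         calibrate = TRUE) {
  stopifnot(all(c("phase", "condition", "time", "mean") %in% names(cell_means)))
  # calibrated targets must be attainable on the 1-9 scale; raw latent means
  # (calibrate = FALSE) may fall outside it and rely on clamping
  if (calibrate && any(cell_means$mean < 1 | cell_means$mean > 9))
    stop_invalid("rating cell means must lie within the 1-9 scale")
  total_sd <- sqrt(subject_sd^2 + noise_sd^2)
  cell_means$latent_mean <- if (calibrate) {
    vapply(cell_means$mean, calibrate_rating_latent, numeric(1), sd = total_sd)
  } else cell_means$mean
  structure(list(cells = cell_means, subject_sd = subject_sd,
                 noise_sd = noise_sd),
            class = "rating_model")
}

#' @rdname rating_model
#' @export
default_rating_cells <- function() {
  tibble::tribble(
    ~phase, ~condition, ~time, ~mean,
    "acquisition", "CSplus", "all", 6.14,
    "acquisition", "CSminus", "all", 3.10,
    "extinction", "CSplus", "early", 3.12,
    "extinction", "CSminus", "early", 2.41,
    "extinction", "CSplus", "late", 2.28,
    "extinction", "CSminus", "late", 1.86
  )
}
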