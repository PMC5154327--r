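# single-trial recording builder: one kernel response of known amplitude
one_trial_recording <- function(amplitude, latency = 2, cs_onset = 10,
                                fs = 50, tonic = 2) {
  ev <- generate_session(design_config(n_acquisition_csplus = 1,
                                       n_acquisition_csminus = 1,
                                       n_extinction_csplus = 1,
                                       n_extinction_csminus = 1), seed = 1)
  tr <- draw_trial_truth(ev[1, ], z_iu = 0, seed = 1)
  tr$cs_onset_s <- cs_onset
  tr$true_amplitude_uS <- amplitude
  tr$true_latency_s <- latency
  render_recording(tr, fs = fs, tonic_level = tonic, drift_sd = 0,
                   noise_sd = 0, seed = 1)
}

test_that("constant and sub-threshold signals score zero", {
  flat <- one_trial_recording(0)
  d <- detect_scr(flat, 10)
  expect_equal(d$amplitude_uS, 0)
  small <- one_trial_recording(0.02)
  expect_equal(detect_scr(small, 10)$amplitude_uS, 0)  # below 0.03 µS
})

test_that("a noiseless injected response is recovered within tolerance", {
  rec <- one_trial_recording(0.5, latency = 2)
  d <- detect_scr(rec, 10)
  expect_equal(d$amplitude_uS, 0.5, tolerance = 0.02)
  expect_equal(d$latency_s, 2, tolerance = 0.2)
})

test_that("responses with onsets outside the 0-7 s window are not counted", {
  rec <- one_trial_recording(0.5, latency = 8)
  expect_equal(detect_scr(rec, 10)$amplitude_uS, 0)
  # but a late PEAK with an in-window onset still counts
  rec2 <- one_trial_recording(0.5, latency = 6.5)
  expect_equal(detect_scr(rec2, 10)$amplitude_uS, 0.5, tolerance = 0.02)
})

test_that("scoring windows outside the recording raise an error", {
  rec <- one_trial_recording(0.5)
  expect_error(detect_scr(rec, 1e5), "outside the recording")
})

test_that("non-uniformly sampled input is rejected, uniform accepted", {
  df <- data.frame(time_s = c(0, 0.02, 0.05, 0.06), eda_uS = rep(2, 4))
  expect_error(as_physio_recording(df), "non-uniform")
  df2 <- data.frame(time_s = seq(0, 1, by = 0.02), eda_uS = 2)
  rec <- as_physio_recording(df2)
  expect_equal(rec$fs_hz, 50)
})

test_that("sqrt transform maps amplitudes and reduces skew", {
  expect_equal(sqrt_transform(0), 0)
  expect_equal(sqrt_transform(0.49), 0.7)
  expect_error(sqrt_transform(-0.1), ">= 0")
  set.seed(8)
  raw <- exp(rnorm(5000, log(0.4), 0.8))   # log-normal amplitudes
  expect_lt(sample_skewness(sqrt_transform(raw)), sample_skewness(raw))
})

test_that("artifact flagging requires distortion in both channels", {
  ev <- generate_session(seed = 3)
  rec <- simulate_recording(ev, z_iu = 0, seed = 3)
  onsets <- rec$truth$cs_onset_s
  expect_false(any(flag_artifacts(rec, onsets)))     # clean recording
  rec_both <- inject_artifacts(rec, 5L, magnitude = 1, seed = 1)
  expect_true(flag_artifacts(rec_both, onsets)[5])
  # transient in the electrodermal channel only: conjunctive rule holds off
  rec_eda <- rec
  j <- floor((onsets[5] + 3) * rec$fs_hz) + 1:5
  rec_eda$eda[j] <- rec_eda$eda[j] + 1
  expect_false(flag_artifacts(rec_eda, onsets)[5])
})

test_that("artifact detection on labelled synthetic data has high recall", {
  hits <- 0L; total <- 0L
  for (s in 1:6) {
    ev <- generate_session(seed = s)
    rec <- simulate_recording(ev, z_iu = 0, seed = s + 50)
    idx <- withr::with_seed(s, sample(nrow(ev), 2))  # ~1.4% of 2x56 trials
    rec <- inject_artifacts(rec, idx, magnitude = 1, seed = s)
    fl <- flag_artifacts(rec, rec$truth$cs_onset_s)
    hits <- hits + sum(fl[idx]); total <- total + length(idx)
  }
  expect_gte(hits / total, 0.9)
})

test_that("a missing pulse channel disables flagging with a warning", {
  ev <- generate_session(seed = 2)
  rec <- simulate_recording(ev, seed = 2)
  rec$pulse <- NULL
  expect_warning(fl <- flag_artifacts(rec, rec$truth$cs_onset_s), "pulse")
  expect_false(any(fl))
})

test_that("session scoring excludes the first trial of each phase", {
  ev <- generate_session(seed = 5)
  rec <- simulate_recording(ev, seed = 5)
  sc <- suppressWarnings(score_session(rec))
  expect_equal(nrow(sc), 56L)
  expect_equal(sum(sc$excluded_first_trial[sc$phase == "acquisition"]), 1L)
  expect_equal(sum(sc$excluded_first_trial[sc$phase == "extinction"]), 1L)
  expect_true(all(sc$amplitude_sqrt == sqrt(sc$amplitude_uS)))
  expect_true(all(sc$is_zero == (sc$amplitude_uS == 0)))
})

test_that("an all-flat recording scores every trial zero", {
  ev <- generate_session(seed = 7)
  m0 <- effect_model(zero_prob = c(acquisition = 1, extinction = 1))
  rec <- simulate_recording(ev, model = m0, drift_sd = 0, noise_sd = 0,
                            seed = 7)
  sc <- score_session(rec)
  expect_true(all(sc$amplitude_uS == 0))
})

test_that("scorer recovers injected amplitudes across sampling rates", {
  ev <- generate_session(seed = 11)
  truth <- draw_trial_truth(ev, z_iu = 0, seed = 11)
  rec50 <- render_recording(truth, fs = 50, drift_sd = 0, noise_sd = 0, seed = 1)
  rec250 <- render_recording(truth, fs = 250, drift_sd = 0, noise_sd = 0, seed = 1)
  a50 <- score_session(rec50)$amplitude_uS
  a250 <- score_session(rec250)$amplitude_uS
  resp <- truth$true_amplitude_uS > 0.05
  expect_equal(a50[resp], a250[resp], tolerance = 0.02)
})

test_that("raising the minimum amplitude never increases a cell magnitude", {
  ev <- generate_session(seed = 13)
  rec <- simulate_recording(ev, z_iu = 0, seed = 13)
  m_lo <- compute_cell_magnitudes(score_session(rec, config = scoring_config()))
  m_hi <- compute_cell_magnitudes(
    score_session(rec, config = scoring_config(min_amplitude_uS = 0.25)))
  joined <- merge(m_lo, m_hi, by = c("phase", "condition", "time"))
  expect_true(all(joined$magnitude.y <= joined$magnitude.x + 1e-12))
})

test_that("cell magnitudes average sqrt values including zeros", {
  sc <- make_scored(rep("CSplus", 4), c(0.8, 0, 0, 0))
  m <- compute_cell_magnitudes(sc)
  expect_equal(m$magnitude, 0.2)
  expect_equal(m$n_trials, 4L)
  # zero-inclusion: magnitude never exceeds the mean of non-zero responses
  expect_lte(m$magnitude, 0.8)
  sc_art <- make_scored(rep("CSplus", 4), c(0.8, 0, 0, 0), artifact = TRUE)
  expect_error(compute_cell_magnitudes(sc_art), class = "missing_cell")
})

test_that("rating reduction takes plain cell means without exclusions", {
  ev <- generate_session(seed = 1)
  r <- simulate_ratings(ev, rating_model(subject_sd = 0, noise_sd = 0), seed = 1)
  r$rating <- 3L
  red <- reduce_ratings(r)
  expect_true(all(red$mean_rating == 3))
  r2 <- r[r$phase == "extinction" & r$condition == "CSplus", ][1:2, ]
  r2$rating <- c(2L, 4L)
  expect_equal(reduce_ratings(r2)$mean_rating, 3)
})
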