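test_that("questionnaire sampling reproduces the requested moments", {
  p <- sample_questionnaires(10000, seed = 1)
  expect_equal(mean(p$iu), 63.92, tolerance = 0.5 / 63.92)
  expect_lt(abs(mean(p$stai) - 44.02), 0.5)
  expect_lt(abs(mean(p$pswq) - 51.60), 0.5)
  expect_true(all(p$iu >= 27 & p$iu <= 135))
  expect_true(all(p$stai >= 20 & p$stai <= 80))
  # default inter-correlation 0.6 (truncation shrinks it slightly)
  expect_lt(abs(cor(p$iu, p$stai) - 0.6), 0.03)
  expect_identical(sample_questionnaires(50, seed = 3),
                   sample_questionnaires(50, seed = 3))
})

test_that("identity correlation gives near-independent instruments", {
  qd <- questionnaire_defaults()
  p <- sample_questionnaires(10000, correlation = diag(3) |>
                               `dimnames<-`(dimnames(qd$correlation)),
                             seed = 2)
  expect_lt(abs(cor(p$iu, p$stai)), 0.03)
  expect_lt(abs(cor(p$iu, p$pswq)), 0.03)
})

test_that("non-positive-semi-definite correlation is rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3,
                dimnames = list(c("iu", "stai", "pswq"),
                                c("iu", "stai", "pswq")))
  expect_error(sample_questionnaires(10, correlation = bad),
               "positive semi-definite")
})

test_that("SCR kernel is normalized with the analytic peak time", {
  kp <- kernel_params()
  expect_equal(scr_kernel(0, kp), 0)
  expect_equal(scr_kernel(-1, kp), 0)
  tt <- seq(0, 20, by = 1e-4)
  expect_equal(max(scr_kernel(tt, kp)), 1.0, tolerance = 1e-6)
  t_star <- log(kp$tau_decay / kp$tau_rise) * kp$tau_decay * kp$tau_rise /
    (kp$tau_decay - kp$tau_rise)
  expect_equal(tt[which.max(scr_kernel(tt, kp))], t_star, tolerance = 1e-3)
  expect_equal(scr_kernel_peak_time(kp), t_star)
  expect_lt(scr_kernel(60, kp), 1e-8)
  expect_error(kernel_params(tau_rise = 3, tau_decay = 2), "tau_rise")
})

test_that("noise-free rendering conserves the injected amplitude", {
  ev <- generate_session(design_config(n_acquisition_csplus = 1,
                                       n_acquisition_csminus = 1,
                                       n_extinction_csplus = 1,
                                       n_extinction_csminus = 1), seed = 1)
  tr <- draw_trial_truth(ev[1, ], z_iu = 0, seed = 1)
  tr$true_amplitude_uS <- 0.5
  tr$true_latency_s <- 2
  rec <- render_recording(tr, fs = 1000, tonic_level = 2,
                          drift_sd = 0, noise_sd = 0, seed = 1)
  expect_equal(max(rec$eda) - 2, 0.5, tolerance = 1e-6)
  # restricted to the trial, signal - baseline equals amplitude x kernel
  t_grid <- (seq_along(rec$eda) - 1) / rec$fs_hz
  expect_equal(rec$eda - 2,
               0.5 * scr_kernel(t_grid - tr$cs_onset_s[1] - 2),
               tolerance = 1e-9)
})

test_that("zero-probability one forces all-zero truth amplitudes", {
  ev <- generate_session(seed = 2)
  m <- effect_model(zero_prob = c(acquisition = 1, extinction = 1))
  tr <- draw_trial_truth(ev, z_iu = 0, model = m, seed = 3)
  expect_true(all(tr$true_amplitude_uS == 0))
})

test_that("truth-level zero fractions follow the configured probabilities", {
  m <- effect_model()
  zeros <- vapply(1:12, function(i) {
    ev <- generate_session(seed = i)
    tr <- draw_trial_truth(ev, z_iu = 0, model = m, seed = 100 + i)
    c(mean(tr$true_amplitude_uS[tr$phase == "acquisition"] == 0),
      mean(tr$true_amplitude_uS[tr$phase == "extinction"] == 0))
  }, numeric(2))
  expect_lt(abs(mean(zeros[1, ]) - 0.33), 0.05)
  expect_lt(abs(mean(zeros[2, ]) - 0.53), 0.05)
})

test_that("raising a cell mean raises that cell's expected magnitude", {
  m <- effect_model()
  m2 <- m
  m2$cells$raw_mean[3] <- m2$cells$raw_mean[3] + 0.3
  z <- rep(0, 400)
  a <- simulate_cell_magnitudes(z, m, seed = 5)
  b <- simulate_cell_magnitudes(z, m2, seed = 5)
  cell3 <- function(x) mean(x$magnitude[x$condition == "CSplus" &
                                          x$time == "early"])
  other <- function(x) mean(x$magnitude[x$condition == "CSminus" &
                                          x$time == "late"])
  expect_gt(cell3(b), cell3(a))
  expect_equal(other(b), other(a))
})

test_that("default effect model encodes the IU-moderated extinction pattern", {
  m <- effect_model()
  get <- function(tbl, cond, tm) {
    tbl$expected_sqrt[tbl$phase == "extinction" & tbl$condition == cond &
                        tbl$time == tm]
  }
  lo <- model_cell_means(m, z = -1)
  hi <- model_cell_means(m, z = 1)
  # low IU: early differential, late cells equal
  expect_gt(get(lo, "CSplus", "early") - get(lo, "CSminus", "early"), 0.03)
  expect_lt(abs(get(lo, "CSplus", "late") - get(lo, "CSminus", "late")), 0.02)
  # high IU: early cells equal, late differential, safety cue drops
  expect_lt(abs(get(hi, "CSplus", "early") - get(hi, "CSminus", "early")), 0.02)
  expect_gt(get(hi, "CSplus", "late") - get(hi, "CSminus", "late"), 0.05)
  expect_gt(get(hi, "CSminus", "early") - get(hi, "CSminus", "late"), 0.05)
})

test_that("rating simulation hits cell targets and respects the scale", {
  ev <- generate_session(seed = 1)
  # zero noise, uncalibrated cell mean 6.14 rounds every rating to 6
  cells <- default_rating_cells()
  m0 <- rating_model(cells, subject_sd = 0, noise_sd = 0, calibrate = FALSE)
  r0 <- simulate_ratings(ev, m0, seed = 1)
  acq_plus <- r0$rating[r0$phase == "acquisition" & r0$condition == "CSplus"]
  expect_true(all(acq_plus == 6L))
  # clamp floor: latent mean 0.5 yields all ones
  cells$mean <- 0.5
  mfloor <- rating_model(cells, subject_sd = 0, noise_sd = 0, calibrate = FALSE)
  expect_true(all(simulate_ratings(ev, mfloor, seed = 2)$rating == 1L))
  # calibrated large-sample mean: extinction CS- (early+late pooled) ~ 2.14
  mdef <- rating_model()
  rats <- unlist(lapply(1:300, function(i) {
    r <- simulate_ratings(ev, mdef, seed = i)
    r$rating[r$phase == "extinction" & r$condition == "CSminus"]
  }))
  expect_equal(mean(rats), 2.14, tolerance = 0.1 / 2.14)
  expect_true(all(rats >= 1 & rats <= 9))
})

test_that("artifact injection labels exactly the chosen trials in both channels", {
  ev <- generate_session(seed = 6)
  rec <- simulate_recording(ev, seed = 6)
  expect_identical(inject_artifacts(rec, integer(0)), rec)
  rec1 <- inject_artifacts(rec, 17L, magnitude = 1, seed = 2)
  expect_equal(sum(rec1$truth$artifact), 1L)
  expect_equal(which(rec1$truth$artifact), 17L)
  expect_gt(max(abs(rec1$eda - rec$eda)), 0.5)
  expect_gt(max(abs(rec1$pulse - rec$pulse)), 0.5)
  expect_error(inject_artifacts(rec, 999L), "out of range")
})

test_that("recordings are deterministic under a seed and rate-valid", {
  ev <- generate_session(seed = 4)
  a <- simulate_recording(ev, z_iu = 0.3, seed = 9)
  b <- simulate_recording(ev, z_iu = 0.3, seed = 9)
  expect_identical(a$eda, b$eda)
  expect_true(all(a$eda >= 0))
  expect_error(simulate_recording(ev, fs = 10), "fs")
})
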