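# Independent oracles used across tests: explicit normal-equations /
# model-comparison least squares, kept free of lm() and of the package's
# ANCOVA code path.

ols_rss <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

# model-comparison F for dropping one column of [1, x]
oracle_contrast_F <- function(y, x) {
  n <- length(y)
  Xf <- cbind(1, x)
  rss_full <- ols_rss(Xf, y)
  ms_err <- rss_full / (n - 2)
  list(
    within = (ols_rss(matrix(x, ncol = 1), y) - rss_full) / ms_err,
    moderation = (ols_rss(matrix(1, n, 1), y) - rss_full) / ms_err
  )
}

# brute-force RM-ANCOVA on a wide 2x2 cell matrix + covariate: all seven Fs
oracle_rm_ancova <- function(wide, cov_raw) {
  iu_c <- cov_raw - mean(cov_raw)
  pe <- wide$CSplus_early; me <- wide$CSminus_early
  pl <- wide$CSplus_late; ml <- wide$CSminus_late
  sc <- list(
    G = (pe + me + pl + ml) / 4,
    C = (pe + pl) / 2 - (me + ml) / 2,
    T = (pe + me) / 2 - (pl + ml) / 2,
    X = (pe - me) - (pl - ml)
  )
  f <- lapply(sc, oracle_contrast_F, x = iu_c)
  c("Condition" = f$C$within, "Condition x IU" = f$C$moderation,
    "Time" = f$T$within, "Time x IU" = f$T$moderation,
    "Condition x Time" = f$X$within,
    "Condition x Time x IU" = f$X$moderation,
    "IU" = f$G$moderation)
}

oracle_r_squared <- function(X, y) {
  1 - ols_rss(cbind(1, X), y) / sum((y - mean(y))^2)
}

# random small wide cell dataset for oracle-equivalence checks
random_wide_cells <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    subject_id = seq_len(n),
    CSplus_early = rnorm(n, 0.3, 0.2),
    CSminus_early = rnorm(n, 0.25, 0.2),
    CSplus_late = rnorm(n, 0.28, 0.2),
    CSminus_late = rnorm(n, 0.2, 0.2)
  )
}

wide_to_long <- function(wide) {
  tidyr::pivot_longer(wide, -subject_id, names_to = c("condition", "time"),
                      names_sep = "_", values_to = "value") |>
    dplyr::mutate(phase = "extinction")
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# minimal scored-trial table builder for learning / reduction tests
make_scored <- function(condition, amplitude_sqrt, phase = "extinction",
                        trial_index = seq_along(condition),
                        artifact = FALSE, excluded = FALSE,
                        time = "early", subject_id = 1L) {
  tibble::tibble(
    subject_id = subject_id, phase = phase, trial_index = trial_index,
    condition = condition, time = time,
    amplitude_uS = amplitude_sqrt^2, amplitude_sqrt = amplitude_sqrt,
    onset_latency_s = ifelse(amplitude_sqrt > 0, 2, NA_real_),
    is_zero = amplitude_sqrt == 0,
    artifact = rep_len(artifact, length(condition)),
    excluded_first_trial = rep_len(excluded, length(condition))
  )
}
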