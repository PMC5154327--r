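test_that("mean centering sums to zero over the analyzed values", {
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(mean_center(rep(5, 4)), rep(0, 4))
  set.seed(2)
  iu <- rnorm(34, 64, 19)
  expect_lt(abs(sum(mean_center(iu))), 1e-10)
  expect_error(mean_center(c(NA_real_, NA_real_)), "finite")
})

test_that("partial eta squared satisfies its identity and printed values", {
  expect_equal(partial_eta_squared(0, 1, 30), 0)
  expect_equal(partial_eta_squared(30, 1, 30), 0.5)  # F = df2 gives one half
  f <- seq(0.5, 50, by = 0.5)
  expect_true(all(diff(partial_eta_squared(f, 1, 32)) > 0))
  expect_error(partial_eta_squared(-1, 1, 30), ">= 0")
})

test_that("ANCOVA F values match the brute-force least-squares oracle", {
  worst <- 0
  for (s in 1:50) {
    n <- sample(6:14, 1)
    wide <- random_wide_cells(n, seed = 1000 + s)
    cov_raw <- rnorm(n, 64, 19)
    fit <- fit_rm_ancova(wide_to_long(wide),
                         tibble::tibble(subject_id = wide$subject_id,
                                        iu = cov_raw))
    want <- oracle_rm_ancova(wide, cov_raw)
    got <- setNames(fit$effects$F, fit$effects$effect)[names(want)]
    worst <- max(worst, max(abs(got - want)))
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
    expect_true(all(fit$effects$df2 == n - 2))
  }
  expect_lt(worst, 1e-8)
})

test_that("constant covariate reduces the Condition test to a one-sample t", {
  set.seed(5)
  n <- 16
  wide <- random_wide_cells(n, seed = 77)
  wide$CSplus_early <- wide$CSminus_early + 0.15 + rnorm(n, 0, 0.1)
  wide$CSplus_late <- wide$CSminus_late + 0.15 + rnorm(n, 0, 0.1)
  fit <- fit_rm_ancova(wide_to_long(wide),
                       tibble::tibble(subject_id = wide$subject_id, iu = 0))
  C <- (wide$CSplus_early + wide$CSplus_late) / 2 -
    (wide$CSminus_early + wide$CSminus_late) / 2
  t_stat <- unname(t.test(C)$statistic)
  f_cond <- fit$effects$F[fit$effects$effect == "Condition"]
  expect_equal(f_cond, t_stat^2, tolerance = 1e-10)
})

test_that("degrees of freedom follow the n - 2 rule", {
  for (n in c(37, 34)) {
    wide <- random_wide_cells(n, seed = n)
    fit <- fit_rm_ancova(wide_to_long(wide),
                         tibble::tibble(subject_id = wide$subject_id,
                                        iu = rnorm(n, 64, 19)))
    expect_true(all(fit$effects$df2 == n - 2))
    expect_true(all(fit$effects$df1 == 1))
  }
})

test_that("simple slopes reproduce a linear IU dependence analytically", {
  # cell means exactly linear in the covariate: contrasts at +/-1 SD equal
  # the analytic linear combination
  n <- 20
  iu <- seq(30, 110, length.out = n)
  z <- (iu - mean(iu)) / sd(iu)
  wide <- tibble::tibble(
    subject_id = seq_len(n),
    CSplus_early = 0.32 + 0.00 * z,
    CSminus_early = 0.29 + 0.03 * z,
    CSplus_late = 0.29 + 0.05 * z,
    CSminus_late = 0.22 - 0.03 * z
  )
  # exact-linear cells: lm warns about a perfect fit, which is the point
  fit <- suppressWarnings(
    fit_rm_ancova(wide_to_long(wide),
                  tibble::tibble(subject_id = wide$subject_id, iu = iu)))
  ss <- suppressWarnings(simple_slope_contrasts(fit, at_sd = c(-1, 1)))
  g <- function(ct, at) ss$estimate[ss$contrast == ct & ss$at_sd == at]
  expect_equal(g("CSplus - CSminus (early)", -1), 0.03 + 0.03, tolerance = 1e-10)
  expect_equal(g("CSplus - CSminus (early)", 1), 0.03 - 0.03, tolerance = 1e-10)
  expect_equal(g("CSplus - CSminus (late)", 1), 0.07 + 0.08, tolerance = 1e-10)
  expect_equal(g("early - late (CSminus)", 1), 0.07 + 0.06, tolerance = 1e-10)
  # estimated marginal means evaluate each cell's regression at the level
  emm <- suppressWarnings(emm_table(fit, at_sd = c(-1, 1)))
  expect_equal(emm$estimate[emm$cell == "CSplus_late" & emm$at_sd == 1],
               0.29 + 0.05, tolerance = 1e-10)
})

test_that("without moderation the contrasts coincide across IU levels", {
  n <- 400
  wide <- random_wide_cells(n, seed = 3)
  iu <- rnorm(n, 64, 19)   # independent of the cells
  fit <- fit_rm_ancova(wide_to_long(wide),
                       tibble::tibble(subject_id = wide$subject_id, iu = iu))
  ss <- simple_slope_contrasts(fit)
  for (ct in unique(ss$contrast)) {
    d <- abs(diff(ss$estimate[ss$contrast == ct]))
    expect_lt(d, 0.1)   # Monte-Carlo error only
  }
})

test_that("difference scores are the four named cell combinations", {
  wide <- tibble::tibble(subject_id = 1L, CSplus_early = 0.32,
                         CSminus_early = 0.29, CSplus_late = 0.29,
                         CSminus_late = 0.22)
  ds <- build_difference_scores(wide_to_long(wide))
  expect_equal(ds$csminus_early_minus_late, 0.07)
  expect_equal(ds$csp_minus_csm_early, 0.03)
  expect_equal(ds$csp_minus_csm_late, 0.07)
  expect_equal(ds$csplus_early_minus_late, 0.03)
  same <- tibble::tibble(subject_id = 1L, CSplus_early = 0.4,
                         CSminus_early = 0.4, CSplus_late = 0.4,
                         CSminus_late = 0.4)
  expect_true(all(unlist(build_difference_scores(wide_to_long(same))[-1]) == 0))
})

test_that("hierarchical regression matches the normal-equations oracle", {
  set.seed(12)
  n <- 10
  d <- data.frame(stai = rnorm(n, 44, 9), pswq = rnorm(n, 52, 12),
                  iu = rnorm(n, 64, 19))
  d$y <- 0.2 + 0.01 * d$stai - 0.005 * d$pswq + 0.008 * d$iu + rnorm(n, 0, 0.1)
  h <- hierarchical_regression(d, "y", c("stai", "pswq"), "iu")
  r2_1 <- oracle_r_squared(as.matrix(d[, c("stai", "pswq")]), d$y)
  r2_2 <- oracle_r_squared(as.matrix(d[, c("stai", "pswq", "iu")]), d$y)
  expect_equal(h$steps$step1$r_squared, r2_1, tolerance = 1e-12)
  expect_equal(h$steps$step2$r_squared, r2_2, tolerance = 1e-12)
  expect_equal(h$steps$step2$delta_r_sq, r2_2 - r2_1, tolerance = 1e-12)
  # F-change identity
  fc <- (r2_2 - r2_1) / ((1 - r2_2) / (n - 3 - 1))
  expect_equal(h$steps$step2$f_change, fc, tolerance = 1e-10)
  expect_gte(h$steps$step2$delta_r_sq, 0)
})

test_that("a response exactly linear in IU gives step-2 R squared of one", {
  set.seed(4)
  n <- 12
  d <- data.frame(stai = rnorm(n), pswq = rnorm(n), iu = rnorm(n))
  d$y <- 2 + 3 * d$iu
  h <- suppressWarnings(hierarchical_regression(d, "y", c("stai", "pswq"), "iu"))
  expect_equal(h$steps$step2$r_squared, 1, tolerance = 1e-10)
})

test_that("delta R squared vanishes for an orthogonal added predictor", {
  set.seed(6)
  n <- 60
  d <- data.frame(stai = rnorm(n), pswq = rnorm(n))
  d$y <- 0.5 * d$stai + rnorm(n, 0, 0.2)
  # construct an added predictor orthogonal to y given step 1: residualize
  # pure noise against y and the step-1 block
  noise <- rnorm(n)
  d$iu <- resid(lm(noise ~ d$y + d$stai + d$pswq))
  h <- hierarchical_regression(d, "y", c("stai", "pswq"), "iu")
  expect_lt(h$steps$step2$delta_r_sq, 1e-3)
})

test_that("collinear predictors raise a rank-deficiency error naming them", {
  set.seed(7)
  d <- data.frame(stai = rnorm(10), pswq = rnorm(10))
  d$y <- rnorm(10)
  d$stai2 <- d$stai
  expect_error(hierarchical_regression(d, "y", c("stai", "pswq"), "stai2"),
               class = "rank_deficient")
  expect_error(hierarchical_regression(d, "y", c("stai", "pswq"), "stai2"),
               "stai2")
})

test_that("standardized betas come from the z-scored fit", {
  set.seed(10)
  n <- 50
  d <- data.frame(stai = rnorm(n, 44, 9), pswq = rnorm(n, 52, 12),
                  iu = rnorm(n, 64, 19))
  d$y <- 0.01 * d$iu + rnorm(n, 0, 0.1)
  h <- hierarchical_regression(d, "y", c("stai", "pswq"), "iu")
  co <- h$steps$step2$coefficients
  b_iu <- co$B[co$term == "iu"]
  beta_iu <- co$beta[co$term == "iu"]
  expect_equal(beta_iu, unname(b_iu) * sd(d$iu) / sd(d$y), tolerance = 1e-10)
})
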