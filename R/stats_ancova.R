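#' Mean-center a covariate
#'
#' Centering uses the mean of the supplied (analyzed) values, so the
#' centered vector sums to zero over the analyzed subsample.
#'
#' @param x numeric vector with at least 2 finite values.
#' @return `x - mean(x)` (NAs preserved).
#' @export
mean_center <- function(x) {
  if (sum(is.finite(x)) < 2L)
    stop_invalid("need at least 2 finite values to center")
  x - mean(x, na.rm = TRUE)
}

#' Partial eta squared for a single-df effect
#'
#' `F * df1 / (F * df1 + df2)`, the proportion of effect-plus-error variance
#' attributable to the effect.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator/denominator degrees of freedom.
#' @return Value in `[0, 1)`.
#' @export
partial_eta_squared <- function(f, df1, df2) {
  if (any(f < 0, na.rm = TRUE)) stop_invalid("F must be >= 0")
  if (any(df1 < 1, na.rm = TRUE) || any(df2 < 1, na.rm = TRUE))
    stop_invalid("degrees of freedom must be >= 1")
  f * df1 / (f * df1 + df2)
}

# value column auto-detection for cell tables
pick_value_col <- function(cells, value_col) {
  if (!is.null(value_col)) return(value_col)
  for (cand in c("value", "magnitude", "mean_rating"))
    if (cand %in% names(cells)) return(cand)
  stop_invalid("no value column found; supply value_col")
}

# long cells -> wide (one row per subject, one column per cell)
cells_to_wide <- function(cells, design, value_col = NULL) {
  value_col <- pick_value_col(cells, value_col)
  if (design == "condition_by_time") {
    w <- cells |>
      dplyr::mutate(cell = paste(.data$condition, .data$time, sep = "_")) |>
      dplyr::select("subject_id", "cell", dplyr::all_of(value_col)) |>
      tidyr::pivot_wider(names_from = "cell",
                         values_from = dplyr::all_of(value_col))
    need <- c("CSplus_early", "CSminus_early", "CSplus_late", "CSminus_late")
  } else {
    w <- cells |>
      dplyr::select("subject_id", "condition", dplyr::all_of(value_col)) |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = dplyr::all_of(value_col))
    need <- c("CSplus", "CSminus")
  }
  if (!all(need %in% names(w)))
    stop_invalid("cells are missing columns: ",
                 paste(setdiff(need, names(w)), collapse = ", "))
  w[, c("subject_id", need)]
}

# per-subject orthogonal contrast scores for the 2x2 (or 2-cell) design
contrast_scores <- function(wide, design) {
  if (design == "condition_by_time") {
    pe <- wide$CSplus_early; me <- wide$CSminus_early
    pl <- wide$CSplus_late; ml <- wide$CSminus_late
    tibble::tibble(
      subject_id = wide$subject_id,
      G = (pe + me + pl + ml) / 4,
      C = (pe + pl) / 2 - (me + ml) / 2,
      T = (pe + me) / 2 - (pl + ml) / 2,
      X = (pe - me) - (pl - ml)
    )
  } else {
    tibble::tibble(
      subject_id = wide$subject_id,
      G = (wide$CSplus + wide$CSminus) / 2,
      C = wide$CSplus - wide$CSminus
    )
  }
}

# one contrast regression on the centered moderator -> within-F (intercept)
# and moderation-F (slope), each on (1, n-2) df. A constant moderator is
# degenerate: the within test collapses to the one-sample t (df n-1) and the
# moderation effect is undefined.
contrast_regression <- function(score, iu_c) {
  n <- length(score)
  if (sd(iu_c) < 1e-12) {
    t1 <- summary(lm(score ~ 1))$coefficients[1, "t value"]
    return(tibble::tibble(
      term = c("within", "moderation"),
      F = c(t1^2, NA_real_), df1 = 1, df2 = c(n - 1, NA_real_),
      p = c(pf(t1^2, 1, n - 1, lower.tail = FALSE), NA_real_)))
  }
  s <- summary(lm(score ~ iu_c))$coefficients
  tibble::tibble(
    term = c("within", "moderation"),
    F = s[, "t value"]^2,
    df1 = 1, df2 = n - 2,
    p = pf(s[, "t value"]^2, 1, n - 2, lower.tail = FALSE)
  )
}

#' Repeated-measures ANCOVA with a continuous mean-centered moderator
#'
#' Fits the Condition x Time x moderator model (or Condition x moderator for
#' a single-time phase) via per-subject orthogonal contrast scores: each
#' within-subject contrast (Condition `C`, Time `T`, interaction `X`) and
#' the subject mean `G` is regressed on the mean-centered moderator. The
#' within-subject effect F is the squared t of that regression's intercept,
#' the effect x moderator F the squared t of its slope, and the
#' between-subject moderator effect comes from the `G` regression — all on
#' (1, n-2) degrees of freedom, exactly the classical RM-ANCOVA.
#'
#' @param cells long cell tibble: `subject_id`, `condition`
#'   (`CSplus`/`CSminus`), `time` (`early`/`late`, ignored for
#'   `condition_only`), and a value column (`value`, `magnitude` or
#'   `mean_rating`, or named via `value_col`).
#' @param covariate data frame `subject_id` + one numeric moderator column
#'   (raw scores; centered internally on the analyzed subsample).
#' @param design `"condition_by_time"` (2x2) or `"condition_only"`.
#' @param value_col optional value column name.
#' @return An object of class `rm_ancova`: `$effects` (effect, F, df1, df2,
#'   p, partial_eta_sq), `$n`, `$sd_cov` (moderator SD in the analyzed
#'   sample), `$data` (wide cells + `iu_c`), `$design`.
#' @export
fit_rm_ancova <- function(cells, covariate,
                          design = c("condition_by_time", "condition_only"),
                          value_col = NULL) {
  design <- match.arg(design)
  wide <- cells_to_wide(cells, design, value_col)
  cov_col <- setdiff(names(covariate), "subject_id")[1]
  dat <- dplyr::inner_join(wide, covariate[, c("subject_id", cov_col)],
                           by = "subject_id")
  dat <- dat[complete.cases(dat), ]
  n <- nrow(dat)
  if (n < 4L)
    stop(structure(class = c("insufficient_data", "error", "condition"),
                   list(message = paste0("only ", n, " complete subjects"),
                        call = NULL)))
  dat$iu_c <- mean_center(dat[[cov_col]])
  sc <- contrast_scores(dat, design)
  eff <- list()
  labmap <- if (design == "condition_by_time") {
    list(C = c("Condition", "Condition x IU"),
         T = c("Time", "Time x IU"),
         X = c("Condition x Time", "Condition x Time x IU"))
  } else {
    list(C = c("Condition", "Condition x IU"))
  }
  for (k in names(labmap)) {
    r <- contrast_regression(sc[[k]], dat$iu_c)
    r$effect <- labmap[[k]]
    eff[[k]] <- r
  }
  g <- contrast_regression(sc$G, dat$iu_c)
  g$effect <- c("(Intercept)", "IU")
  eff$G <- g[2, ]                         # grand intercept is not an effect
  effects <- dplyr::bind_rows(eff) |>
    dplyr::select("effect", "F", "df1", "df2", "p")
  effects$partial_eta_sq <- partial_eta_squared(effects$F, 1, effects$df2)
  structure(list(effects = effects, n = n, sd_cov = sd(dat[[cov_col]]),
                 data = dat, scores = sc, design = design,
                 covariate = cov_col),
            class = "rm_ancova")
}

#' @export
print.rm_ancova <- function(x, ...) {
  cat("Repeated-measures ANCOVA (", x$design, "), n = ", x$n,
      ", moderator = ", x$covariate, " (SD = ", round(x$sd_cov, 2), ")\n\n",
      sep = "")
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

# fitted value and SE of a per-subject score regressed on iu_c, at iu0
predict_at <- function(score, iu_c, iu0) {
  fit <- lm(score ~ iu_c)
  b <- coef(fit); V <- vcov(fit)
  xv <- c(1, iu0)
  est <- sum(b * xv)
  se <- sqrt(drop(t(xv) %*% V %*% xv))
  list(estimate = est, se = se)
}

#' Estimated marginal cell means at chosen moderator levels
#'
#' Each cell's per-subject value is regressed on the centered moderator and
#' evaluated at `at_sd` standard deviations from the mean, with standard
#' errors from the regression's coefficient covariance.
#'
#' @param result an [fit_rm_ancova()] result.
#' @param at_sd moderator levels in SD units (default -1, 0, +1).
#' @return Tibble `cell`, `at_sd`, `estimate`, `se`.
#' @export
emm_table <- function(result, at_sd = c(-1, 0, 1)) {
  cell_cols <- setdiff(names(result$data), c("subject_id", "iu_c",
                                             result$covariate))
  out <- list()
  for (a in at_sd) {
    iu0 <- a * result$sd_cov
    for (cc in cell_cols) {
      p <- predict_at(result$data[[cc]], result$data$iu_c, iu0)
      out[[length(out) + 1L]] <- tibble::tibble(
        cell = cc, at_sd = a, estimate = p$estimate, se = p$se)
    }
  }
  dplyr::bind_rows(out)
}

#' Simple-slopes pairwise contrasts at moderator levels
#'
#' For each requested moderator level (in SD units), estimates CS+ vs CS-
#' within each time half and early vs late within each condition, from the
#' whole-sample ANCOVA fit (each per-subject contrast score regressed on the
#' centered moderator and evaluated at the level) — the simple-slopes
#' analogue. t statistics use n - 2 df; p values are two-sided and
#' uncorrected.
#'
#' @param result an [fit_rm_ancova()] result.
#' @param at_sd moderator levels in SD units (default -1 and +1).
#' @return Tibble `contrast`, `at_sd`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
simple_slope_contrasts <- function(result, at_sd = c(-1, 1)) {
  d <- result$data
  defs <- if (result$design == "condition_by_time") {
    list("CSplus - CSminus (early)" = d$CSplus_early - d$CSminus_early,
         "CSplus - CSminus (late)" = d$CSplus_late - d$CSminus_late,
         "early - late (CSplus)" = d$CSplus_early - d$CSplus_late,
         "early - late (CSminus)" = d$CSminus_early - d$CSminus_late)
  } else {
    list("CSplus - CSminus" = d$CSplus - d$CSminus)
  }
  n <- result$n
  out <- list()
  for (a in at_sd) {
    iu0 <- a * result$sd_cov
    for (nm in names(defs)) {
      p <- predict_at(defs[[nm]], d$iu_c, iu0)
      tval <- p$estimate / p$se
      out[[length(out) + 1L]] <- tibble::tibble(
        contrast = nm, at_sd = a, estimate = p$estimate, se = p$se,
        t = tval, df = n - 2,
        p = 2 * pt(abs(tval), n - 2, lower.tail = FALSE))
    }
  }
  dplyr::bind_rows(out)
}

#' Extinction difference scores
#'
#' The four condition/time difference scores analysed in the hierarchical
#' regressions: CS+ - CS- early, CS+ - CS- late, CS+ early - late and
#' CS- early - late.
#'
#' @param cells long cell tibble for the extinction phase (see
#'   [fit_rm_ancova()]).
#' @param value_col optional value column name.
#' @return Tibble with `subject_id` and the four difference scores.
#' @export
build_difference_scores <- function(cells, value_col = NULL) {
  w <- cells_to_wide(cells, "condition_by_time", value_col)
  if (anyNA(w))
    stop(structure(class = c("missing_cell", "error", "condition"),
                   list(message = "missing cell value", call = NULL)))
  tibble::tibble(
    subject_id = w$subject_id,
    csp_minus_csm_early = w$CSplus_early - w$CSminus_early,
    csp_minus_csm_late = w$CSplus_late - w$CSminus_late,
    csplus_early_minus_late = w$CSplus_early - w$CSplus_late,
    csminus_early_minus_late = w$CSminus_early - w$CSminus_late
  )
}
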