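#' Hierarchical (stepwise-entry) regression with delta R squared
#'
#' Ordinary least squares in nested steps: step 1 regresses the response on
#' the step-1 predictors (trait anxiety and worry by convention), step 2
#' adds the step-2 predictors (IU). Reports per step the unstandardized
#' coefficients with standard errors, standardized betas (from the z-scored
#' fit), R squared, the overall F, and for step 2 the R squared increment
#' with its F-change test
#' `F = (dR2 / m) / ((1 - R2_full) / (n - k_full - 1))` on
#' `(m, n - k_full - 1)` df.
#'
#' @param data data frame holding response and predictors.
#' @param response response column name (a difference score).
#' @param step1 character vector of step-1 predictor names.
#' @param step2_add character vector of predictors added at step 2.
#' @return Object of class `hier_reg`: `$steps` is a list with per-step
#'   `coefficients` (term, B, SE_B, beta), `r_squared`, `f`, `df1`, `df2`,
#'   `p`, and for step 2 `delta_r_sq`, `f_change`, `p_change`.
#' @export
hierarchical_regression <- function(data, response, step1, step2_add) {
  vars <- c(response, step1, step2_add)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L)
    stop_invalid("columns not found: ", paste(missing_cols, collapse = ", "))
  d <- data[complete.cases(data[, vars]), vars]
  n <- nrow(d)
  if (n <= length(c(step1, step2_add)) + 1L)
    stop(structure(class = c("insufficient_data", "error", "condition"),
                   list(message = "too few complete cases for the full model",
                        call = NULL)))
  check_rank <- function(preds) {
    X <- as.matrix(cbind(1, d[, preds, drop = FALSE]))
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
      stop(structure(class = c("rank_deficient", "error", "condition"),
                     list(message = paste0("design is rank deficient; ",
                                           "collinear column(s): ",
                                           paste(dropped, collapse = ", ")),
                          call = NULL)))
    }
  }
  fit_step <- function(preds) {
    check_rank(preds)
    fml <- stats::reformulate(preds, response)
    fit <- lm(fml, data = d)
    s <- summary(fit)
    dz <- as.data.frame(lapply(d[, c(response, preds)], function(x) {
      if (sd(x) == 0) x * 0 else (x - mean(x)) / sd(x)
    }))
    beta <- coef(lm(stats::reformulate(preds, response), data = dz))[-1]
    co <- s$coefficients
    list(
      coefficients = tibble::tibble(
        term = rownames(co)[-1],
        B = co[-1, "Estimate"],
        SE_B = co[-1, "Std. Error"],
        beta = unname(beta)
      ),
      r_squared = s$r.squared,
      f = unname(s$fstatistic["value"]),
      df1 = unname(s$fstatistic["numdf"]),
      df2 = unname(s$fstatistic["dendf"]),
      p = pf(s$fstatistic["value"], s$fstatistic["numdf"],
             s$fstatistic["dendf"], lower.tail = FALSE)
    )
  }
  s1 <- fit_step(step1)
  s2 <- fit_step(c(step1, step2_add))
  m <- length(step2_add)
  k2 <- length(step1) + m
  s2$delta_r_sq <- s2$r_squared - s1$r_squared
  s2$f_change <- (s2$delta_r_sq / m) / ((1 - s2$r_squared) / (n - k2 - 1))
  s2$p_change <- pf(s2$f_change, m, n - k2 - 1, lower.tail = FALSE)
  s1$delta_r_sq <- s1$r_squared        # vs the intercept-only model
  structure(list(steps = list(step1 = s1, step2 = s2), n = n,
                 response = response),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat("Hierarchical regression of", x$response, "( n =", x$n, ")\n")
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat("\n", nm, ": R2 = ", round(s$r_squared, 3),
        ", F(", s$df1, ",", s$df2, ") = ", round(s$f, 3),
        if (!is.null(s$f_change))
          paste0(", dR2 = ", round(s$delta_r_sq, 3),
                 ", F-change = ", round(s$f_change, 3)),
        "\n", sep = "")
    print(as.data.frame(s$coefficients), row.names = FALSE, digits = 3)
  }
  invisible(x)
}
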