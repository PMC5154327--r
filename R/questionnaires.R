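#' Default questionnaire calibration
#'
#' Instrument means, SDs and admissible score ranges for the three trait
#' measures: Intolerance of Uncertainty (IU, 27 items, range 27-135), trait
#' anxiety (STAIX-2, range 20-80) and worry (PSWQ, range 16-80). Defaults
#' are the sample descriptives the generator emulates (IU M = 63.92,
#' SD = 19.56; STAIX-2 M = 44.02, SD = 9.33; PSWQ M = 51.60, SD = 11.56).
#'
#' @return A list with `means`, `sds`, `ranges` and the default
#'   inter-instrument `correlation` matrix (0.6 between each pair, an
#'   assumption: the source descriptives do not report inter-correlations).
#' @export
questionnaire_defaults <- function() {
  list(
    means = c(iu = 63.92, stai = 44.02, pswq = 51.60),
    sds = c(iu = 19.56, stai = 9.33, pswq = 11.56),
    ranges = list(iu = c(27, 135), stai = c(20, 80), pswq = c(16, 80)),
    correlation = matrix(c(1, 0.6, 0.6,
                           0.6, 1, 0.6,
                           0.6, 0.6, 1), 3, 3,
                         dimnames = list(c("iu", "stai", "pswq"),
                                         c("iu", "stai", "pswq")))
  )
}

# core sampler: latent MVN, then out-of-range values redrawn from their
# exact truncated conditional given the subject's other scores
qsample_core <- function(n, lat_mu, lat_s, lat_corr, lo, hi) {
  k <- length(lat_mu)
  L <- chol(lat_corr + diag(1e-10, k))
  Sigma <- diag(lat_s, k) %*% lat_corr %*% diag(lat_s, k)
  z <- matrix(rnorm(n * k), n, k) %*% L
  scores <- sweep(sweep(z, 2, lat_s, `*`), 2, lat_mu, `+`)
  for (j in seq_len(k)) {
    bad <- which(scores[, j] < lo[j] | scores[, j] > hi[j])
    if (length(bad) == 0L) next
    o <- setdiff(seq_len(k), j)
    w <- solve(Sigma[o, o], Sigma[o, j])
    cm <- lat_mu[j] +
      (scores[bad, o, drop = FALSE] -
         matrix(lat_mu[o], length(bad), k - 1, byrow = TRUE)) %*% w
    cs <- sqrt(Sigma[j, j] - sum(Sigma[j, o] * w))
    u <- runif(length(bad), pnorm(lo[j], cm, cs), pnorm(hi[j], cm, cs))
    scores[bad, j] <- qnorm(u, cm, cs)
  }
  scores
}

.q_cache <- new.env(parent = emptyenv())

# fixed-point calibration of the latent location/scale/correlation so the
# generated (range-respecting) scores carry the requested moments; solved
# once per parameter set on an internal deterministic stream and cached
calibrate_questionnaire_latents <- function(means, sds, correlation,
                                            lo, hi, m = 40000L, iters = 4L) {
  key <- paste(signif(c(means, sds, correlation, lo, hi), 8), collapse = ",")
  if (!is.null(.q_cache[[key]])) return(.q_cache[[key]])
  k <- length(means)
  lat_mu <- means; lat_s <- sds; lat_corr <- correlation
  for (it in seq_len(iters)) {
    sim <- with_seed(990000L + it, {
      qsample_core(m, lat_mu, lat_s, lat_corr, lo, hi)
    })
    lat_mu <- lat_mu + (means - colMeans(sim))
    lat_s <- lat_s * sds / apply(sim, 2, sd)
    adj <- correlation - stats::cor(sim)
    diag(adj) <- 0
    lat_corr <- lat_corr + adj
    lat_corr[lat_corr > 0.999] <- 0.999
    lat_corr[lat_corr < -0.999] <- -0.999
    ev <- eigen(lat_corr, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {       # project back to the PSD cone
      v <- pmax(ev$values, 1e-8)
      lat_corr <- ev$vectors %*% diag(v) %*% t(ev$vectors)
      d <- sqrt(diag(lat_corr))
      lat_corr <- lat_corr / tcrossprod(d)
    }
  }
  out <- list(mu = lat_mu, s = lat_s, corr = lat_corr)
  .q_cache[[key]] <- out
  out
}

#' Sample a cohort's questionnaire panel
#'
#' Draws correlated range-respecting scores for IU, STAIX-2 and PSWQ from a
#' latent multivariate normal. Values falling outside an instrument's
#' admissible range are redrawn from their exact truncated conditional
#' distribution given the subject's other scores; the latent location,
#' scale and correlation are pre-calibrated by a deterministic fixed-point
#' scheme so the delivered scores carry the requested means, SDs and
#' correlations (within Monte-Carlo error).
#'
#' @param n cohort size (>= 1).
#' @param means,sds named numeric vectors over instruments.
#' @param correlation positive semi-definite correlation matrix.
#' @param ranges list of length-2 numeric admissible ranges per instrument.
#' @param seed integer seed.
#' @return A tibble with `subject_id`, `iu`, `stai`, `pswq`.
#' @export
sample_questionnaires <- function(n,
                                  means = questionnaire_defaults()$means,
                                  sds = questionnaire_defaults()$sds,
                                  correlation = questionnaire_defaults()$correlation,
                                  ranges = questionnaire_defaults()$ranges,
                                  seed = 1L) {
  if (!is.numeric(n) || n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    stop_invalid("correlation matrix is not positive semi-definite")
  inst <- colnames(correlation)
  lo <- vapply(inst, function(j) ranges[[j]][1], numeric(1))
  hi <- vapply(inst, function(j) ranges[[j]][2], numeric(1))
  cal <- calibrate_questionnaire_latents(means[inst], sds[inst], correlation,
                                         lo, hi)
  scores <- with_seed(seed, {
    qsample_core(n, cal$mu, cal$s, cal$corr, lo, hi)
  })
  out <- tibble::as_tibble(as.data.frame(scores))
  names(out) <- inst
  dplyr::bind_cols(tibble::tibble(subject_id = seq_len(n)), out)
}
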