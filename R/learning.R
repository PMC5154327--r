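#' Conditioned-response score at the start of extinction
#'
#' CR score = mean of the first two usable CS+ extinction trials minus the
#' mean of the first two usable CS- extinction trials, on either the SCR
#' sqrt-magnitude or the rating scale. A positive value indexes a
#' conditioned (differential) response. For SCR the phase-first-trial
#' exclusion and artifact flags apply before the "first 2" are selected
#' (configurable via `post_exclusion`).
#'
#' @param trials one subject's scored trials ([score_session()]) for
#'   `measure = "scr_magnitude"`, or rating trials ([simulate_ratings()])
#'   for `measure = "rating"`.
#' @param measure `"scr_magnitude"` or `"rating"`.
#' @param post_exclusion select the first two trials after dropping
#'   excluded/artifact trials (default) rather than the first two presented.
#' @return List with `measure` and `value`.
#' @export
conditioned_response_score <- function(trials,
                                       measure = c("scr_magnitude", "rating"),
                                       post_exclusion = TRUE) {
  measure <- match.arg(measure)
  ext <- dplyr::filter(trials, .data$phase == "extinction")
  if (measure == "scr_magnitude") {
    if (post_exclusion)
      ext <- dplyr::filter(ext, !.data$artifact, !.data$excluded_first_trial)
    value_col <- "amplitude_sqrt"
    idx_col <- "trial_index"
  } else {
    value_col <- "rating"
    idx_col <- "index_in_phase"
  }
  first2 <- function(cond) {
    x <- ext[ext$condition == cond, ]
    x <- x[order(x[[idx_col]]), ]
    if (nrow(x) < 2L)
      stop(structure(class = c("insufficient_data", "error", "condition"),
                     list(message = paste0("fewer than 2 usable extinction ",
                                           cond, " trials"), call = NULL)))
    mean(x[[value_col]][1:2])
  }
  list(measure = measure, value = first2("CSplus") - first2("CSminus"))
}

#' Classify a subject as learner or non-learner
#'
#' Non-learner iff the subject shows no positive differential response on
#' EITHER measure: both the SCR and the rating CR score are <= 0 (a score of
#' exactly zero counts as no differential response). A missing measure
#' defers to the other; both missing is an error.
#'
#' @param cr_scr,cr_rating CR scores (numeric or the list returned by
#'   [conditioned_response_score()]); `NULL`/`NA` if unavailable.
#' @return `"learner"` or `"non_learner"`.
#' @export
classify_learner <- function(cr_scr = NULL, cr_rating = NULL) {
  val <- function(x) {
    if (is.null(x)) return(NA_real_)
    if (is.list(x)) x <- x$value
    as.numeric(x)
  }
  v <- c(val(cr_scr), val(cr_rating))
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop(structure(class = c("insufficient_data", "error", "condition"),
                   list(message = "both CR scores missing", call = NULL)))
  if (all(v <= 0)) "non_learner" else "learner"
}
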