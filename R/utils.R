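#' @importFrom stats rnorm runif qnorm pnorm dnorm sd lm coef vcov pt pf
#'   integrate uniroot median mad complete.cases setNames rbinom
#' @importFrom utils head tail
#' @importFrom rlang .data
NULL

# Deterministic per-subject child seed from a master seed, so that subject i's
# data does not depend on cohort size. Kept strictly below 2^31.
child_seed <- function(master_seed, i, salt = 0L) {
  s <- (as.numeric(master_seed) %% 2147483647) * 48271 + i * 10007 + salt * 101
  as.integer(s %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# longest run of identical values in a vector
max_run_length <- function(x) {
  if (length(x) == 0L) return(0L)
  max(rle(as.character(x))$lengths)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
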