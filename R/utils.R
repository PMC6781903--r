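# Small internal helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Draw from a log-uniform distribution
#'
#' Density proportional to 1/x on `[lo, hi]`; used for rate, variance and
#' selection-strength priors.
#'
#' @param n number of draws
#' @param lo,hi positive bounds
#' @keywords internal
rloguniform <- function(n, lo, hi) {
  stopifnot(lo > 0, hi > lo)
  exp(stats::runif(n, log(lo), log(hi)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
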