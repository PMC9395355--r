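#' Clip values into an interval
#' @noRd
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Stop unless a condition holds, with a formatted message
#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Derive a child seed from a base seed and a stream index.
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to `set.seed()`.
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483647)
}

#' Round a proportion to an integer percent, half away from zero
#'
#' The display convention used for all reported percentages: multiply by
#' 100 and round to the nearest integer, resolving ties away from zero
#' (so 90.5 displays as 91). `round()` in R rounds half to even and is not
#' used for display.
#'
#' @param p proportion (or vector) in `[-1, 1]`.
#' @return integer percent(s); `NA` propagates.
#' @examples
#' percent_round(0.905) # 91
#' percent_round(0.5949) # 59
#' @export
percent_round <- function(p) {
  ifelse(is.na(p), NA_integer_, as.integer(sign(p) * floor(abs(p) * 100 + 0.5)))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive scores higher than a randomly chosen negative, with ties
#' counted half.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels logical or 0/1 vector of true classes.
#' @return AUROC in `[0, 1]`; `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
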