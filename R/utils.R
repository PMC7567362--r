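#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed so that stages can be re-run in isolation with identical results.
#' Kept below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param tag character stage tag
#' @return an integer seed
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# significance stars at the conventional 0.05 / 0.01 / 0.001 levels
#' @noRd
p_stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds such that every fold contains
#' (as close as possible to) the same class mix as the full sample.
#'
#' @param y class labels (factor or vector) or, for regression, any vector —
#'   a non-factor `y` is stratified on its quantile bins
#' @param k number of folds
#' @param seed integer seed for the shuffle
#' @return integer vector of fold ids in 1..k
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  set.seed(seed)
  n <- length(y)
  if (k > n) stopf("cannot make %d folds from %d observations", k, n)
  if (!is.factor(y)) {
    if (is.numeric(y) && length(unique(y)) > k) {
      y <- cut(rank(y, ties.method = "first"), breaks = min(k, 4), labels = FALSE)
    }
    y <- factor(y)
  }
  folds <- integer(n)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
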