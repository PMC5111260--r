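# Shared validators and small helpers.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_in <- function(x, field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be a single number")
  }
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    abort_field(field, sprintf(
      "must be in %s%s, %s%s but is %s",
      if (lo_open) "(" else "[", format(lo), format(hi),
      if (hi_open) ")" else "]", format(x)
    ))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort_field(field, sprintf("must be an integer >= %d", min))
  }
  as.integer(x)
}

check_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg), call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have gene row names and sample column names", arg), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    stop(sprintf("duplicate gene id in `%s`: '%s'", arg, dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1L]
    stop(sprintf("duplicate sample id in `%s`: '%s'", arg, dup), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("`%s` contains negative values; expression must be non-negative", arg), call. = FALSE)
  }
  invisible(x)
}

#' Empirical one-tailed p-value from a permutation null
#'
#' Uses the add-one estimator `(1 + #\{null >= observed\}) / (B + 1)`, which is
#' never zero and corresponds to including the observed statistic in its own
#' null ensemble.
#'
#' @param observed Observed statistic (scalar).
#' @param null Numeric vector of null statistics.
#' @return A single p-value in (0, 1].
#' @examples
#' empirical_p(5, c(3, 5, 7))  # (1 + 2) / 4 = 0.75
#' @export
empirical_p <- function(observed, null) {
  stopifnot(length(observed) == 1L, is.numeric(null), length(null) >= 1L)
  (1 + sum(null >= observed)) / (length(null) + 1)
}

# deterministic per-stratum seed fork: independent of stratum evaluation order
fork_seed <- function(seed, key) {
  base <- as.integer(seed) %% 1000003L
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 65521L
  (base * 1021L + h * 7L + 1L) %% 2147483647L
}
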