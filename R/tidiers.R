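# broom-style tidiers for the package's result objects.

#' Tidy a Forbes result
#'
#' For a single-partition result, one row of totals; for a
#' partition-conditioned result, one row per partition cell with its
#' counts, expectation and per-cell coefficient.
#'
#' @param x A `"forbes_result"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.forbes_result <- function(x, ...) {
  if (is.null(x$partitions)) {
    return(tibble(
      partition = "all", n = x$n, g = x$g, s = x$s, b = x$b,
      expected = x$expected, coefficient = x$coefficient
    ))
  }
  dplyr::select(
    x$partitions, "partition", "n", "g", "s", "b", "expected", "coefficient"
  )
}

#' One-row summary of a Forbes result
#'
#' @param x A `"forbes_result"`.
#' @param ... Unused.
#' @return One-row tibble: `m`, `n`, `g`, `s`, `b`, `expected`,
#'   `coefficient`, `explained_fraction`.
#' @export
glance.forbes_result <- function(x, ...) {
  tibble(
    m = x$m, n = x$n, g = x$g, s = x$s, b = x$b,
    expected = x$expected, coefficient = x$coefficient,
    explained_fraction = x$explained_fraction
  )
}

#' Tidy a leakage estimate (per-depth table)
#'
#' @param x A `"leakage_estimate"`.
#' @param ... Unused.
#' @return The per-depth tibble: `depth`, `s_d`, `b_d`, `rate`, `expected`,
#'   `excess`.
#' @export
tidy.leakage_estimate <- function(x, ...) {
  x$per_depth
}

#' One-row summary of a leakage estimate
#'
#' @param x A `"leakage_estimate"`.
#' @param ... Unused.
#' @return One-row tibble with the baseline rate, total excess and
#'   per-exome estimates.
#' @export
glance.leakage_estimate <- function(x, ...) {
  tibble(
    baseline_rate = x$baseline_rate,
    baseline_depth = x$baseline_depth,
    excess_max_depth = x$excess_max_depth,
    total_excess = x$total_excess,
    n_exomes = x$n_exomes,
    per_exome = x$per_exome,
    per_exome_corrected = x$per_exome_corrected
  )
}
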