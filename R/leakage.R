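# Estimation of germline leakage into the somatic call set from
# matched-normal read depth, and the GC/CpG confounder diagnostics.

#' Shared-variant rate by matched-normal read depth
#'
#' Per depth (or depth bin): the number of somatic sample-level calls and
#' the fraction of them that are shared with the germline set. Sample-level
#' records are used because leakage is a per-sample phenomenon.
#'
#' @param somatic Sample-level somatic calls with `n_depth`.
#' @param germline Germline calls.
#' @param binwidth Depth bin width (default 1 = per-depth resolution).
#' @return Tibble: `depth` (bin lower edge), `s_d` (somatic calls), `b_d`
#'   (shared calls), `rate` (= b_d/s_d).
#' @export
shared_rate_by_depth <- function(somatic, germline, binwidth = 1) {
  gl <- distinct_site_alleles(germline)
  key <- c("chrom", "pos", "ref", "alt")
  so <- dplyr::mutate(
    somatic,
    .shared = vctrs_in(somatic, gl, key),
    .depth = (.data$n_depth %/% binwidth) * binwidth
  )
  out <- dplyr::summarise(
    dplyr::group_by(so, depth = .data$.depth),
    s_d = dplyr::n(),
    b_d = sum(.data$.shared),
    .groups = "drop"
  )
  out$rate <- out$b_d / out$s_d
  dplyr::arrange(out, .data$depth)
}

# membership of calls (rows) in a site-allele set, as a logical vector
#' @noRd
vctrs_in <- function(calls, set, key) {
  idx <- dplyr::left_join(
    dplyr::select(calls, dplyr::all_of(key)),
    dplyr::mutate(set, .hit = TRUE),
    by = key
  )
  !is.na(idx$.hit)
}

#' Estimate germline leakage from the depth profile of shared rates
#'
#' The baseline shared-variant rate is taken from somatic calls with
#' matched-normal depth >= `baseline_depth` (default 200), where the power
#' to subtract germline variants is essentially complete. For every depth
#' below `excess_max_depth` (default 98) the excess of observed over
#' baseline-expected shared calls is accumulated; depths in
#' `[excess_max_depth, baseline_depth)` contribute nothing. The total
#' excess divided by the number of exomes gives the per-exome leakage
#' estimate.
#'
#' Because a leaked call inflates both the shared count and the somatic
#' denominator at its depth, the raw excess recovers only
#' `(1 - baseline_rate)` of the true leaked count; `per_exome_corrected`
#' divides this attenuation out and is the recommended point estimate.
#' Negative per-depth excesses are retained by default so the estimator is
#' centred at zero under no leakage; `floor_negative = TRUE` floors them.
#'
#' @param per_depth Per-depth table from [shared_rate_by_depth()] (bin
#'   width 1).
#' @param baseline_depth Depth from which the baseline rate is pooled.
#' @param excess_max_depth Depths strictly below this accumulate excess.
#' @param n_exomes Number of somatic exomes (samples).
#' @param floor_negative Floor negative per-depth excesses at 0.
#' @return Object of class `"leakage_estimate"`: `baseline_rate`,
#'   `per_depth` (with `expected` and `excess` columns), `total_excess`,
#'   `per_exome`, `per_exome_corrected`, `n_exomes`.
#' @export
estimate_leakage <- function(per_depth, baseline_depth = 200,
                             excess_max_depth = 98, n_exomes,
                             floor_negative = FALSE) {
  base <- dplyr::filter(per_depth, .data$depth >= baseline_depth)
  if (nrow(base) == 0 || sum(base$s_d) == 0) {
    abort(sprintf(
      "empty baseline stratum: no somatic calls at depth >= %g", baseline_depth
    ))
  }
  baseline_rate <- sum(base$b_d) / sum(base$s_d)
  tab <- per_depth
  tab$expected <- baseline_rate * tab$s_d
  tab$excess <- ifelse(
    tab$depth < excess_max_depth, tab$b_d - tab$expected, 0
  )
  excess_vals <- tab$excess
  if (floor_negative) excess_vals <- pmax(excess_vals, 0)
  total_excess <- sum(excess_vals)
  structure(
    list(
      baseline_rate = baseline_rate,
      per_depth = tab,
      total_excess = total_excess,
      per_exome = total_excess / n_exomes,
      per_exome_corrected = total_excess / ((1 - baseline_rate) * n_exomes),
      n_exomes = n_exomes,
      baseline_depth = baseline_depth,
      excess_max_depth = excess_max_depth
    ),
    class = "leakage_estimate"
  )
}

#' @export
print.leakage_estimate <- function(x, ...) {
  cat(sprintf(
    "<leakage_estimate>\n  baseline shared rate (depth >= %g): %.4f\n  total excess below depth %g: %.1f over %d exomes\n  per exome: %.3f raw, %.3f attenuation-corrected\n",
    x$baseline_depth, x$baseline_rate, x$excess_max_depth,
    x$total_excess, x$n_exomes, x$per_exome, x$per_exome_corrected
  ))
  invisible(x)
}

#' CpG composition and context-standardized shared rate by depth
#'
#' Diagnoses the GC/CpG confounder of the leakage analysis: per depth bin,
#' the fraction of somatic calls in an NCG (CpG-deamination-prone) context
#' and the shared rate *predicted* from context composition alone, i.e.
#' `sum_c (fraction of bin in context c) * (global shared rate of c)`. A
#' rising observed rate at low depth alongside a flat predicted rate points
#' to leakage; a rising predicted rate points to context composition.
#'
#' @param somatic Sample-level somatic calls with `n_depth`.
#' @param germline Germline calls (for the shared flags).
#' @param universe Annotated universe (for context labels).
#' @param level Context column used for standardization (default
#'   `"trimer"`).
#' @param binwidth Depth bin width (default 10).
#' @return Tibble: `depth`, `n_calls`, `cpg_fraction`, `observed_rate`,
#'   `predicted_rate`.
#' @export
context_confound_by_depth <- function(somatic, germline, universe,
                                      level = "trimer", binwidth = 10) {
  key <- c("chrom", "pos", "ref", "alt")
  lab <- dplyr::select(
    universe, dplyr::all_of(c(key, level, "basic_class"))
  )
  so <- dplyr::inner_join(somatic, lab, by = key, suffix = c("", ".u"))
  ctx <- if (paste0(level, ".u") %in% names(so)) paste0(level, ".u") else level
  cls <- if ("basic_class.u" %in% names(so)) "basic_class.u" else "basic_class"
  gl <- distinct_site_alleles(germline)
  so$.shared <- vctrs_in(so, gl, key)
  # global per-context shared rate among somatic calls
  glob <- dplyr::summarise(
    dplyr::group_by(so, context = .data[[ctx]]),
    global_rate = mean(.data$.shared), .groups = "drop"
  )
  so$.depth <- (so$n_depth %/% binwidth) * binwidth
  so <- dplyr::left_join(
    dplyr::mutate(so, context = .data[[ctx]]), glob,
    by = "context"
  )
  out <- dplyr::summarise(
    dplyr::group_by(so, depth = .data$.depth),
    n_calls = dplyr::n(),
    cpg_fraction = mean(.data[[cls]] == "deamination"),
    observed_rate = mean(.data$.shared),
    predicted_rate = mean(.data$global_rate),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$depth)
}

#' Mean matched-normal depth by GC window content
#'
#' @param somatic Sample-level somatic calls with `n_depth`.
#' @param universe Universe with `gc_win` (GC content of the surrounding
#'   window) -- used to annotate the calls.
#' @param bins Number of GC bins (default 10).
#' @return Tibble: `gc_bin` (midpoint), `n_calls`, `mean_depth`.
#' @export
depth_by_gc <- function(somatic, universe, bins = 10) {
  key <- c("chrom", "pos", "ref", "alt")
  so <- dplyr::inner_join(
    somatic,
    dplyr::select(universe, dplyr::all_of(key), "gc_win"),
    by = key
  )
  brk <- seq(min(so$gc_win), max(so$gc_win), length.out = bins + 1)
  if (length(unique(brk)) == 1) {
    return(tibble(
      gc_bin = brk[1], n_calls = nrow(so), mean_depth = mean(so$n_depth)
    ))
  }
  cut_idx <- pmin(findInterval(so$gc_win, brk, all.inside = TRUE), bins)
  mid <- (brk[-length(brk)] + brk[-1]) / 2
  out <- dplyr::summarise(
    dplyr::group_by(tibble(
      gc_bin = mid[cut_idx], depth = so$n_depth
    ), .data$gc_bin),
    n_calls = dplyr::n(),
    mean_depth = mean(.data$depth),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$gc_bin)
}
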