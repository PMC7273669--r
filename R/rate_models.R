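# Per-context mutation-rate estimation in the germline and somatic
# settings, and the cross-setting correlation analyses (including the
# "controlling for the central bases" stratified variants).

#' Per-context mutation rates in both settings
#'
#' For every substitution context at the chosen level, the germline and
#' somatic rate is the number of unique mutated site-alleles in the context
#' divided by the context's size in the universe. Contexts absent from the
#' universe are excluded.
#'
#' @param germline,somatic Call tibbles restricted to the universe.
#' @param universe Annotated universe with the requested level column.
#' @param level Universe context column: `"trimer"`, `"pentamer"` or
#'   `"heptamer"` (any annotation column works).
#' @return Tibble: `context`, `basic_class`, `central` (the contained
#'   context one flank smaller; the basic-class label for trimers), `n`,
#'   `g`, `s`, `germline_rate`, `somatic_rate`.
#' @export
context_rates <- function(germline, somatic, universe, level = "trimer") {
  if (!level %in% names(universe)) {
    abort(sprintf("universe has no context column '%s'", level))
  }
  key <- c("chrom", "pos", "ref", "alt")
  nn <- dplyr::count(universe,
    context = .data[[level]], basic_class = .data$basic_class,
    name = "n"
  )
  gl <- dplyr::inner_join(distinct_site_alleles(germline), universe, by = key)
  so <- dplyr::inner_join(distinct_site_alleles(somatic), universe, by = key)
  gg <- dplyr::count(gl, context = .data[[level]], name = "g")
  ss <- dplyr::count(so, context = .data[[level]], name = "s")
  out <- dplyr::left_join(nn, gg, by = "context")
  out <- dplyr::left_join(out, ss, by = "context")
  out <- dplyr::mutate(out, dplyr::across(c("g", "s"), ~ dplyr::coalesce(.x, 0L)))
  out$germline_rate <- out$g / out$n
  out$somatic_rate <- out$s / out$n
  flank <- (nchar(out$context[1]) - 5L) %/% 2L
  out$central <- if (flank >= 2) {
    context_central(out$context, flank - 1L)
  } else {
    as.character(out$basic_class)
  }
  dplyr::select(
    out, "context", "basic_class", "central", "n", "g", "s",
    "germline_rate", "somatic_rate"
  )
}

#' Rate ratio between two basic substitution classes
#'
#' Pooled rate (mutated / eligible summed over the class's contexts) of
#' `class_a` divided by that of `class_b`, in one setting. With the default
#' classes this is the transition/transversion or deamination/transversion
#' rate ratio.
#'
#' @param rates A [context_rates()] table.
#' @param class_a,class_b Basic class labels (`"deamination"`,
#'   `"other_transition"`, `"transversion"`).
#' @param setting `"germline"` or `"somatic"`.
#' @return The pooled rate ratio (double).
#' @export
rate_ratio <- function(rates, class_a, class_b,
                       setting = c("germline", "somatic")) {
  setting <- match.arg(setting)
  count_col <- if (setting == "germline") "g" else "s"
  pooled <- function(cl) {
    sub <- dplyr::filter(rates, .data$basic_class == cl)
    if (nrow(sub) == 0) abort(sprintf("class '%s' has no contexts", cl))
    sum(sub[[count_col]]) / sum(sub$n)
  }
  rb <- pooled(class_b)
  if (rb == 0) abort(sprintf("class '%s' has zero pooled rate", class_b))
  pooled(class_a) / rb
}

#' Cross-setting correlation of context mutation rates
#'
#' Rank (Spearman) correlation between the germline and somatic rates
#' across contexts, optionally excluding NCG contexts (those whose
#' pyrimidine-strand reference C is followed by G -- the CpG-deamination
#' contexts).
#'
#' @param rates A [context_rates()] table (>= 3 contexts).
#' @param method Correlation method (default `"spearman"`).
#' @param exclude_ncg Drop contexts whose canonical key has ref C and 3' G.
#' @return Tibble: `rho`, `p_value`, `n_contexts`.
#' @export
cross_setting_correlation <- function(rates, method = "spearman",
                                      exclude_ncg = FALSE) {
  tab <- rates
  if (exclude_ncg) {
    p <- parse_context(tab$context)
    ncg <- p$ref == "C" & substr(p$downstream, 1, 1) == "G"
    tab <- tab[!ncg, , drop = FALSE]
  }
  if (nrow(tab) < 3) abort("need at least 3 contexts for a correlation")
  ct <- suppressWarnings(cor.test(
    tab$germline_rate, tab$somatic_rate,
    method = method, exact = FALSE
  ))
  tibble(
    rho = unname(ct$estimate), p_value = ct$p.value, n_contexts = nrow(tab)
  )
}

#' Cross-setting rate correlation controlling for the central context
#'
#' Measures whether flanking bases beyond a central sub-context carry
#' correlated rate information between the settings. Within each stratum
#' (all contexts sharing a central sub-context), ranks of the germline and
#' somatic rates are computed separately; the default `"pooled"` mode
#' centres and scales the within-stratum ranks and correlates them pooled
#' across strata, while `"average"` computes Spearman's rho per stratum and
#' averages it weighted by stratum size. Strata with fewer than 2 contexts
#' are dropped. The statistic is invariant to any monotone transform
#' applied per-stratum to both settings' rates.
#'
#' @param rates A [context_rates()] table.
#' @param stratum Column defining the strata (default `"central"`).
#' @param mode `"pooled"` (default) or `"average"`.
#' @return Tibble: `rho`, `n_contexts`, `n_strata`.
#' @export
stratified_correlation <- function(rates, stratum = "central",
                                   mode = c("pooled", "average")) {
  mode <- match.arg(mode)
  if (!stratum %in% names(rates)) {
    abort(sprintf("rates table has no stratum column '%s'", stratum))
  }
  tab <- dplyr::add_count(rates, .data[[stratum]], name = ".stratum_size")
  tab <- dplyr::filter(tab, .data$.stratum_size >= 2)
  if (nrow(tab) == 0) abort("all strata are degenerate (size < 2)")
  grp <- dplyr::group_by(tab, .data[[stratum]])
  if (mode == "pooled") {
    scaled <- dplyr::mutate(
      grp,
      rg = scale_ranks(rank(.data$germline_rate)),
      rs = scale_ranks(rank(.data$somatic_rate))
    )
    scaled <- dplyr::ungroup(scaled)
    # all-tied ranks carry no residual signal: rho is 0 by definition
    rho <- if (stats::sd(scaled$rg) == 0 || stats::sd(scaled$rs) == 0) {
      0
    } else {
      cor(scaled$rg, scaled$rs)
    }
    tibble(
      rho = rho, n_contexts = nrow(scaled),
      n_strata = dplyr::n_distinct(scaled[[stratum]])
    )
  } else {
    per <- dplyr::summarise(
      grp,
      rho = suppressWarnings(cor(
        .data$germline_rate, .data$somatic_rate,
        method = "spearman"
      )),
      size = dplyr::n(),
      .groups = "drop"
    )
    per <- dplyr::filter(per, !is.na(.data$rho))
    tibble(
      rho = sum(per$rho * per$size) / sum(per$size),
      n_contexts = sum(per$size), n_strata = nrow(per)
    )
  }
}

# Centre and scale within-stratum ranks to mean 0, unit variance (ties get
# average ranks via rank()); degenerate strata (all tied) map to 0.
#' @noRd
scale_ranks <- function(r) {
  s <- stats::sd(r)
  if (is.na(s) || s == 0) {
    return(rep(0, length(r)))
  }
  (r - mean(r)) / s
}

#' Per-context rate pairs for plotting/reporting
#'
#' Emits the per-context germline/somatic rate pairs annotated with the
#' context's GC content and alternate allele, flagging CpG>T contexts for
#' omission from rate scatter plots (their rates dwarf everything else).
#'
#' @param rates A [context_rates()] table.
#' @return The table plus `gc_content`, `alt_allele` and `omit_from_plot`.
#' @export
rate_scatter_report <- function(rates) {
  p <- parse_context(rates$context)
  kmer <- paste0(p$upstream, p$ref, p$downstream)
  gc <- vapply(
    strsplit(kmer, "", fixed = TRUE),
    function(ch) mean(ch %in% c("G", "C")), numeric(1)
  )
  out <- rates
  out$gc_content <- gc
  out$alt_allele <- p$alt
  out$omit_from_plot <- p$ref == "C" & p$alt == "T" &
    substr(p$downstream, 1, 1) == "G"
  out
}
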