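# Subset characterizations: trinucleotide-matched downsampling, allele-age
# and ancestry analyses, continent counts, and VAF comparisons.

#' Trinucleotide-matched downsampling of variant categories
#'
#' For each trinucleotide context, every category is randomly downsampled
#' to the minimum count of that context across categories, so that after
#' matching all categories have exactly identical trinucleotide context
#' distributions. Deterministic under `seed`; invariant to the order of the
#' input categories. Contexts absent from all categories are skipped.
#'
#' @param categories Named list of variant tibbles, each with a `trimer`
#'   column (join against the annotated universe to obtain it).
#' @param seed Integer seed for the downsampling draws.
#' @return Named list of downsampled tibbles (same names, original columns).
#' @export
trinucleotide_matched_downsample <- function(categories, seed = 1) {
  if (length(categories) < 1) abort("need at least one category")
  if (is.null(names(categories)) || any(names(categories) == "")) {
    abort("categories must be named")
  }
  for (nm in names(categories)) {
    if (!"trimer" %in% names(categories[[nm]])) {
      abort(sprintf("category '%s' lacks a 'trimer' column", nm))
    }
  }
  if (length(categories) == 1) {
    return(categories)
  }
  # leave the caller's RNG stream untouched
  old_rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })
  counts <- purrr::map(categories, ~ dplyr::count(.x, .data$trimer))
  all_trimers <- sort(unique(unlist(purrr::map(counts, "trimer"))))
  count_mat <- vapply(counts, function(ct) {
    v <- setNames(rep(0L, length(all_trimers)), all_trimers)
    v[ct$trimer] <- ct$n
    v
  }, integer(length(all_trimers)))
  target <- apply(count_mat, 1, min)

  # stable ordering + category-specific substream keeps the draw
  # independent of input order
  out <- purrr::imap(categories, function(df, nm) {
    df <- dplyr::arrange(df, .data$trimer)
    keep <- unlist(purrr::map(all_trimers, function(tr) {
      idx <- which(df$trimer == tr)
      k <- target[[tr]]
      if (length(idx) <= k) {
        return(idx)
      }
      local_seed <- substream_seed(
        seed, 17L + sum(utf8ToInt(paste0(nm, tr)))
      )
      set.seed(local_seed)
      sort(sample(idx, k))
    }))
    df[sort(keep), , drop = FALSE]
  })
  out
}

#' Forbes coefficients for context-matched categories
#'
#' Downsamples the categories to identical trinucleotide distributions,
#' then computes a Forbes coefficient per category against the full
#' germline set over the full universe. With no selection (or other
#' category-specific) mechanism, matched categories are expected to have
#' equal coefficients up to sampling error.
#'
#' @param categories Named list of somatic variant tibbles with `trimer`.
#' @param germline Germline calls.
#' @param universe Annotated universe.
#' @param seed Seed passed to the matcher.
#' @return Tibble: `category`, `s`, `b`, `expected`, `coefficient`.
#' @export
matched_forbes_comparison <- function(categories, germline, universe,
                                      seed = 1) {
  matched <- trinucleotide_matched_downsample(categories, seed = seed)
  n <- nrow(universe)
  gl <- distinct_site_alleles(germline)
  g <- nrow(gl)
  key <- c("chrom", "pos", "ref", "alt")
  purrr::imap_dfr(matched, function(df, nm) {
    dd <- dplyr::distinct(df, dplyr::pick(dplyr::all_of(key)))
    if (nrow(dd) == 0) {
      abort(sprintf("category '%s' is empty after matching", nm))
    }
    b <- nrow(dplyr::semi_join(dd, gl, by = key))
    e <- expected_independence(g, nrow(dd), n)
    tibble(
      category = nm, s = nrow(dd), b = b, expected = e, coefficient = b / e
    )
  })
}

#' Somatically-shared rate of germline variants by allele age
#'
#' Bins germline variants by allele age (log-spaced generation bins by
#' default) and reports the fraction of each bin that is somatically
#' shared, plus a two-sample proportion test comparing variants younger
#' than `threshold` generations against older ones.
#'
#' @param germline Germline calls with an `age` column (generations; de
#'   novo variants have age <= 1).
#' @param somatic Somatic calls.
#' @param breaks Age bin breaks in generations (default log-spaced from 1
#'   to the maximum age).
#' @param threshold Age split for the two-group comparison (default 500
#'   generations).
#' @return List: `by_bin` tibble (`age_bin`, `n`, `shared`, `rate`) and
#'   `comparison` tibble (`rate_young`, `rate_old`, `p_value`, counts); the
#'   comparison is `NULL` (with a warning) when either group is empty.
#' @export
shared_rate_by_allele_age <- function(germline, somatic, breaks = NULL,
                                      threshold = 500) {
  if (!"age" %in% names(germline)) abort("germline calls lack an 'age' column")
  key <- c("chrom", "pos", "ref", "alt")
  so <- distinct_site_alleles(somatic)
  g <- dplyr::mutate(germline, .shared = vctrs_in(germline, so, key))
  if (is.null(breaks)) {
    top <- max(g$age, na.rm = TRUE)
    breaks <- unique(c(0, 2^seq(0, ceiling(log2(max(top, 2))) + 1)))
  }
  g$.bin <- cut(g$age, breaks = breaks, include.lowest = TRUE)
  by_bin <- dplyr::summarise(
    dplyr::group_by(g, age_bin = .data$.bin),
    n = dplyr::n(), shared = sum(.data$.shared),
    rate = mean(.data$.shared), .groups = "drop"
  )
  young <- g$age < threshold
  comparison <- NULL
  if (any(young) && any(!young)) {
    x <- c(sum(g$.shared[young]), sum(g$.shared[!young]))
    nn <- c(sum(young), sum(!young))
    pt <- suppressWarnings(prop.test(x, nn))
    comparison <- tibble(
      threshold = threshold,
      n_young = nn[1], n_old = nn[2],
      rate_young = x[1] / nn[1], rate_old = x[2] / nn[2],
      p_value = pt$p.value
    )
  } else {
    warn("one age group is empty; the young/old comparison was skipped")
  }
  list(by_bin = by_bin, comparison = comparison)
}

#' Somatically-shared rate by continent count and allele-count stratum
#'
#' Stratifies germline variants by total allele count and by the number of
#' continents on which they are observed, reporting the somatically-shared
#' rate per cell. Among ultra-rare variants a rate rising with continent
#' count indicates recurrent (mutation-prone) sites.
#'
#' @param germline Germline calls with per-continent `ac_*` columns.
#' @param somatic Somatic calls.
#' @param ac_breaks Allele-count strata breaks (default strata: 1-5
#'   "ultra-rare", 6-49, >= 50).
#' @return Tibble: `ac_stratum`, `n_continents`, `n`, `shared`, `rate`
#'   (empty cells are absent, i.e. reported as missing).
#' @export
shared_rate_by_continent_count <- function(germline, somatic,
                                           ac_breaks = c(0, 5, 49, Inf)) {
  cont_cols <- grep("^ac_", names(germline), value = TRUE)
  if (length(cont_cols) == 0) {
    abort("germline calls lack per-continent ac_* columns")
  }
  key <- c("chrom", "pos", "ref", "alt")
  so <- distinct_site_alleles(somatic)
  g <- germline
  g$.n_cont <- rowSums(as.matrix(g[cont_cols]) > 0)
  if (!"ac" %in% names(g)) {
    g$ac <- rowSums(as.matrix(g[cont_cols]))
  }
  g$.shared <- vctrs_in(g, so, key)
  g$.stratum <- cut(g$ac, breaks = ac_breaks, include.lowest = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(
      g,
      ac_stratum = .data$.stratum, n_continents = .data$.n_cont
    ),
    n = dplyr::n(), shared = sum(.data$.shared), rate = mean(.data$.shared),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$ac_stratum, .data$n_continents)
}

#' Shared-rate matrix across germline and somatic ancestries
#'
#' Restricts the germline side to variants exclusive to one continental
#' ancestry (observed on exactly one continent) and the somatic side to
#' calls from donors of one ancestry, and reports the shared rate for every
#' (germline ancestry, somatic ancestry) pair: the fraction of that
#' germline subset shared with that somatic subset.
#'
#' @param germline Germline calls with per-continent `ac_*` columns.
#' @param somatic Somatic calls with an `ancestry` column.
#' @return Tibble: `germline_ancestry`, `somatic_ancestry`, `n_germline`,
#'   `shared`, `rate`.
#' @export
ancestry_cross_table <- function(germline, somatic) {
  cont_cols <- grep("^ac_", names(germline), value = TRUE)
  if (length(cont_cols) == 0) {
    abort("germline calls lack per-continent ac_* columns")
  }
  if (!"ancestry" %in% names(somatic)) {
    abort("somatic calls lack an 'ancestry' column")
  }
  key <- c("chrom", "pos", "ref", "alt")
  mat <- as.matrix(germline[cont_cols]) > 0
  exclusive <- rowSums(mat) == 1
  g <- germline[exclusive, , drop = FALSE]
  anc_of <- toupper(sub("^ac_", "", cont_cols))
  g$.ancestry <- anc_of[max.col(mat[exclusive, , drop = FALSE])]
  purrr::map_dfr(sort(unique(somatic$ancestry)), function(sa) {
    so <- distinct_site_alleles(
      dplyr::filter(somatic, .data$ancestry == sa)
    )
    hits <- vctrs_in(g, so, key)
    out <- dplyr::summarise(
      dplyr::group_by(
        tibble(germline_ancestry = g$.ancestry, hit = hits),
        .data$germline_ancestry
      ),
      n_germline = dplyr::n(), shared = sum(.data$hit),
      rate = mean(.data$hit), .groups = "drop"
    )
    out$somatic_ancestry <- sa
    out
  })
}

#' VAF comparison of shared vs database-unique somatic calls
#'
#' Splits sample-level somatic calls by whether their (site, alt) is shared
#' with the germline set, and summarises the variant-allele-frequency
#' distribution per group plus a rank-based location comparison.
#'
#' @param somatic Sample-level somatic calls with `vaf`.
#' @param germline Germline calls.
#' @return List: `summary` tibble (per group: n, quantiles, mean) and
#'   `test` tibble (Wilcoxon rank-sum p-value and median difference), the
#'   latter `NULL` if a group is empty.
#' @export
vaf_comparison <- function(somatic, germline) {
  key <- c("chrom", "pos", "ref", "alt")
  gl <- distinct_site_alleles(germline)
  so <- dplyr::mutate(
    somatic,
    group = ifelse(vctrs_in(somatic, gl, key), "shared", "unique")
  )
  summ <- dplyr::summarise(
    dplyr::group_by(so, .data$group),
    n = dplyr::n(),
    q25 = quantile(.data$vaf, 0.25),
    median = median(.data$vaf),
    q75 = quantile(.data$vaf, 0.75),
    mean = mean(.data$vaf),
    .groups = "drop"
  )
  test <- NULL
  if (dplyr::n_distinct(so$group) == 2) {
    wt <- wilcox.test(vaf ~ group, data = so)
    med <- dplyr::summarise(
      dplyr::group_by(so, .data$group),
      m = median(.data$vaf), .groups = "drop"
    )
    test <- tibble(
      p_value = wt$p.value,
      median_shared = med$m[med$group == "shared"],
      median_unique = med$m[med$group == "unique"]
    )
  }
  list(summary = summ, test = test)
}
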