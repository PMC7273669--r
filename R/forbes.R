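# Forbes coefficient of co-occurrence and its partition-conditioned
# generalization. Counts live in a PartitionTable tibble with one row per
# partition cell: n (eligible potential SNVs), g (unique germline-mutated),
# s (unique somatic-mutated), b (shared).

#' Expected shared variants under statistical independence
#'
#' If germline and somatic mutation were statistically independent over a
#' universe of `n` potential SNVs of which `g` are germline-mutated and `s`
#' somatic-mutated, the expected number of shared variants is
#' `e = (g/n) * (s/n) * n = g*s/n`. Kept real-valued; rounding happens only
#' at the reporting layer.
#'
#' @param g,s Unique mutated site-allele counts in each setting.
#' @param n Universe size (potential SNVs).
#' @return Expected shared count (double).
#' @export
#' @examples
#' expected_independence(5225731, 1629311, 73517652) # ~115814
expected_independence <- function(g, s, n) {
  if (any(n <= 0)) abort("n must be > 0")
  if (any(g < 0 | s < 0 | g > n | s > n)) {
    abort("need 0 <= g, s <= n")
  }
  g * s / n
}

#' Forbes coefficient of association
#'
#' `F = b / e|independence = b * n / (g * s)`: the factor by which the
#' observed shared-variant count exceeds the independence expectation.
#'
#' @param b Observed shared count (b <= min(g, s)).
#' @param g,s,n As in [expected_independence()].
#' @return Object of class `"forbes_result"`: fields `expected`,
#'   `coefficient`, `explained_fraction` (= expected/b), `m` (= 1), and the
#'   input totals.
#' @export
#' @examples
#' forbes(336987, 5225731, 1629311, 73517652)
forbes <- function(b, g, s, n) {
  e <- expected_independence(g, s, n)
  if (g * s == 0) {
    abort("Forbes coefficient undefined: g * s = 0 gives zero expectation")
  }
  if (b > min(g, s)) abort("b cannot exceed min(g, s)")
  new_forbes_result(
    expected = e, b = b, g = g, s = s, n = n, m = 1L,
    partitions = NULL
  )
}

#' @noRd
new_forbes_result <- function(expected, b, g, s, n, m, partitions = NULL) {
  structure(
    list(
      expected = expected,
      coefficient = b / expected,
      explained_fraction = expected / b,
      b = b, g = g, s = s, n = n, m = as.integer(m),
      partitions = partitions
    ),
    class = "forbes_result"
  )
}

#' @export
print.forbes_result <- function(x, ...) {
  cat(sprintf(
    "<forbes_result>  m = %d partition(s)\n  b = %s observed shared; expected = %.1f\n  coefficient = %.3f; explained fraction = %.1f%%\n",
    x$m, format(x$b, big.mark = ","), x$expected,
    x$coefficient, 100 * x$explained_fraction
  ))
  invisible(x)
}

#' Build a partition table of universe/germline/somatic/shared counts
#'
#' @param universe Annotated universe tibble (see [annotate_universe()]).
#' @param germline,somatic Call tibbles; deduplicated internally to unique
#'   site-alleles. Calls must already be restricted to the universe (see
#'   [apply_variant_filters()]); calls outside it raise an error.
#' @param by Name of the universe column defining the partition (e.g.
#'   `"basic_class"`, `"trimer"`), or `NULL` for a single-cell table.
#' @return Tibble with columns `partition`, `n`, `g`, `s`, `b`.
#' @export
partition_table <- function(universe, germline, somatic, by = NULL) {
  gl <- distinct_site_alleles(germline)
  so <- distinct_site_alleles(somatic)
  key <- c("chrom", "pos", "ref", "alt")
  shared <- dplyr::semi_join(gl, so, by = key)

  if (is.null(by)) {
    ng_out <- nrow(dplyr::anti_join(gl, universe, by = key))
    ns_out <- nrow(dplyr::anti_join(so, universe, by = key))
    if (ng_out + ns_out > 0) {
      abort(sprintf(
        "%d germline and %d somatic site-alleles lie outside the universe; apply filters first",
        ng_out, ns_out
      ))
    }
    return(tibble(
      partition = "all", n = nrow(universe), g = nrow(gl), s = nrow(so),
      b = nrow(shared)
    ))
  }
  if (!by %in% names(universe)) {
    abort(sprintf("universe has no column '%s' to partition by", by))
  }
  lab <- dplyr::select(
    universe, dplyr::all_of(c(key, by))
  )
  join_labelled <- function(calls, what) {
    j <- dplyr::inner_join(calls, lab, by = key)
    if (nrow(j) < nrow(calls)) {
      abort(sprintf(
        "%d %s site-alleles lie outside the universe; apply filters first",
        nrow(calls) - nrow(j), what
      ))
    }
    j
  }
  gl <- join_labelled(gl, "germline")
  so <- join_labelled(so, "somatic")
  shared <- join_labelled(shared, "shared")

  nn <- dplyr::count(universe, partition = .data[[by]], name = "n")
  gg <- dplyr::count(gl, partition = .data[[by]], name = "g")
  ss <- dplyr::count(so, partition = .data[[by]], name = "s")
  bb <- dplyr::count(shared, partition = .data[[by]], name = "b")
  out <- Reduce(
    function(a, b) dplyr::left_join(a, b, by = "partition"),
    list(nn, gg, ss, bb)
  )
  out$partition <- as.character(out$partition)
  out <- dplyr::mutate(out, dplyr::across(
    c("g", "s", "b"),
    ~ dplyr::coalesce(.x, 0L)
  ))
  out
}

#' Partition-conditioned Forbes coefficient
#'
#' Generalizes the Forbes coefficient by conditioning on a partition of the
#' universe: `P(v) = b / sum_i e_i` with `e_i = (g_i/n_i) * (s_i/n_i) * n_i`,
#' letting every partition cell carry its own germline and somatic rates.
#' Cells with `n_i = 0` contribute nothing.
#'
#' @param table Partition table from [partition_table()] (columns
#'   `partition`, `n`, `g`, `s`, `b`).
#' @return `"forbes_result"` with `m` = number of cells and the per-cell
#'   table (including per-cell expectations and coefficients) in
#'   `$partitions`.
#' @export
partition_forbes <- function(table) {
  req <- c("n", "g", "s", "b")
  if (!all(req %in% names(table))) {
    abort("partition table needs columns n, g, s, b")
  }
  if (all(table$n == 0)) abort("all partitions are empty")
  tab <- dplyr::filter(table, .data$n > 0)
  bad <- tab$b > pmin(tab$g, tab$s) | tab$g > tab$n | tab$s > tab$n
  if (any(bad)) abort("invalid partition counts: need b_i <= min(g_i, s_i) <= n_i")
  tab$expected <- tab$g * tab$s / tab$n
  tab$coefficient <- ifelse(tab$expected > 0, tab$b / tab$expected, NA_real_)
  new_forbes_result(
    expected = sum(tab$expected),
    b = sum(tab$b), g = sum(tab$g), s = sum(tab$s), n = sum(tab$n),
    m = nrow(tab), partitions = tab
  )
}

#' Count shared variants
#'
#' A shared variant is a (chrom, pos, ref, alt) present in both call sets.
#' Counting is at the unique site-allele level.
#'
#' @param germline,somatic Call tibbles.
#' @param universe Optional universe; calls outside it raise an error, and
#'   per-partition shared counts are returned for any annotation columns
#'   requested via `by`.
#' @param by Optional universe column for per-partition counts.
#' @return If `by` is `NULL`, a single count. Otherwise a tibble
#'   `partition`, `b`.
#' @export
count_shared <- function(germline, somatic, universe = NULL, by = NULL) {
  key <- c("chrom", "pos", "ref", "alt")
  gl <- distinct_site_alleles(germline)
  so <- distinct_site_alleles(somatic)
  shared <- dplyr::semi_join(gl, so, by = key)
  if (is.null(universe)) {
    if (!is.null(by)) abort("`by` requires a universe with annotation columns")
    return(nrow(shared))
  }
  out_g <- nrow(dplyr::anti_join(gl, universe, by = key))
  out_s <- nrow(dplyr::anti_join(so, universe, by = key))
  if (out_g + out_s > 0) {
    abort(sprintf(
      "%d germline and %d somatic site-alleles lie outside the universe; apply filters first",
      out_g, out_s
    ))
  }
  if (is.null(by)) {
    return(nrow(shared))
  }
  lab <- dplyr::inner_join(shared, universe, by = key)
  dplyr::count(lab, partition = .data[[by]], name = "b")
}

#' Decomposition of shared variants over nested partitions
#'
#' Applies [partition_forbes()] to a sequence of partitions from coarse to
#' fine and reports, per level, the expected shared count, the conditioned
#' coefficient, the explained fraction `expected/b`, and the incremental
#' explanatory value over the previous level.
#'
#' @param tables Named list of partition tables, ordered coarse to fine
#'   (all sharing the same totals `n` and `b`).
#' @param b Total observed shared count (defaults to the first table's).
#' @return Tibble: `level`, `m`, `expected`, `coefficient`,
#'   `explained_fraction`, `incremental`.
#' @export
explained_decomposition <- function(tables, b = NULL) {
  if (length(tables) == 0) abort("need at least one partition table")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("level_", seq_along(tables))
  }
  if (is.null(b)) b <- sum(tables[[1]]$b)
  if (b == 0) abort("no shared variants: decomposition undefined (b = 0)")
  ns <- vapply(tables, function(t) sum(t$n), numeric(1))
  bs <- vapply(tables, function(t) sum(t$b), numeric(1))
  if (length(unique(ns)) != 1 || any(bs != b)) {
    abort("all partition tables must share the same totals n and b")
  }
  res <- purrr::map(tables, partition_forbes)
  out <- tibble(
    level = names(tables),
    m = vapply(res, function(r) r$m, integer(1), USE.NAMES = FALSE),
    expected = vapply(res, function(r) r$expected, numeric(1), USE.NAMES = FALSE),
    coefficient = vapply(
      res, function(r) r$coefficient, numeric(1),
      USE.NAMES = FALSE
    ),
    explained_fraction = vapply(
      res, function(r) r$explained_fraction, numeric(1),
      USE.NAMES = FALSE
    )
  )
  out$incremental <- out$explained_fraction -
    dplyr::lag(out$explained_fraction, default = 0)
  out
}

#' Forbes decomposition of a cohort over context levels
#'
#' High-level wrapper: builds the partition tables for the requested
#' context levels of an annotated universe and returns the Table-2-style
#' decomposition.
#'
#' @param universe Annotated universe.
#' @param germline,somatic Call tibbles (restricted to the universe).
#' @param levels Universe columns to partition by, coarse to fine;
#'   `"unpartitioned"` means the single-cell table.
#' @return See [explained_decomposition()].
#' @export
forbes_decomposition <- function(universe, germline, somatic,
                                 levels = c(
                                   "unpartitioned", "basic_class", "trimer"
                                 )) {
  tables <- purrr::map(levels, function(lv) {
    partition_table(
      universe, germline, somatic,
      by = if (identical(lv, "unpartitioned")) NULL else lv
    )
  })
  names(tables) <- levels
  explained_decomposition(tables)
}

#' Site-level bootstrap confidence interval for the Forbes coefficient
#'
#' Resamples universe sites (positions, carrying all three alts) with
#' replacement and recomputes the coefficient, giving a percentile
#' confidence interval. Off the default path: the point decomposition is
#' the package's primary output and the coefficient is a ratio of large
#' counts, so the interval is typically narrow.
#'
#' @param universe Annotated universe.
#' @param germline,somatic Call tibbles restricted to the universe.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the resampling.
#' @return Tibble: `coefficient`, `conf_low`, `conf_high`, `n_boot`.
#' @export
forbes_bootstrap <- function(universe, germline, somatic, n_boot = 200,
                             conf_level = 0.95, seed = 1) {
  key <- c("chrom", "pos", "ref", "alt")
  gl <- distinct_site_alleles(germline)
  so <- distinct_site_alleles(somatic)
  shared <- dplyr::semi_join(gl, so, by = key)
  sites <- dplyr::distinct(universe, .data$chrom, .data$pos)
  sites$site_id <- seq_len(nrow(sites))
  per_site <- function(calls) {
    cnt <- dplyr::count(
      dplyr::inner_join(calls, sites, by = c("chrom", "pos")),
      .data$site_id
    )
    v <- integer(nrow(sites))
    v[cnt$site_id] <- cnt$n
    v
  }
  gv <- per_site(gl)
  sv <- per_site(so)
  bv <- per_site(shared)
  point <- (sum(bv) * 3 * nrow(sites)) / (sum(gv) * sum(sv))
  boots <- with_substream(seed, stage = 11L, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(sites), replace = TRUE)
      (sum(bv[idx]) * 3 * nrow(sites)) / (sum(gv[idx]) * sum(sv[idx]))
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
  tibble(
    coefficient = point, conf_low = unname(ci[1]), conf_high = unname(ci[2]),
    n_boot = n_boot
  )
}

#' Per-sample Forbes coefficients
#'
#' For each somatic sample, the Forbes coefficient of its own unique
#' eligible variants against the full germline set. Samples with zero
#' eligible variants are excluded (reported via a message).
#'
#' @param somatic Sample-level somatic calls (column `sample`).
#' @param germline Germline calls.
#' @param universe Annotated universe.
#' @return Tibble: `sample`, `s`, `b`, `expected`, `coefficient`.
#' @export
per_sample_forbes <- function(somatic, germline, universe) {
  n <- nrow(universe)
  g <- nrow(distinct_site_alleles(germline))
  key <- c("chrom", "pos", "ref", "alt")
  gl <- distinct_site_alleles(germline)
  per <- dplyr::distinct(
    somatic, .data$sample, .data$chrom, .data$pos, .data$ref, .data$alt
  )
  shared <- dplyr::semi_join(per, gl, by = key)
  s_tab <- dplyr::count(per, .data$sample, name = "s")
  b_tab <- dplyr::count(shared, .data$sample, name = "b")
  out <- dplyr::left_join(s_tab, b_tab, by = "sample")
  out$b <- dplyr::coalesce(out$b, 0L)
  empty <- out$s == 0
  if (any(empty)) {
    inform(sprintf(
      "per_sample_forbes: excluded %d sample(s) with no eligible variants",
      sum(empty)
    ))
    out <- out[!empty, , drop = FALSE]
  }
  out$expected <- expected_independence(g, out$s, n)
  out$coefficient <- out$b / out$expected
  out
}

#' Forbes coefficients for labelled somatic subsets
#'
#' Restricts the somatic call set to one label at a time (e.g. cancer
#' type), keeping the full germline set, and computes a Forbes coefficient
#' per label. Empty labels are excluded.
#'
#' @param somatic Somatic calls.
#' @param germline Germline calls.
#' @param universe Annotated universe.
#' @param by Name of the somatic column holding the label (default
#'   `"project"`).
#' @return Tibble: label column, `s`, `b`, `expected`, `coefficient`,
#'   `shared_rate` (= b/s).
#' @export
subset_forbes <- function(somatic, germline, universe, by = "project") {
  if (!by %in% names(somatic)) {
    abort(sprintf("somatic calls have no column '%s'", by))
  }
  n <- nrow(universe)
  gl <- distinct_site_alleles(germline)
  g <- nrow(gl)
  key <- c("chrom", "pos", "ref", "alt")
  per <- dplyr::distinct(
    somatic,
    dplyr::pick(dplyr::all_of(c(by, key)))
  )
  shared <- dplyr::semi_join(per, gl, by = key)
  s_tab <- dplyr::count(per, .data[[by]], name = "s")
  b_tab <- dplyr::count(shared, .data[[by]], name = "b")
  out <- dplyr::left_join(s_tab, b_tab, by = by)
  out$b <- dplyr::coalesce(out$b, 0L)
  out <- dplyr::filter(out, .data$s > 0)
  out$expected <- expected_independence(g, out$s, n)
  out$coefficient <- out$b / out$expected
  out$shared_rate <- out$b / out$s
  out
}
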