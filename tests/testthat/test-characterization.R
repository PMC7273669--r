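mk_cat <- function(trimers, seed_base = 1) {
  n <- length(trimers)
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n) + seed_base * 10000L,
    ref = "C", alt = "T", trimer = trimers
  )
}

test_that("matched downsampling hits the per-trimer minimum exactly", {
  a <- mk_cat(rep(c("A[C>T]A", "G[C>T]G"), c(10, 4)), 1)
  b <- mk_cat(rep(c("A[C>T]A", "G[C>T]G"), c(6, 8)), 2)
  out <- trinucleotide_matched_downsample(list(A = a, B = b), seed = 5)
  counts <- function(df) table(factor(df$trimer, c("A[C>T]A", "G[C>T]G")))
  expect_equal(as.integer(counts(out$A)), c(6L, 4L))
  expect_equal(as.integer(counts(out$B)), c(6L, 4L))
  # identical post-matching distributions: chi-square statistic is zero
  expect_equal(unname(counts(out$A)), unname(counts(out$B)))
  # downsampled rows are a subset of the originals
  expect_equal(nrow(dplyr::anti_join(out$A, a, by = names(a))), 0)
})

test_that("matching leaves identical distributions untouched and is seed-stable", {
  a <- mk_cat(rep(c("A[C>T]A", "G[C>T]G"), c(5, 5)), 1)
  b <- mk_cat(rep(c("A[C>T]A", "G[C>T]G"), c(5, 5)), 2)
  out <- trinucleotide_matched_downsample(list(A = a, B = b), seed = 1)
  expect_equal(nrow(out$A), 10)
  expect_equal(nrow(out$B), 10)
  # single category unchanged
  expect_identical(
    trinucleotide_matched_downsample(list(only = a), seed = 1)$only, a
  )
  # determinism and input-order invariance
  big_a <- mk_cat(rep(c("A[C>T]A", "G[C>T]G", "T[C>T]T"), c(30, 20, 10)), 1)
  big_b <- mk_cat(rep(c("A[C>T]A", "G[C>T]G"), c(12, 25)), 2)
  r1 <- trinucleotide_matched_downsample(list(A = big_a, B = big_b), seed = 9)
  r2 <- trinucleotide_matched_downsample(list(A = big_a, B = big_b), seed = 9)
  r3 <- trinucleotide_matched_downsample(list(B = big_b, A = big_a), seed = 9)
  expect_identical(r1, r2)
  expect_identical(r1$A, r3$A)
  expect_identical(r1$B, r3$B)
  # a trimer absent from one category disappears from all
  expect_false("T[C>T]T" %in% r1$A$trimer)
})

test_that("matched categories without a selection mechanism score equal coefficients", {
  cohort <- small_cohort()
  key <- c("chrom", "pos", "ref", "alt")
  s <- dplyr::distinct(
    cohort$somatic_calls, chrom, pos, ref, alt,
    .keep_all = TRUE
  )
  s <- dplyr::inner_join(
    dplyr::select(s, dplyr::all_of(key)),
    dplyr::select(cohort$universe, dplyr::all_of(key), trimer),
    by = key
  )
  # random split emulating synonymous/nonsynonymous labels with different
  # context mixes: split by whether the site index is even after sorting
  s <- dplyr::arrange(s, chrom, pos, alt)
  cat_a <- s[seq(1, nrow(s), by = 2), c(key, "trimer")]
  cat_b <- s[seq(2, nrow(s), by = 2), c(key, "trimer")]
  res <- matched_forbes_comparison(
    list(syn = cat_a, nonsyn = cat_b),
    cohort$germline_calls, cohort$universe,
    seed = 3
  )
  expect_equal(nrow(res), 2)
  expect_lt(
    abs(res$coefficient[1] - res$coefficient[2]) /
      mean(res$coefficient), 0.35
  )
  # full-set category equals the global coefficient
  full <- matched_forbes_comparison(
    list(all = s[, c(key, "trimer")]),
    cohort$germline_calls, cohort$universe
  )
  g_cnt <- nrow(dplyr::distinct(cohort$germline_calls, chrom, pos, ref, alt))
  glob <- forbes(
    count_shared(cohort$germline_calls, s), g_cnt, nrow(s),
    nrow(cohort$universe)
  )
  expect_equal(full$coefficient, glob$coefficient)
})

test_that("age analysis reproduces prop.test and respects binning edges", {
  g <- tibble::tibble(
    chrom = "chr1", pos = 1:400, ref = "A", alt = "C",
    age = rep(c(10, 5000), each = 200)
  )
  # young variants shared at 30%, old at 10%
  shared_pos <- c(1:60, 201:220)
  s <- tibble::tibble(chrom = "chr1", pos = shared_pos, ref = "A", alt = "C")
  out <- shared_rate_by_allele_age(g, s, threshold = 500)
  expect_equal(out$comparison$rate_young, 0.3)
  expect_equal(out$comparison$rate_old, 0.1)
  oracle <- prop.test(c(60, 20), c(200, 200))
  expect_equal(out$comparison$p_value, oracle$p.value)
  expect_equal(sum(out$by_bin$n), 400)
  expect_equal(sum(out$by_bin$shared), 80)
  # all variants in one group: comparison skipped with a warning
  expect_warning(
    one <- shared_rate_by_allele_age(
      dplyr::mutate(g, age = 10), s,
      threshold = 500
    ),
    "skipped"
  )
  expect_null(one$comparison)
})

test_that("age-independent cohorts show no significant young/old difference", {
  pvals <- vapply(1:6, function(seed) {
    cohort <- cached_cohort(
      exome_length = 6e4, age_rate_bias = 0, age_gc_bias = 0,
      seed = 600 + seed
    )
    out <- shared_rate_by_allele_age(
      cohort$germline_calls, cohort$somatic_calls
    )
    out$comparison$p_value
  }, numeric(1))
  # under the null, small p-values appear at the nominal rate
  expect_lte(sum(pvals < 0.05), 2)
})

test_that("the mutation-prone-sites-are-younger mechanism elevates young bins", {
  cohort <- cached_cohort(
    exome_length = 2e5, age_rate_bias = 1.2, seed = 610,
    n_somatic_samples = 20
  )
  out <- shared_rate_by_allele_age(
    cohort$germline_calls, cohort$somatic_calls,
    threshold = 500
  )
  expect_gt(out$comparison$rate_young, out$comparison$rate_old)
  expect_lt(out$comparison$p_value, 0.05)
})

test_that("continent-count analysis flags recurrent ultra-rare variants", {
  cohort <- cached_cohort(
    exome_length = 2e5, seed = 620, n_somatic_samples = 20
  )
  tab <- shared_rate_by_continent_count(
    cohort$germline_calls, cohort$somatic_calls
  )
  ultra <- dplyr::filter(tab, as.integer(ac_stratum) == 1, n >= 50)
  # among ultra-rare variants the shared rate rises with continent count
  if (nrow(ultra) >= 2) {
    expect_gt(
      ultra$rate[which.max(ultra$n_continents)],
      ultra$rate[which.min(ultra$n_continents)]
    )
  }
  # weighted cell rates recover the global shared count exactly
  expect_equal(
    sum(tab$shared),
    count_shared(cohort$germline_calls, cohort$somatic_calls)
  )
})

test_that("single-continent germline sets yield one continent-count column", {
  cohort <- cached_cohort(exome_length = 4e4, n_continents = 1, seed = 630)
  tab <- shared_rate_by_continent_count(
    cohort$germline_calls, cohort$somatic_calls
  )
  expect_true(all(tab$n_continents == 1))
})

test_that("the ancestry cross table is exchangeable without ancestry-linked leakage", {
  cohort <- cached_cohort(
    exome_length = 1e5, leakage_per_exome = 0, seed = 640,
    n_somatic_samples = 40
  )
  tab <- ancestry_cross_table(cohort$germline_calls, cohort$somatic_calls)
  expect_true(all(c("germline_ancestry", "somatic_ancestry", "rate") %in% names(tab)))
  # cells agree within Monte-Carlo error: no cell deviates wildly
  expect_lt(diff(range(tab$rate)), max(0.15, 6 * stats::sd(tab$rate)))

  # heavy ancestry-linked leakage elevates the matched (diagonal) cells
  leaky <- cached_cohort(
    exome_length = 1e5, leakage_per_exome = 60, seed = 641,
    n_somatic_samples = 40
  )
  tab2 <- ancestry_cross_table(leaky$germline_calls, leaky$somatic_calls)
  diag_rate <- mean(tab2$rate[tab2$germline_ancestry == tab2$somatic_ancestry])
  off_rate <- mean(tab2$rate[tab2$germline_ancestry != tab2$somatic_ancestry])
  expect_gt(diag_rate, off_rate)
})

test_that("a single ancestry on each side gives a 1x1 table", {
  g <- tibble::tibble(
    chrom = "chr1", pos = 1:50, ref = "A", alt = "C", ac_nfe = 1L
  )
  s <- tibble::tibble(
    chrom = "chr1", pos = 26:75, ref = "A", alt = "C",
    ancestry = "NFE", sample = "s1"
  )
  tab <- ancestry_cross_table(g, s)
  expect_equal(dim(tab), c(1L, 5L))
  expect_equal(tab$rate, 0.5)
})

test_that("leaked variants raise the VAF of the shared group", {
  cohort <- cached_cohort(
    exome_length = 1e5, leakage_per_exome = 20, seed = 650,
    n_somatic_samples = 30
  )
  out <- vaf_comparison(cohort$somatic_calls, cohort$germline_calls)
  med <- setNames(out$summary$median, out$summary$group)
  expect_gt(med["shared"], med["unique"])
  expect_lt(out$test$p_value, 0.05)
})

test_that("VAF comparison handles identical and single-group inputs", {
  s <- tibble::tibble(
    chrom = "chr1", pos = rep(1:20, 2), ref = "A", alt = "C",
    vaf = rep(seq(0.05, 1, length.out = 20), 2), sample = "s1"
  )
  g_all <- tibble::tibble(chrom = "chr1", pos = 1:20, ref = "A", alt = "C")
  both <- vaf_comparison(s, g_all)
  expect_equal(nrow(both$summary), 1) # everything shared -> one group
  expect_null(both$test)
  g_none <- tibble::tibble(chrom = "chr2", pos = 1:5, ref = "A", alt = "C")
  none <- vaf_comparison(s, g_none)
  expect_equal(none$summary$group, "unique")
})
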