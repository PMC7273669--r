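# Totals from the published gnomAD/TCGA comparison, used as a frozen
# worked example for the statistics layer.
G0 <- 5225731
S0 <- 1629311
N0 <- 73517652
B0 <- 336987

test_that("independence expectation reproduces the worked example", {
  expect_equal(round(expected_independence(G0, S0, N0)), 115814)
  expect_equal(expected_independence(0, S0, N0), 0)
  expect_equal(expected_independence(10, 10, 100), 1)
  expect_error(expected_independence(5, 5, 0), "n must be")
})

test_that("Forbes coefficient reproduces the worked example", {
  f <- forbes(B0, G0, S0, N0)
  expect_equal(round(f$coefficient, 3), 2.910)
  expect_equal(round(f$explained_fraction, 3), 0.344)
  # b equal to the expectation gives exactly 1
  expect_equal(forbes(25, 50, 50, 100)$coefficient, 1)
  expect_error(forbes(1, 0, 10, 100), "undefined")
  expect_error(forbes(11, 10, 100, 1000), "exceed")
})

test_that("shared counting agrees with brute-force set intersection", {
  for (seed in 1:20) {
    u <- random_universe(150, seed)
    g <- sample_calls(u, 90, seed + 100)
    s <- sample_calls(u, 60, seed + 200)
    expect_equal(count_shared(g, s), oracle_shared(g, s))
    expect_equal(count_shared(g, s, universe = u), oracle_shared(g, s))
  }
  # disjoint and identical sets
  u <- random_universe(50, 1)
  g <- u[1:30, ]
  s <- u[31:60, ]
  expect_equal(count_shared(g, s), 0)
  expect_equal(count_shared(g, g), nrow(g))
})

test_that("calls outside the universe are a contract violation", {
  u <- random_universe(50, 2)
  g <- sample_calls(u, 10, 3)
  rogue <- tibble::tibble(chrom = "chrX", pos = 1L, ref = "A", alt = "C")
  expect_error(count_shared(rbind(g, rogue), g, universe = u), "outside")
  expect_error(partition_table(u, rbind(g, rogue), g), "outside")
})

test_that("partition-conditioned Forbes reduces to plain Forbes for m = 1", {
  tab <- tibble::tibble(partition = "all", n = 1000L, g = 100L, s = 80L, b = 30L)
  pf <- partition_forbes(tab)
  f <- forbes(30, 100, 80, 1000)
  expect_equal(pf$coefficient, f$coefficient)
  expect_equal(pf$expected, f$expected)
  expect_equal(pf$m, 1L)
})

test_that("partitioned expectation follows the direct arithmetic oracle", {
  tab <- tibble::tibble(
    partition = c("a", "b"),
    n = c(100L, 100L), g = c(20L, 2L), s = c(20L, 2L), b = c(5L, 1L)
  )
  pf <- partition_forbes(tab)
  expect_equal(pf$expected, 20 * 20 / 100 + 2 * 2 / 100) # 4.04
  un <- forbes(6, 22, 22, 200)
  expect_equal(un$expected, 2.42)
  # empty partitions contribute nothing
  tab3 <- rbind(tab, tibble::tibble(partition = "c", n = 0L, g = 0L, s = 0L, b = 0L))
  expect_equal(partition_forbes(tab3)$expected, pf$expected)
  expect_error(
    partition_forbes(tibble::tibble(partition = "x", n = 0L, g = 0L, s = 0L, b = 0L)),
    "empty"
  )
})

test_that("the published conditioned coefficients follow from their expected counts", {
  expect_equal(round(B0 / 294619, 3), 1.144)
  expect_equal(round(B0 / 307393, 3), 1.096)
  expect_equal(round(100 * 115814 / B0, 1), 34.4)
  expect_equal(round(100 * 294619 / B0, 1), 87.4)
  expect_equal(round(100 * 307393 / B0, 1), 91.2)
})

test_that("explained fractions telescope across nested partitions", {
  u <- small_cohort()$universe
  g <- small_cohort()$germline_calls
  s <- small_cohort()$somatic_calls
  dec <- forbes_decomposition(
    u, g, s,
    levels = c("unpartitioned", "basic_class", "trimer")
  )
  expect_equal(dec$m, c(1L, 3L, dplyr::n_distinct(u$trimer)))
  expect_equal(
    dec$incremental,
    dec$explained_fraction - dplyr::lag(dec$explained_fraction, default = 0)
  )
  expect_equal(sum(dec$incremental), dec$explained_fraction[nrow(dec)])
  # refinement with shared context effects should not reduce the expectation
  expect_true(all(diff(dec$expected) >= -1e-9))
  # full explanation when expected equals b
  full <- explained_decomposition(
    list(all = tibble::tibble(partition = "x", n = 100L, g = 10L, s = 10L, b = 1L))
  )
  expect_equal(full$explained_fraction, 1)
})

test_that("partition tables conserve totals", {
  cohort <- small_cohort()
  u <- cohort$universe
  g <- cohort$germline_calls
  s <- cohort$somatic_calls
  for (by in list(NULL, "basic_class", "trimer")) {
    tab <- partition_table(u, g, s, by = by)
    expect_equal(sum(tab$n), nrow(u))
    expect_equal(sum(tab$g), nrow(dplyr::distinct(g, chrom, pos, ref, alt)))
    expect_equal(sum(tab$s), nrow(dplyr::distinct(s, chrom, pos, ref, alt)))
    expect_equal(sum(tab$b), count_shared(g, s))
    expect_true(all(tab$b <= pmin(tab$g, tab$s)))
    expect_true(all(tab$g <= tab$n & tab$s <= tab$n))
  }
})

test_that("sum of partition expectations exceeds the pooled expectation iff rates covary", {
  # positively covarying per-cell rates
  pos <- tibble::tibble(
    partition = c("a", "b"), n = c(100L, 100L),
    g = c(30L, 5L), s = c(30L, 5L), b = c(9L, 1L)
  )
  e_pos <- partition_forbes(pos)$expected
  e_pool <- expected_independence(35, 35, 200)
  expect_gt(e_pos, e_pool)
  # negatively covarying
  neg <- tibble::tibble(
    partition = c("a", "b"), n = c(100L, 100L),
    g = c(30L, 5L), s = c(5L, 30L), b = c(2L, 2L)
  )
  expect_lt(partition_forbes(neg)$expected, e_pool)
})

test_that("per-sample coefficients behave at the algebraic edges", {
  u <- random_universe(400, 7)
  g <- sample_calls(u, 200, 8)
  # sample A: all variants shared -> coefficient = n/g; sample B: single
  # unshared variant -> coefficient 0
  sa <- dplyr::mutate(g[1:10, ], sample = "A")
  unshared <- dplyr::anti_join(u, g, by = c("chrom", "pos", "ref", "alt"))
  sb <- dplyr::mutate(unshared[1, ], sample = "B")
  ps <- per_sample_forbes(rbind(sa, sb), g, u)
  expect_equal(
    ps$coefficient[ps$sample == "A"], nrow(u) / nrow(g)
  )
  expect_equal(ps$coefficient[ps$sample == "B"], 0)
})

test_that("per-sample coefficients centre above 1 under shared context effects", {
  cohort <- small_cohort()
  ps <- per_sample_forbes(
    cohort$somatic_calls, cohort$germline_calls, cohort$universe
  )
  expect_equal(nrow(ps), cohort$config$n_somatic_samples)
  expect_gt(mean(ps$coefficient), 1)
})

test_that("subset coefficients reduce to the global value for the whole cohort", {
  cohort <- small_cohort()
  s <- dplyr::mutate(cohort$somatic_calls, whole = "all")
  sub <- subset_forbes(s, cohort$germline_calls, cohort$universe, by = "whole")
  g_cnt <- nrow(dplyr::distinct(cohort$germline_calls, chrom, pos, ref, alt))
  s_cnt <- nrow(dplyr::distinct(s, chrom, pos, ref, alt))
  glob <- forbes(
    count_shared(cohort$germline_calls, s),
    g_cnt, s_cnt, nrow(cohort$universe)
  )
  expect_equal(sub$coefficient, glob$coefficient)
})

test_that("deamination-heavy cancer types share more with the germline", {
  cohort <- cached_cohort(
    exome_length = 1e5, n_somatic_samples = 20,
    cancer_types = c("ENDO", "EXO"), cancer_deam_weight = c(4, 0.25),
    seed = 55
  )
  sub <- subset_forbes(
    cohort$somatic_calls, cohort$germline_calls, cohort$universe,
    by = "project"
  )
  expect_gt(
    sub$coefficient[sub$project == "ENDO"],
    sub$coefficient[sub$project == "EXO"]
  )
})

test_that("the bootstrap interval brackets the point coefficient", {
  cohort <- small_cohort()
  ci <- forbes_bootstrap(
    cohort$universe, cohort$germline_calls, cohort$somatic_calls,
    n_boot = 50, seed = 2
  )
  glob <- forbes(
    count_shared(cohort$germline_calls, cohort$somatic_calls),
    nrow(dplyr::distinct(cohort$germline_calls, chrom, pos, ref, alt)),
    nrow(dplyr::distinct(cohort$somatic_calls, chrom, pos, ref, alt)),
    nrow(cohort$universe)
  )
  expect_equal(ci$coefficient, glob$coefficient, tolerance = 1e-12)
  expect_true(ci$conf_low < glob$coefficient & glob$coefficient < ci$conf_high)
  # deterministic under the seed
  ci2 <- forbes_bootstrap(
    cohort$universe, cohort$germline_calls, cohort$somatic_calls,
    n_boot = 50, seed = 2
  )
  expect_equal(ci, ci2)
})

test_that("tidy and glance return the documented shapes", {
  f <- forbes(B0, G0, S0, N0)
  expect_equal(nrow(tidy(f)), 1)
  expect_named(
    glance(f),
    c("m", "n", "g", "s", "b", "expected", "coefficient", "explained_fraction")
  )
  tab <- tibble::tibble(
    partition = c("a", "b"), n = c(10L, 20L), g = c(2L, 3L),
    s = c(1L, 4L), b = c(1L, 1L)
  )
  td <- tidy(partition_forbes(tab))
  expect_equal(nrow(td), 2)
  expect_true(all(c("expected", "coefficient") %in% names(td)))
})
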