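toy_reference <- function() {
  # 60-base single chromosome named like an autosome
  c(chr1 = paste(rep("ACGTGTCCGGAT", 5), collapse = ""))
}

test_that("the universe holds exactly three potential SNVs per surviving site", {
  ref <- toy_reference()
  spec <- whitelist_spec(
    target_sets = list(tibble::tibble(chrom = "chr1", start = 11, end = 20)),
    blacklists = list(tibble::tibble(chrom = "chr1", start = 15, end = 18)),
    gc_min = 0, gc_max = 1
  )
  u <- build_universe(ref, spec)
  expect_equal(sort(unique(u$pos)), c(11:14, 19:20))
  expect_equal(nrow(u), 3 * 6)
  expect_true(all(u$ref != u$alt))
  stages <- attr(u, "filter_stages")
  expect_true(all(diff(unname(stages[c(
    "reference", "targets", "blacklists", "autosomes", "coverage", "gc_window"
  )])) <= 0))
})

test_that("interval filtering agrees with a per-base membership oracle", {
  set.seed(42)
  for (rep in 1:25) {
    L <- 400L
    ref <- c(chr1 = paste(
      sample(c("A", "C", "G", "T"), L, replace = TRUE),
      collapse = ""
    ))
    mk_iv <- function(k) {
      s <- sort(sample.int(L, k))
      tibble::tibble(
        chrom = "chr1", start = s,
        end = pmin(s + sample(0:30, k, replace = TRUE), L)
      )
    }
    targets <- list(mk_iv(4), mk_iv(5))
    blacklist <- list(mk_iv(3))
    spec <- whitelist_spec(
      target_sets = targets, blacklists = blacklist, gc_min = 0, gc_max = 1
    )
    u <- suppressWarnings(build_universe(ref, spec))
    # oracle: per-base membership
    in_iv <- function(p, iv) any(p >= iv$start & p <= iv$end)
    keep <- vapply(seq_len(L), function(p) {
      all(vapply(targets, in_iv, p = p, logical(1))) &&
        !any(vapply(blacklist, in_iv, p = p, logical(1)))
    }, logical(1))
    expect_equal(sort(unique(u$pos)), which(keep))
  }
})

test_that("the GC-window rule excludes extreme-GC sites", {
  # AT-rich head, long GC-rich core, AT-rich tail: window GC spans ~0 to ~1
  ref <- c(chr1 = paste0(strrep("AT", 40), strrep("GC", 60), strrep("TA", 40)))
  L <- nchar(ref)
  spec <- whitelist_spec(
    target_sets = list(tibble::tibble(chrom = "chr1", start = 1, end = L))
  )
  u <- build_universe(ref, spec)
  # oracle: GC fraction of the 50-base flanks excluding the site itself
  s <- strsplit(unname(ref), "")[[1]]
  gc_at <- vapply(seq_len(L), function(p) {
    w <- s[setdiff(max(1, p - 50):min(L, p + 50), p)]
    mean(w %in% c("G", "C"))
  }, numeric(1))
  keep <- which(gc_at >= 0.3 & gc_at <= 0.7)
  expect_equal(sort(unique(u$pos)), keep)
  # the rule is binding in both directions on this fixture
  expect_true(any(gc_at > 0.7) && any(gc_at < 0.3))
  # a site deep in the GC core is excluded
  expect_false(130 %in% u$pos)
})

test_that("the allele-frequency cutoff removes AF >= 0.001 and keeps AF below it", {
  ref <- toy_reference()
  spec <- whitelist_spec(
    target_sets = list(tibble::tibble(chrom = "chr1", start = 5, end = 24)),
    gc_min = 0, gc_max = 1
  )
  base <- build_universe(ref, spec)
  g <- base[base$pos %in% c(10, 11), ][c(1, 4), c("chrom", "pos", "ref", "alt")]
  g$af <- c(0.001, 0.0009)
  u <- build_universe(ref, spec, germline = g)
  expect_false(any(
    u$pos == g$pos[1] & u$alt == g$alt[1]
  ))
  expect_true(any(
    u$pos == g$pos[2] & u$alt == g$alt[2]
  ))
  # allele mode removes only the one alt; the site keeps its other two
  expect_equal(sum(u$pos == g$pos[1]), 2)
  # site mode removes all three
  spec$af_filter_mode <- "site"
  u2 <- build_universe(ref, spec, germline = g)
  expect_equal(sum(u2$pos == g$pos[1]), 0)
})

test_that("coverage and autosome rules apply", {
  ref <- c(chr1 = strrep("ACGT", 10), chrX = strrep("ACGT", 10))
  cov <- tibble::tibble(
    chrom = "chr1", pos = 1:40, frac = rep(c(0.9, 0.2), 20)
  )
  spec <- whitelist_spec(
    target_sets = list(tibble::tibble(
      chrom = c("chr1", "chrX"), start = 1, end = 40
    )),
    coverage_track = cov, gc_min = 0, gc_max = 1
  )
  u <- build_universe(ref, spec)
  expect_true(all(u$chrom == "chr1"))
  expect_true(all(u$pos %% 2 == 1)) # only the 0.9-coverage positions
})

test_that("an empty universe warns rather than failing silently", {
  ref <- toy_reference()
  spec <- whitelist_spec(
    target_sets = list(tibble::tibble(chrom = "chr1", start = 1, end = 60)),
    blacklists = list(tibble::tibble(chrom = "chr1", start = 1, end = 60))
  )
  expect_warning(u <- build_universe(ref, spec), "empty")
  expect_equal(nrow(u), 0)
})

test_that("variant-level filters keep PASS germline and drop artifact somatic calls", {
  g <- tibble::tibble(
    chrom = "chr1", pos = 1:3, ref = "A", alt = "C",
    filter = c("PASS", "RF", "PASS")
  )
  expect_equal(apply_variant_filters(g, "germline")$pos, c(1L, 3L))
  s <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "C",
    filter = c("PASS", "oxog", "nonpreferredpair", "PASS;other")
  )
  expect_equal(apply_variant_filters(s, "somatic")$pos, c(1L, 4L))
  # idempotence
  once <- apply_variant_filters(s, "somatic")
  expect_equal(apply_variant_filters(once, "somatic"), once)
})

test_that("filtering deduplicates presence but keeps sample-level records", {
  s <- tibble::tibble(
    chrom = "chr1", pos = c(5L, 5L), ref = "A", alt = "C",
    sample = c("s1", "s2"), filter = "PASS"
  )
  kept <- apply_variant_filters(s, "somatic")
  expect_equal(nrow(kept), 2)
  expect_equal(count_shared(kept, kept), 1)
})

test_that("cohort files round-trip through the readers", {
  cohort <- cached_cohort(exome_length = 2e4, n_somatic_samples = 5, seed = 31)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(back$reference, cohort$reference)

  g0 <- dplyr::arrange(cohort$germline_calls, chrom, pos, alt)
  g1 <- dplyr::arrange(back$germline_calls, chrom, pos, alt)
  expect_equal(g1$pos, g0$pos)
  expect_equal(g1$ref, g0$ref)
  expect_equal(g1$alt, g0$alt)
  expect_equal(g1$ac, g0$ac)
  expect_equal(g1$af, g0$af, tolerance = 1e-6)
  expect_equal(g1$age, g0$age, tolerance = 1e-5)
  expect_equal(g1$filter, g0$filter)
  expect_equal(g1$ac_afr, g0$ac_afr)

  s0 <- dplyr::arrange(cohort$somatic_calls, chrom, pos, alt, sample)
  s1 <- dplyr::arrange(back$somatic_calls, chrom, pos, alt, sample)
  for (col in c("chrom", "pos", "ref", "alt", "sample", "project", "n_depth", "filter", "origin")) {
    expect_equal(s1[[col]], s0[[col]], label = col)
  }
  expect_equal(s1$vaf, s0$vaf, tolerance = 1e-6)
  # truth column for leaked variants survives the round trip
  if (any(s0$origin == "leaked_germline")) {
    expect_true("leaked_germline" %in% s1$origin)
  }
  # universe BED covers exactly the universe's sites
  sites <- dplyr::distinct(cohort$universe, chrom, pos)
  in_bed <- vapply(seq_len(nrow(sites)), function(i) {
    any(back$universe_sites$chrom == sites$chrom[i] &
      back$universe_sites$start <= sites$pos[i] &
      back$universe_sites$end >= sites$pos[i])
  }, logical(1))
  expect_true(all(in_bed))
  expect_equal(
    sum(back$universe_sites$end - back$universe_sites$start + 1),
    nrow(sites)
  )
})

test_that("an empty cohort writes valid headers with zero records", {
  cohort <- cached_cohort(
    exome_length = 2e4, n_somatic_samples = 2, seed = 32,
    germline_site_rate = 1e-6, somatic_site_rate = 1e-6,
    leakage_per_exome = 0
  )
  # force-empty both call sets
  cohort$germline_calls <- cohort$germline_calls[0, ]
  cohort$somatic_calls <- cohort$somatic_calls[0, ]
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$germline_calls), 0)
  expect_equal(nrow(back$somatic_calls), 0)
})

test_that("multi-allelic VCF records split into one row per alt", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "##FILTER=<ID=RF,Description=\"rf\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t10\t.\tA\tC\t.\tPASS\tAC=3;AF=0.0001",
    "chr1\t20\t.\tG\tA,T\t.\tPASS\tAC=5,2;AF=0.0002,0.00008",
    "chr1\t30\t.\tC\tT\t.\tRF\tAC=1;AF=0.00001"
  ), path)
  g <- read_germline_sites(path)
  expect_equal(nrow(g), 4)
  expect_equal(g$alt[g$pos == 20], c("A", "T"))
  expect_equal(g$ac[g$pos == 20], c(5, 2))
  # records failing FILTER are retained with their flag
  expect_equal(g$filter[g$pos == 30], "RF")
})

test_that("malformed inputs raise informative errors", {
  bad_vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf at all"), bad_vcf)
  expect_error(read_germline_sites(bad_vcf), "malformed VCF")

  bad_maf <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(tibble::tibble(Chromosome = "chr1", Start_Position = 1), bad_maf)
  expect_error(read_somatic_maf(bad_maf), "schema error")
})

test_that("non-SNV MAF rows are dropped with a count", {
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(tibble::tibble(
    Chromosome = "chr1", Start_Position = c(1, 2, 3),
    Reference_Allele = c("A", "AT", "G"),
    Tumor_Seq_Allele2 = c("C", "T", "-"),
    Tumor_Sample_Barcode = "s1", project_code = "CT1",
    t_vaf = 0.4, n_depth = 50L, FILTER = "PASS"
  ), path)
  expect_message(s <- read_somatic_maf(path), "dropped 2")
  expect_equal(nrow(s), 1)
})

test_that("BED conversion preserves 1-based inclusive coordinates", {
  iv <- tibble::tibble(chrom = "chr1", start = c(5L, 11L), end = c(9L, 11L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, path)
  # on disk: 0-based half-open
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(raw$X2, c(4, 10))
  expect_equal(raw$X3, c(9, 11))
  expect_equal(read_bed(path)[c("chrom", "start", "end")], iv)
})
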