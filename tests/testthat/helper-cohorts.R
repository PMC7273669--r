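# Shared fixtures built in code. Cohorts are cached per option set so the
# generator runs once per configuration across the whole suite.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(...) {
  args <- list(...)
  key <- paste(deparse(args), collapse = "")
  if (!exists(key, envir = .cohort_cache)) {
    cfg <- do.call(generator_config, args)
    assign(key, simulate_cohort(cfg), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# The suite's workhorse: a small cohort under default study conditions.
small_cohort <- function(seed = 11) {
  cached_cohort(exome_length = 6e4, n_somatic_samples = 12, seed = seed)
}

# Deterministic tiny call-set fixtures for oracle tests.
random_universe <- function(n_sites, seed) {
  set.seed(seed)
  sites <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
    pos = sample.int(10 * n_sites, n_sites)
  )
  sites <- dplyr::distinct(sites, chrom, pos)
  sites$ref <- sample(c("A", "C", "G", "T"), nrow(sites), replace = TRUE)
  u <- sites[rep(seq_len(nrow(sites)), each = 3), ]
  u$alt <- unlist(lapply(sites$ref, function(b) setdiff(c("A", "C", "G", "T"), b)))
  tibble::as_tibble(u)
}

sample_calls <- function(universe, k, seed) {
  set.seed(seed)
  universe[sample.int(nrow(universe), k), c("chrom", "pos", "ref", "alt")]
}

# Brute-force oracle: shared count by string-key set intersection.
oracle_shared <- function(g, s) {
  gk <- unique(paste(g$chrom, g$pos, g$ref, g$alt))
  sk <- unique(paste(s$chrom, s$pos, s$ref, s$alt))
  length(intersect(gk, sk))
}

# Independent reverse-complement oracle (character by character).
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(unname(comp[ch])), collapse = ""),
    character(1)
  )
}
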