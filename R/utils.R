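# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")

# Continental ancestry codes used for per-continent allele counts. The first
# n_continents of these label the generator's continents.
CONTINENT_CODES <- c("AFR", "AMR", "EAS", "NFE", "SAS", "OTH")

#' @noRd
complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Reverse-complement of a vector of sequences (vectorized; delegates the
# heavy lifting to Biostrings).
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0) {
    return(character(0))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
assert_bases <- function(x, what = "base") {
  bad <- !is.na(x) & !(x %in% BASES)
  if (any(bad)) {
    abort(sprintf(
      "invalid %s value(s): %s (must be A, C, G or T)",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

# Derive a stage-specific RNG seed from a master seed. Stage indices are
# small fixed integers per stage; the result stays below 2^31.
#' @noRd
substream_seed <- function(seed, stage) {
  (as.double(seed) * 97L + stage * 7919L) %% 2147483647
}

#' @noRd
with_substream <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stage))
  force(code)
}

# Unique site-alleles of a call set.
#' @noRd
distinct_site_alleles <- function(calls) {
  dplyr::distinct(calls, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' @noRd
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g)", name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

# Expand a site tibble (with `ref`) into one row per alternate allele:
# every site contributes its three possible substitutions.
#' @noRd
expand_alts <- function(sites) {
  n <- nrow(sites)
  out <- sites[rep(seq_len(n), each = 3L), , drop = FALSE]
  if (n == 0) {
    out$alt <- character(0)
    return(out)
  }
  alt_lookup <- lapply(BASES, function(b) setdiff(BASES, b))
  names(alt_lookup) <- BASES
  out$alt <- unlist(alt_lookup[sites$ref], use.names = FALSE)
  out
}

# Fraction of G/C in the window of `window` bases around each position
# (window/2 on each flank, the site itself excluded). Windows are truncated
# at chromosome ends. `seq_str` is a single chromosome string, `pos` 1-based.
#' @noRd
gc_window_content <- function(seq_str, pos, window = 100) {
  flank <- window %/% 2
  n <- nchar(seq_str)
  is_gc <- as.integer(strsplit(seq_str, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  cum <- c(0, cumsum(is_gc))
  lo <- pmax(pos - flank, 1L)
  hi <- pmin(pos + flank, n)
  tot <- cum[hi + 1] - cum[lo]
  site <- is_gc[pos]
  width <- hi - lo + 1L - 1L # window size excluding the site itself
  (tot - site) / pmax(width, 1L)
}
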