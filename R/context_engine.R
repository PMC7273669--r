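#' Collapse substitution contexts onto the pyrimidine strand
#'
#' Canonicalizes a nucleotide substitution context so the central reference
#' base is a pyrimidine (C or T). Purine-centred contexts are
#' reverse-complemented: flanks are swapped and complemented and the
#' ref/alt pair complemented; pyrimidine-centred contexts are returned
#' unchanged. For example, the trimer context A\[G>T\]C is an instance of
#' G\[C>A\]T, because wherever one occurs on the forward strand, the other
#' occurs on the reverse strand.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param upstream,downstream Flanking sequences (equal lengths per element;
#'   may be "" for flank 0).
#' @param ref,alt Single reference/alternate bases (ref != alt).
#' @return Tibble with canonical `upstream`, `ref`, `alt`, `downstream` and
#'   the formatted `context` key, e.g. `"G[C>A]T"`.
#' @export
#' @examples
#' collapse_context("A", "G", "T", "C")$context # "G[C>A]T"
collapse_context <- function(upstream, ref, alt, downstream) {
  n <- max(length(upstream), length(ref), length(alt), length(downstream))
  upstream <- rep_len(toupper(upstream), n)
  downstream <- rep_len(toupper(downstream), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  assert_bases(ref, "ref")
  assert_bases(alt, "alt")
  bad_flank <- grepl("[^ACGT]", paste0(upstream, downstream))
  if (any(bad_flank)) {
    abort("invalid flank value(s): flanks must contain only A, C, G or T")
  }
  if (any(ref == alt, na.rm = TRUE)) abort("ref and alt must differ")
  if (any(nchar(upstream) != nchar(downstream))) {
    abort("upstream and downstream flanks must have equal length")
  }
  purine <- ref %in% c("A", "G")
  out_up <- upstream
  out_down <- downstream
  out_ref <- ref
  out_alt <- alt
  if (any(purine)) {
    out_up[purine] <- revcomp(downstream[purine])
    out_down[purine] <- revcomp(upstream[purine])
    out_ref[purine] <- complement_base(ref[purine])
    out_alt[purine] <- complement_base(alt[purine])
  }
  tibble(
    upstream = out_up, ref = out_ref, alt = out_alt, downstream = out_down,
    context = format_context(out_up, out_ref, out_alt, out_down)
  )
}

#' @noRd
format_context <- function(upstream, ref, alt, downstream) {
  paste0(upstream, "[", ref, ">", alt, "]", downstream)
}

# Reverse complement for equal-width short strings (width <= 3), built from
# per-position chartr/substr passes; much faster than generic machinery on
# millions of elements.
#' @noRd
revcomp_fixed <- function(x, width) {
  if (width == 0) {
    return(rep_len("", length(x)))
  }
  cols <- vector("list", width)
  for (i in seq_len(width)) {
    cols[[i]] <- complement_base(substr(x, width - i + 1L, width - i + 1L))
  }
  if (width == 1) cols[[1]] else do.call(paste0, cols)
}

# Trusted-input collapse used on whole universes: assumes uppercase ACGT
# single-base ref/alt and equal-width flanks, skipping validation and case
# handling. Returns list(upstream, ref, alt, downstream, context).
#' @noRd
collapse_fast <- function(upstream, ref, alt, downstream, flank) {
  purine <- ref == "A" | ref == "G"
  if (any(purine)) {
    new_up <- upstream
    new_down <- downstream
    new_up[purine] <- revcomp_fixed(downstream[purine], flank)
    new_down[purine] <- revcomp_fixed(upstream[purine], flank)
    ref[purine] <- complement_base(ref[purine])
    alt[purine] <- complement_base(alt[purine])
    upstream <- new_up
    downstream <- new_down
  }
  # 12 possible substitution cores; build via lookup instead of 7-way paste0
  core_idx <- (match(ref, BASES) - 1L) * 4L + match(alt, BASES)
  cores <- character(16)
  for (r in 1:4) {
    for (a in 1:4) cores[(r - 1) * 4 + a] <- paste0("[", BASES[r], ">", BASES[a], "]")
  }
  context <- if (flank == 0) {
    cores[core_idx]
  } else {
    paste0(upstream, cores[core_idx], downstream)
  }
  list(
    upstream = upstream, ref = ref, alt = alt, downstream = downstream,
    context = context
  )
}

# Parse "XX[C>T]YY" keys back into components.
#' @noRd
parse_context <- function(key) {
  m <- stringr::str_match(key, "^([ACGT]*)\\[([ACGT])>([ACGT])\\]([ACGT]*)$")
  if (anyNA(m[, 1])) {
    abort(sprintf(
      "malformed context key(s): %s",
      paste(head(unique(key[is.na(m[, 1])]), 5), collapse = ", ")
    ))
  }
  tibble(upstream = m[, 2], ref = m[, 3], alt = m[, 4], downstream = m[, 5])
}

# Central sub-context of a context key at a smaller flank (e.g. the trimer
# inside a pentamer). flank_to must not exceed the key's own flank.
#' @noRd
context_central <- function(key, flank_to) {
  p <- parse_context(key)
  f <- nchar(p$upstream)
  if (any(flank_to > f)) abort("flank_to exceeds the context's flank")
  format_context(
    substr(p$upstream, f - flank_to + 1, f),
    p$ref, p$alt,
    substr(p$downstream, 1, flank_to)
  )
}

#' Classify a substitution into its basic mutation class
#'
#' The three basic substitution classes are CpG deamination (C>T with a 3'
#' G on the pyrimidine strand, i.e. the spontaneous deamination of
#' methylated CpG to TpG), other transitions, and transversions. Inputs are
#' collapsed onto the pyrimidine strand first, so purine-centred
#' substitutions classify via their reverse complement (a G>A with a 5' C
#' is a deamination).
#'
#' @param ref,alt Reference/alternate bases (vectorized).
#' @param three_prime_base The base immediately 3' of `ref` (on `ref`'s
#'   strand). Required to separate deaminations from other transitions.
#' @param five_prime_base The base immediately 5' of `ref`; only consulted
#'   when `ref` is a purine (it is the 3' base after collapsing).
#' @return Factor with levels `deamination`, `other_transition`,
#'   `transversion`.
#' @export
#' @examples
#' classify_basic("C", "T", "G") # deamination
#' classify_basic("T", "C", "A") # other_transition
classify_basic <- function(ref, alt, three_prime_base,
                           five_prime_base = NULL) {
  n <- max(length(ref), length(alt), length(three_prime_base))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  three_prime_base <- rep_len(toupper(three_prime_base), n)
  up <- if (is.null(five_prime_base)) {
    rep_len("A", n) # placeholder; irrelevant for pyrimidine-centred input
  } else {
    rep_len(toupper(five_prime_base), n)
  }
  if (is.null(five_prime_base) && any(ref %in% c("A", "G"))) {
    abort("purine-centred input requires `five_prime_base` for collapsing")
  }
  cc <- collapse_context(up, ref, alt, three_prime_base)
  is_ti <- cc$ref == "C" & cc$alt == "T" | cc$ref == "T" & cc$alt == "C"
  is_deam <- cc$ref == "C" & cc$alt == "T" &
    substr(cc$downstream, 1, 1) == "G"
  out <- ifelse(is_deam, "deamination",
    ifelse(is_ti, "other_transition", "transversion")
  )
  factor(out, levels = BASIC_CLASSES)
}

#' @noRd
BASIC_CLASSES <- c("deamination", "other_transition", "transversion")

#' Enumerate all collapsed substitution contexts at a flank level
#'
#' @param flank Number of flanking bases on each side (0-3). Flank 1 gives
#'   the 96 trinucleotide contexts, flank 2 the 1536 pentanucleotide
#'   contexts, flank 3 the 24,576 heptanucleotide contexts; flank 0 gives
#'   the 6 pyrimidine substitution types.
#' @return Tibble with one row per context key: `context`, `upstream`,
#'   `ref`, `alt`, `downstream`, `basic_class`.
#' @export
#' @examples
#' nrow(enumerate_contexts(1)) # 96
enumerate_contexts <- function(flank) {
  check_scalar_number(flank, "flank", 0, 3)
  flank <- as.integer(flank)
  kmers <- function(f) {
    if (f == 0) {
      return("")
    }
    do.call(paste0, rev(expand.grid(rep(list(BASES), f),
      stringsAsFactors = FALSE
    )))
  }
  grid <- tidyr::expand_grid(
    upstream = kmers(flank),
    ref = PYRIMIDINES,
    alt = BASES,
    downstream = kmers(flank)
  )
  grid <- dplyr::filter(grid, .data$ref != .data$alt)
  grid$context <- format_context(
    grid$upstream, grid$ref, grid$alt, grid$downstream
  )
  # at flank 0 there is no 3' information, so deamination is not separable
  # from other transitions and every C>T keys as other_transition
  grid$basic_class <- classify_basic(
    grid$ref, grid$alt,
    three_prime_base = if (flank == 0) "A" else substr(grid$downstream, 1, 1)
  )
  dplyr::select(
    grid, "context", "upstream", "ref", "alt", "downstream", "basic_class"
  )
}

#' Annotate a universe of potential SNVs with substitution contexts
#'
#' Extracts the flanking reference bases around every potential SNV,
#' collapses contexts onto the pyrimidine strand, and assigns each variant
#' one context key per requested flank level plus its basic substitution
#' class. Sites lacking full flanks at the largest level (chromosome ends)
#' are dropped so all levels share one universe; the dropped count is
#' reported via a message.
#'
#' @param universe Tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @param reference Named character vector of chromosome sequences (as from
#'   [generate_reference()] or [read_reference_fasta()]).
#' @param flank Maximum flank level to annotate (1-3). Columns `trimer`,
#'   `pentamer`, `heptamer` are added up to this level.
#' @return The universe tibble with `basic_class` and context-key columns.
#' @export
annotate_universe <- function(universe, reference, flank = 1) {
  check_scalar_number(flank, "flank", 1, 3)
  flank <- as.integer(flank)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(universe)))
  missing_chrom <- setdiff(unique(universe$chrom), names(reference))
  if (length(missing_chrom) > 0) {
    abort(sprintf(
      "reference lacks chromosome(s): %s",
      paste(missing_chrom, collapse = ", ")
    ))
  }
  chrom_len <- setNames(nchar(reference), names(reference))
  full <- universe$pos > flank &
    universe$pos + flank <= chrom_len[universe$chrom]
  n_drop <- sum(!full)
  if (n_drop > 0) {
    inform(sprintf(
      "annotate_universe: dropped %d potential SNV(s) lacking full %d-base flanks",
      n_drop, flank
    ))
    universe <- universe[full, , drop = FALSE]
  }

  seqs <- unname(reference[universe$chrom])
  ref_base <- substr(seqs, universe$pos, universe$pos)
  bad <- ref_base != universe$ref
  if (any(bad)) {
    offending <- paste(
      utils::head(paste0(
        universe$chrom[bad], ":", universe$pos[bad],
        " (universe ", universe$ref[bad], ", reference ", ref_base[bad], ")"
      ), 10),
      collapse = "; "
    )
    abort(paste0("universe ref alleles disagree with the reference: ", offending))
  }

  up <- substr(seqs, universe$pos - flank, universe$pos - 1)
  down <- substr(seqs, universe$pos + 1, universe$pos + flank)
  cc <- collapse_fast(up, universe$ref, universe$alt, down, flank)
  out <- as_tibble(universe)
  key_max <- cc$context
  level_names <- c("trimer", "pentamer", "heptamer")
  # cc is already pyrimidine-collapsed; classify directly
  is_ti <- (cc$ref == "C" & cc$alt == "T") | (cc$ref == "T" & cc$alt == "C")
  is_deam <- cc$ref == "C" & cc$alt == "T" &
    substr(cc$downstream, 1, 1) == "G"
  out$basic_class <- factor(
    ifelse(is_deam, "deamination",
      ifelse(is_ti, "other_transition", "transversion")
    ),
    levels = BASIC_CLASSES
  )
  for (f in seq_len(flank)) {
    out[[level_names[f]]] <- if (f == flank) {
      key_max
    } else {
      format_context(
        substr(cc$upstream, flank - f + 1, flank),
        cc$ref, cc$alt,
        substr(cc$downstream, 1, f)
      )
    }
  }
  out
}
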