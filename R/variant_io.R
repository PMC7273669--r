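# Readers and writers for the standard formats (FASTA, sites-only VCF,
# MAF-style TSV, BED) plus the variant-level filters. Interval arithmetic
# and format parsing are delegated to Biostrings / rtracklayer /
# VariantAnnotation; this file owns the call-set schemas.

MAF_REQUIRED_COLUMNS <- c(
  "Chromosome", "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
  "Tumor_Sample_Barcode", "project_code", "t_vaf", "n_depth", "FILTER"
)

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a reference genome to FASTA
#'
#' @param reference Named character vector of chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Read a sites-only germline VCF
#'
#' Reads a sites-only VCF into a tibble with one record per (site, alt):
#' multi-allelic records are split, each keeping its own AF/AC INFO values.
#' Records failing FILTER are retained with their flag -- filtering is a
#' separate, later step ([apply_variant_filters()]).
#'
#' Expected INFO fields (as written by [write_cohort()]): `AF` (allele
#' frequency), `AC` (allele count), `AC_<continent>` per-continent allele
#' counts, and `AGE` (allele age in generations). Missing fields yield NA
#' columns.
#'
#' @param path VCF file (plain or bgzipped).
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `ac`, `af`, per-continent
#'   `ac_*` columns, `age`, `filter`.
#' @export
read_germline_sites <- function(path) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) {
      abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
    }
  )
  vcf <- VariantAnnotation::expand(vcf) # split multi-allelic records
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  grab_num <- function(field) {
    if (field %in% names(info)) {
      v <- info[[field]]
      if (is.list(v) || methods::is(v, "List")) v <- vapply(v, function(z) if (length(z)) z[[1]] else NA_real_, numeric(1))
      as.numeric(v)
    } else {
      rep(NA_real_, n)
    }
  }
  filt <- as.character(rr$FILTER)
  filt[is.na(filt) | filt == "."] <- "PASS"
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    ac = grab_num("AC"),
    af = grab_num("AF"),
    age = grab_num("AGE"),
    filter = filt
  )
  cont_fields <- grep("^AC_", names(info), value = TRUE)
  for (f in cont_fields) {
    out[[tolower(f)]] <- grab_num(f)
  }
  snv <- nchar(out$ref) == 1 & nchar(out$alt) == 1 &
    out$ref %in% BASES & out$alt %in% BASES
  if (any(!snv)) {
    inform(sprintf("read_germline_sites: dropped %d non-SNV record(s)", sum(!snv)))
    out <- out[snv, , drop = FALSE]
  }
  out
}

#' Write germline calls as a sites-only VCF
#'
#' @param germline Tibble as returned by [read_germline_sites()] (or the
#'   generator); per-continent count columns are any named `ac_*`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_germline_sites <- function(germline, path) {
  cont_cols <- grep("^ac_", names(germline), value = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    sprintf(
      "##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Allele count, %s ancestry\">",
      toupper(cont_cols), sub("^ac_", "", cont_cols)
    ),
    "##INFO=<ID=AGE,Number=1,Type=Float,Description=\"Allele age in generations\">",
    "##FILTER=<ID=RF,Description=\"Failed random forest filter\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(germline) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  g <- dplyr::arrange(germline, .data$chrom, .data$pos, .data$alt)
  info <- sprintf("AC=%d;AF=%.8g", as.integer(g$ac), g$af)
  for (f in cont_cols) {
    info <- paste0(info, ";", toupper(f), "=", as.integer(g[[f]]))
  }
  if ("age" %in% names(g)) {
    info <- paste0(info, ";AGE=", sprintf("%.6g", g$age))
  }
  filt <- if ("filter" %in% names(g)) g$filter else "PASS"
  rows <- paste(g$chrom, g$pos, ".", g$ref, g$alt, ".", filt, info, sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a somatic call set from a MAF-style TSV
#'
#' Requires columns Chromosome, Start_Position, Reference_Allele,
#' Tumor_Seq_Allele2, Tumor_Sample_Barcode, project_code, t_vaf, n_depth,
#' FILTER. Non-SNV rows (multi-base or non-ACGT alleles) are dropped with a
#' reported count. Extra columns (e.g. a truth `origin` column written by
#' the generator) are carried along.
#'
#' @param path TSV file.
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `sample`, `project`,
#'   `vaf`, `n_depth`, `filter`, plus any extra columns.
#' @export
read_somatic_maf <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(MAF_REQUIRED_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "MAF schema error in '%s': missing required column(s) %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  out <- tibble(
    chrom = as.character(raw$Chromosome),
    pos = as.integer(raw$Start_Position),
    ref = as.character(raw$Reference_Allele),
    alt = as.character(raw$Tumor_Seq_Allele2),
    sample = as.character(raw$Tumor_Sample_Barcode),
    project = as.character(raw$project_code),
    vaf = as.numeric(raw$t_vaf),
    n_depth = as.integer(raw$n_depth),
    filter = as.character(raw$FILTER)
  )
  extra <- setdiff(names(raw), MAF_REQUIRED_COLUMNS)
  for (e in extra) out[[e]] <- raw[[e]]
  snv <- nchar(out$ref) == 1 & nchar(out$alt) == 1 &
    out$ref %in% BASES & out$alt %in% BASES
  if (any(!snv)) {
    inform(sprintf("read_somatic_maf: dropped %d non-SNV row(s)", sum(!snv)))
    out <- out[snv, , drop = FALSE]
  }
  out
}

#' Write somatic calls as a MAF-style TSV
#'
#' @param somatic Tibble with the columns produced by [read_somatic_maf()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_somatic_maf <- function(somatic, path) {
  out <- tibble(
    Chromosome = somatic$chrom %||% character(0),
    Start_Position = somatic$pos,
    Reference_Allele = somatic$ref,
    Tumor_Seq_Allele2 = somatic$alt,
    Tumor_Sample_Barcode = somatic$sample,
    project_code = somatic$project,
    t_vaf = somatic$vaf,
    n_depth = somatic$n_depth,
    FILTER = somatic$filter
  )
  extra <- setdiff(
    names(somatic),
    c("chrom", "pos", "ref", "alt", "sample", "project", "vaf", "n_depth", "filter")
  )
  for (e in extra) out[[e]] <- somatic[[e]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED uses 0-based half-open coordinates; the returned tibble uses 1-based
#' inclusive coordinates (the variant convention throughout the package).
#' This conversion is centralized here and in [write_bed()].
#'
#' @param path BED file.
#' @return Tibble: `chrom`, `start`, `end` (1-based, inclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), # rtracklayer converts to 1-based
    end = GenomicRanges::end(gr)
  )
}

#' Write genomic intervals to BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- intervals_to_granges(intervals)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @noRd
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
  )
}

#' @noRd
granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Whitelist specification for the universe of potential SNVs
#'
#' Encodes the site-level filters that define the conservative universe:
#' intersection of target interval sets minus blacklists, autosomes only, a
#' coverage rule (fraction of database samples with >= `coverage_read_threshold`
#' reads must reach `coverage_sample_fraction`), a GC-window rule (sites are
#' excluded when fewer than `gc_min` or more than `gc_max` of the
#' surrounding `gc_window` bases are G or C), and removal of common germline
#' alleles (frequency >= `af_max`).
#'
#' @param target_sets List of interval tibbles (`chrom`, `start`, `end`,
#'   1-based inclusive) to intersect.
#' @param blacklists List of interval tibbles to subtract.
#' @param coverage_track Tibble `chrom`, `pos`, `frac`: per-position
#'   fraction of database samples with >= `coverage_read_threshold` reads.
#'   `NULL` skips the coverage rule.
#' @param coverage_read_threshold Reads defining "covered" (default 20;
#'   descriptive -- the track is assumed to be computed at this threshold).
#' @param coverage_sample_fraction Minimum fraction of samples covered
#'   (default 0.5).
#' @param gc_window Window size in bases for the GC rule (default 100,
#'   taken as 50 bases on each flank, excluding the site itself).
#' @param gc_min,gc_max GC-content bounds (defaults 0.30 and 0.70,
#'   inclusive).
#' @param af_max Germline allele-frequency cutoff: (site, alt) pairs with
#'   frequency >= this are removed (default 0.001).
#' @param af_filter_mode `"allele"` (default) removes only the specific
#'   (site, alt); `"site"` removes all three alts at the site.
#' @param autosomes_only Keep only chromosomes named like autosomes
#'   (`chr1`..`chr22` or bare numbers).
#' @return A list of class `"whitelist_spec"`.
#' @export
whitelist_spec <- function(target_sets = list(),
                           blacklists = list(),
                           coverage_track = NULL,
                           coverage_read_threshold = 20,
                           coverage_sample_fraction = 0.5,
                           gc_window = 100,
                           gc_min = 0.30,
                           gc_max = 0.70,
                           af_max = 0.001,
                           af_filter_mode = c("allele", "site"),
                           autosomes_only = TRUE) {
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1)) {
    abort("need 0 <= gc_min < gc_max <= 1")
  }
  check_scalar_number(af_max, "af_max", 0, 1, open_lower = TRUE, open_upper = TRUE)
  structure(
    list(
      target_sets = target_sets,
      blacklists = blacklists,
      coverage_track = coverage_track,
      coverage_read_threshold = coverage_read_threshold,
      coverage_sample_fraction = coverage_sample_fraction,
      gc_window = gc_window,
      gc_min = gc_min,
      gc_max = gc_max,
      af_max = af_max,
      af_filter_mode = match.arg(af_filter_mode),
      autosomes_only = autosomes_only
    ),
    class = "whitelist_spec"
  )
}

#' @noRd
is_autosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", chrom)
}

#' Build the whitelisted universe of potential SNVs
#'
#' Starts from all sites of the reference, restricts to the intersection of
#' the target sets minus the blacklists (autosomes only), applies the
#' coverage and GC-window rules, and expands each surviving site into its
#' three possible single-base substitutions. Finally, any (site, alt) whose
#' germline allele frequency is `>= spec$af_max` is removed (or the whole
#' site, under `af_filter_mode = "site"`).
#'
#' @param reference Named character vector of chromosome sequences.
#' @param spec A [whitelist_spec()].
#' @param germline Optional germline call tibble (with `af`) used for the
#'   common-allele filter.
#' @return Tibble of potential SNVs: `chrom`, `pos`, `ref`, `alt`,
#'   `gc_win` (GC content of the surrounding window). Attribute
#'   `"filter_stages"` records site counts after each filter stage.
#' @export
build_universe <- function(reference, spec, germline = NULL) {
  stopifnot(inherits(spec, "whitelist_spec"))
  chrom_len <- setNames(nchar(reference), names(reference))
  all_sites <- tibble(
    chrom = names(reference),
    start = 1L, end = as.integer(chrom_len)
  )
  stages <- c(reference = sum(chrom_len))

  gr <- intervals_to_granges(all_sites)
  for (tg in spec$target_sets) {
    gr <- GenomicRanges::intersect(gr, intervals_to_granges(tg))
  }
  stages <- c(stages, targets = sum(GenomicRanges::width(gr)))
  for (bl in spec$blacklists) {
    gr <- GenomicRanges::setdiff(gr, intervals_to_granges(bl))
  }
  stages <- c(stages, blacklists = sum(GenomicRanges::width(gr)))

  iv <- granges_to_intervals(gr)
  if (spec$autosomes_only) {
    iv <- dplyr::filter(iv, is_autosome(.data$chrom))
  }
  stages <- c(stages, autosomes = sum(iv$end - iv$start + 1))

  sites <- tidyr::unchop(
    dplyr::mutate(iv, pos = purrr::map2(.data$start, .data$end, seq)),
    "pos"
  )
  sites <- dplyr::select(sites, "chrom", "pos")
  sites$pos <- as.integer(sites$pos)

  if (!is.null(spec$coverage_track)) {
    cov <- dplyr::select(spec$coverage_track, "chrom", "pos", "frac")
    sites <- dplyr::left_join(sites, cov, by = c("chrom", "pos"))
    sites$frac[is.na(sites$frac)] <- 0
    sites <- dplyr::filter(sites, .data$frac >= spec$coverage_sample_fraction)
    sites$frac <- NULL
  }
  stages <- c(stages, coverage = nrow(sites))

  # GC window rule
  gc <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- sites$chrom == ch
    gc[idx] <- gc_window_content(reference[[ch]], sites$pos[idx], spec$gc_window)
  }
  sites$gc_win <- gc
  sites <- dplyr::filter(
    sites, .data$gc_win >= spec$gc_min, .data$gc_win <= spec$gc_max
  )
  stages <- c(stages, gc_window = nrow(sites))

  if (nrow(sites) == 0) {
    warn("build_universe: no sites survive the whitelist filters; the universe is empty")
  }

  # expand to 3 alternate alleles per site
  seqs <- unname(reference[sites$chrom])
  sites$ref <- substr(seqs, sites$pos, sites$pos)
  sites <- dplyr::filter(sites, .data$ref %in% BASES)
  universe <- expand_alts(sites)
  universe <- dplyr::select(universe, "chrom", "pos", "ref", "alt", "gc_win")
  stages <- c(stages, potential_snvs = nrow(universe))

  if (!is.null(germline) && nrow(universe) > 0) {
    common <- dplyr::filter(germline, .data$af >= spec$af_max)
    if (spec$af_filter_mode == "allele") {
      universe <- dplyr::anti_join(
        universe, common,
        by = c("chrom", "pos", "ref", "alt")
      )
    } else {
      universe <- dplyr::anti_join(universe, common, by = c("chrom", "pos"))
    }
  }
  stages <- c(stages, af_filter = nrow(universe))

  attr(universe, "filter_stages") <- stages
  universe
}

#' Apply the variant-level filters
#'
#' Germline calls keep only FILTER == "PASS"; somatic calls drop any row
#' whose FILTER contains "nonpreferredpair" or "oxog". Retained calls are
#' restricted to the universe when one is supplied. Site-level presence is
#' obtained separately via deduplication (see [count_shared()]); the rows
#' returned here remain per-sample records for sample-level analyses.
#'
#' @param calls Call tibble with a `filter` column.
#' @param setting `"germline"` or `"somatic"`.
#' @param universe Optional universe tibble to restrict to.
#' @return Filtered tibble.
#' @export
apply_variant_filters <- function(calls, setting = c("germline", "somatic"),
                                  universe = NULL) {
  setting <- match.arg(setting)
  out <- if (setting == "germline") {
    dplyr::filter(calls, .data$filter == "PASS")
  } else {
    dplyr::filter(
      calls,
      !grepl("nonpreferredpair|oxog", .data$filter, ignore.case = TRUE)
    )
  }
  if (!is.null(universe)) {
    out <- dplyr::semi_join(
      out, universe,
      by = c("chrom", "pos", "ref", "alt")
    )
  }
  out
}
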