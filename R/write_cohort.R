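#' Write a synthetic cohort to standard formats
#'
#' Writes the reference as FASTA, the germline calls as a sites-only VCF
#' (INFO: AC, AF, per-continent AC, AGE), the somatic calls as a MAF-style
#' TSV (with the truth `origin` column), and the universe's site intervals
#' as BED. The files round-trip losslessly through the package readers.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))
  paths <- c(
    reference = file.path(dir, "reference.fa"),
    germline = file.path(dir, "germline.vcf"),
    somatic = file.path(dir, "somatic.maf"),
    universe = file.path(dir, "universe.bed")
  )
  write_reference_fasta(cohort$reference, paths["reference"])
  write_germline_sites(cohort$germline_calls, paths["germline"])
  somatic <- dplyr::select(cohort$somatic_calls, -dplyr::any_of(
    c("context", "basic_class")
  ))
  write_somatic_maf(somatic, paths["somatic"])
  sites <- dplyr::distinct(cohort$universe, .data$chrom, .data$pos)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = sites$chrom, ranges = IRanges::IRanges(sites$pos, sites$pos)
  ))
  write_bed(granges_to_intervals(gr), paths["universe"])
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing reference.fa, germline.vcf, somatic.maf
#'   and universe.bed.
#' @return List: `reference`, `germline_calls`, `somatic_calls`,
#'   `universe_sites` (interval tibble).
#' @export
read_cohort <- function(dir) {
  list(
    reference = read_reference_fasta(file.path(dir, "reference.fa")),
    germline_calls = read_germline_sites(file.path(dir, "germline.vcf")),
    somatic_calls = read_somatic_maf(file.path(dir, "somatic.maf")),
    universe_sites = read_bed(file.path(dir, "universe.bed"))
  )
}
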