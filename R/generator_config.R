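#' Configuration for the synthetic exome-cohort generator
#'
#' Bundles every tunable of the synthetic cohort generator with validated
#' defaults. The defaults encode the study conditions the analysis targets:
#' transition/transversion and CpG-deamination/transversion rate ratios of
#' 3.4 (somatic) and 3.8 (germline), and 19.8 / 17.2 respectively; overall
#' mutated fractions of the potential-SNV universe near 0.071 (germline) and
#' 0.022 (somatic); and 2.3 leaked germline variants per somatic exome.
#'
#' @param exome_length Total reference length in bases, summed over
#'   chromosomes (default 2e6).
#' @param n_chromosomes Number of chromosomes the exome is split across.
#' @param gc_fraction Target G+C fraction of the reference, in (0,1).
#' @param cpg_enrichment Multiplier (>= 0) on the CpG dinucleotide frequency
#'   relative to the independence expectation; 1 = no enrichment, 0 = CpG-free.
#' @param germline_titv,somatic_titv Rate ratio of the non-CpG transition
#'   class to the transversion class, per setting.
#' @param germline_deam_tv,somatic_deam_tv Rate ratio of the CpG-deamination
#'   class (C>T with 3' G, pyrimidine strand) to the transversion class.
#' @param context_flank Flanking bases defining the context level at which
#'   rate multipliers are drawn (0-3; 1 = trinucleotide).
#' @param context_sd_log Log-scale SD of per-context lognormal rate
#'   multipliers (0 collapses each basic class to a single rate).
#' @param cross_setting_rho Pearson correlation, in (-1,1), of the log rate
#'   multipliers between the germline and somatic settings.
#' @param germline_site_rate,somatic_site_rate Expected mutated fraction of
#'   eligible potential SNVs per setting, in (0,1).
#' @param n_somatic_samples Number of somatic (tumor) samples.
#' @param leakage_per_exome Expected number of germline variants leaked into
#'   each somatic sample (>= 0).
#' @param depth_gc_slope Log-linear effect of GC window content (centred at
#'   0.5) on matched-normal read depth; negative means GC-rich sites are
#'   sequenced shallower.
#' @param depth_mean Mean matched-normal read depth at GC 0.5.
#' @param depth_dispersion Negative-binomial size parameter of read depth.
#' @param n_continents Number of continental ancestries (1-6).
#' @param af_shape Exponent of the power-law allele-count spectrum
#'   (P(AC = k) proportional to k^-af_shape); 1 approximates a neutral site
#'   frequency spectrum.
#' @param seed Master seed; all stages draw from substreams derived from it.
#' @param n_individuals Germline database size (diploid individuals) used as
#'   the allele-frequency denominator. Allele counts are truncated so every
#'   simulated frequency stays below 0.001, mirroring the common-variant
#'   filter of the analysis.
#' @param p_denovo Probability that a germline variant is de novo (allele
#'   age <= 1 generation).
#' @param age_meanlog,age_sdlog Lognormal parameters (generations) of
#'   inherited allele ages.
#' @param age_rate_bias Strength of the mutation-prone-sites-are-younger
#'   mechanism: log-age decreases by this amount per SD of log context rate.
#'   0 disables the age/context link.
#' @param age_gc_bias Increase of mean log age for G/C alternate alleles,
#'   emulating GC-biased gene conversion favouring the retention of old G/C
#'   alleles. 0 disables.
#' @param cancer_types Character vector of cancer-type (project) labels;
#'   samples are assigned types round-robin.
#' @param cancer_deam_weight Numeric vector (same length as `cancer_types`):
#'   relative propensity of each type's samples to receive CpG-deamination
#'   variants, emulating differential endogenous mutational signature
#'   activity across cancer types.
#' @param germline_fail_rate Fraction of germline records assigned a
#'   non-PASS filter flag.
#' @param somatic_artifact_rate Fraction of somatic records assigned an
#'   artifact filter flag ("oxog" or "nonpreferredpair").
#' @param leak_depth_midpoint,leak_depth_scale Logistic parameters of the
#'   leakage-vs-depth curve: the probability that a germline variant escapes
#'   matched-normal subtraction falls logistically with depth and is 0 at
#'   depth >= 200.
#'
#' @return A list of class `"generator_config"`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- generator_config(exome_length = 5e4, seed = 7)
#' cfg$germline_titv
generator_config <- function(exome_length = 2e6,
                             n_chromosomes = 4,
                             gc_fraction = 0.45,
                             cpg_enrichment = 1,
                             germline_titv = 3.8,
                             somatic_titv = 3.4,
                             germline_deam_tv = 17.2,
                             somatic_deam_tv = 19.8,
                             context_flank = 1,
                             context_sd_log = 0.25,
                             cross_setting_rho = 0.7,
                             germline_site_rate = 0.071,
                             somatic_site_rate = 0.022,
                             n_somatic_samples = 50,
                             leakage_per_exome = 2.3,
                             depth_gc_slope = -3,
                             depth_mean = 110,
                             depth_dispersion = 4,
                             n_continents = 5,
                             af_shape = 1,
                             seed = 1,
                             n_individuals = 125000,
                             p_denovo = 0.02,
                             age_meanlog = log(1000),
                             age_sdlog = 1.5,
                             age_rate_bias = 0.5,
                             age_gc_bias = 0.3,
                             cancer_types = c("CT1", "CT2"),
                             cancer_deam_weight = c(1, 1),
                             germline_fail_rate = 0.02,
                             somatic_artifact_rate = 0.01,
                             leak_depth_midpoint = 40,
                             leak_depth_scale = 8) {
  check_scalar_number(exome_length, "exome_length", lower = 1)
  check_scalar_number(n_chromosomes, "n_chromosomes", lower = 1)
  check_scalar_number(gc_fraction, "gc_fraction", 0, 1,
    open_lower = TRUE, open_upper = TRUE
  )
  check_scalar_number(cpg_enrichment, "cpg_enrichment", lower = 0)
  for (r in c(
    germline_titv = germline_titv, somatic_titv = somatic_titv,
    germline_deam_tv = germline_deam_tv, somatic_deam_tv = somatic_deam_tv
  )) {
    if (!is.numeric(r) || r <= 0) abort("rate ratios must be > 0")
  }
  check_scalar_number(context_flank, "context_flank", 0, 3)
  check_scalar_number(context_sd_log, "context_sd_log", lower = 0)
  check_scalar_number(cross_setting_rho, "cross_setting_rho", -1, 1,
    open_lower = TRUE, open_upper = TRUE
  )
  check_scalar_number(germline_site_rate, "germline_site_rate", 0, 1,
    open_lower = TRUE, open_upper = TRUE
  )
  check_scalar_number(somatic_site_rate, "somatic_site_rate", 0, 1,
    open_lower = TRUE, open_upper = TRUE
  )
  check_scalar_number(n_somatic_samples, "n_somatic_samples", lower = 1)
  check_scalar_number(leakage_per_exome, "leakage_per_exome", lower = 0)
  check_scalar_number(depth_mean, "depth_mean", lower = 1)
  check_scalar_number(depth_dispersion, "depth_dispersion", lower = 0.01)
  check_scalar_number(n_continents, "n_continents", 1, length(CONTINENT_CODES))
  check_scalar_number(af_shape, "af_shape", lower = 0)
  check_scalar_number(p_denovo, "p_denovo", 0, 1)
  if (exome_length < 2 * context_flank + 1) {
    abort("invalid config: exome_length must be >= 2 * context_flank + 1")
  }
  if (length(cancer_deam_weight) != length(cancer_types)) {
    abort("`cancer_deam_weight` must match `cancer_types` in length")
  }
  if (any(cancer_deam_weight < 0)) abort("`cancer_deam_weight` must be >= 0")

  structure(
    list(
      exome_length = as.integer(exome_length),
      n_chromosomes = as.integer(n_chromosomes),
      gc_fraction = gc_fraction,
      cpg_enrichment = cpg_enrichment,
      germline_titv = germline_titv,
      somatic_titv = somatic_titv,
      germline_deam_tv = germline_deam_tv,
      somatic_deam_tv = somatic_deam_tv,
      context_flank = as.integer(context_flank),
      context_sd_log = context_sd_log,
      cross_setting_rho = cross_setting_rho,
      germline_site_rate = germline_site_rate,
      somatic_site_rate = somatic_site_rate,
      n_somatic_samples = as.integer(n_somatic_samples),
      leakage_per_exome = leakage_per_exome,
      depth_gc_slope = depth_gc_slope,
      depth_mean = depth_mean,
      depth_dispersion = depth_dispersion,
      n_continents = as.integer(n_continents),
      af_shape = af_shape,
      seed = as.integer(seed),
      n_individuals = as.integer(n_individuals),
      p_denovo = p_denovo,
      age_meanlog = age_meanlog,
      age_sdlog = age_sdlog,
      age_rate_bias = age_rate_bias,
      age_gc_bias = age_gc_bias,
      cancer_types = cancer_types,
      cancer_deam_weight = cancer_deam_weight,
      germline_fail_rate = germline_fail_rate,
      somatic_artifact_rate = somatic_artifact_rate,
      leak_depth_midpoint = leak_depth_midpoint,
      leak_depth_scale = leak_depth_scale
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf(
    "  exome: %s bases on %d chromosome(s), GC %.2f, CpG enrichment %.2f\n",
    format(x$exome_length, big.mark = ","), x$n_chromosomes,
    x$gc_fraction, x$cpg_enrichment
  ))
  cat(sprintf(
    "  rates: germline %.3g / somatic %.3g of universe; ti/tv %.1f / %.1f; deam/tv %.1f / %.1f\n",
    x$germline_site_rate, x$somatic_site_rate,
    x$germline_titv, x$somatic_titv, x$germline_deam_tv, x$somatic_deam_tv
  ))
  cat(sprintf(
    "  contexts: flank %d, sd(log) %.2f, cross-setting rho %.2f\n",
    x$context_flank, x$context_sd_log, x$cross_setting_rho
  ))
  cat(sprintf(
    "  cohort: %d somatic samples, %.2f leaked germline variants/exome, seed %d\n",
    x$n_somatic_samples, x$leakage_per_exome, x$seed
  ))
  invisible(x)
}
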