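---
title: "Methods: quantifying and explaining germline–somatic variant sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and explaining germline–somatic variant sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedvar)
library(dplyr)
```

## The problem

Large public databases of human single-nucleotide variants exist for two
mutational settings: the germline (population exome databases) and the soma
(cancer exome call sets). Many variants — identical chromosome, position,
reference and alternate allele — appear in both. `sharedvar` implements a
statistical framework for asking *why*: how much sharing is expected from
chance alone, how much from the fact that DNA has the same chemical
vulnerabilities in both settings, and how much might be an artifact such as
germline variants leaking through the matched-normal subtraction used in
somatic calling.

The unit of analysis is the **potential SNV**: one of the three possible
single-base substitutions at a whitelisted exomic site. Over a universe of
`n` potential SNVs, with `g` unique germline-mutated and `s` unique
somatic-mutated site-alleles and `b` shared ones, the framework compares
`b` against model-based expectations.

## The statistics

**Forbes coefficient.** Under statistical independence of the two settings
the expected shared count is

    e | independence = (g / n) * (s / n) * n = g * s / n

and the Forbes coefficient of association is `F = b / e`. `F = 1` means
sharing is fully explained by chance; `F > 1` means co-occurring hotspots.

**Partition-conditioned Forbes coefficient.** Mutation rates differ
enormously by substitution class: spontaneous deamination of methylated CpG
(C>T with a 3' G on the pyrimidine strand), other transitions, and
transversions. To credit a model that knows about such classes, the
universe is partitioned into cells `i = 1..m` with per-cell counts
`(n_i, g_i, s_i)` and

    P(v) = b / sum_i e_i,   e_i = (g_i / n_i) * (s_i / n_i) * n_i.

Successively finer partitions — basic class, trinucleotide, pentanucleotide,
heptanucleotide context (all collapsed onto the pyrimidine strand) — give a
decomposition of the shared count into explained fractions `sum e_i / b`,
with the incremental column showing what each refinement adds
(`forbes_decomposition()`, `render_table2()`).

Expected counts are kept real-valued internally and rounded to integers
only in the rendering layer; both conventions reproduce published
three-decimal coefficients at the printed precision.

**Context rates and their cross-setting correlation.** `context_rates()`
estimates per-context rates as unique mutated site-alleles over context
size; `cross_setting_correlation()` rank-correlates the germline and
somatic rate vectors. "Controlling for the central k bases" is implemented
as a *stratified* rank correlation: within every stratum (contexts sharing
a central sub-context) ranks are computed separately per setting, centred
and scaled, and pooled before correlating. The statistic is then invariant
to any monotone per-stratum transform, which is exactly the sense in which
the central context is "controlled for". A weighted
average-of-per-stratum-Spearman mode (`mode = "average"`) is provided for
sensitivity, since a partial-correlation reading of "controlling for" is
also defensible; stratification is the default because it makes no
linearity assumption.

**Germline leakage.** Somatic call sets are produced by subtracting a
matched normal; when the normal is sequenced shallowly at a site, a true
germline variant can survive subtraction and appear "somatic" — and such a
variant is almost surely shared with the germline database. The estimator
(`estimate_leakage()`) takes the baseline shared rate from calls with
matched-normal depth ≥ 200, accumulates per-depth excess shared calls for
depths < 98, ignores the [98, 200) dead zone entirely (the asymmetry is
deliberate and is preserved, not smoothed), and divides by the number of
exomes. Negative per-depth excesses are retained so the estimator is
centred at zero under no leakage (a floored variant exists behind
`floor_negative`).

One algebraic subtlety: every leaked call adds 1 to the shared count *and*
1 to the somatic denominator at its depth, so the raw excess recovers only
`(1 − baseline_rate)` of the true leaked count. `per_exome` reports the raw
subtraction; `per_exome_corrected` divides the attenuation out and is the
recommended point estimate (at a baseline shared rate of ~0.2 the raw
estimate is ~20% low by construction). Both are reported.

The leakage signal is confounded: GC-extreme regions sequence shallowly,
and CpG-dense (deamination-prone, hence highly shared) contexts live in
GC-rich regions, so low-depth strata are enriched for highly shared
contexts even without leakage. `context_confound_by_depth()` quantifies
this by predicting each depth bin's shared rate from its context
composition alone; `depth_by_gc()` shows the GC–depth relationship.

**Characterizations.** `trinucleotide_matched_downsample()` equalizes the
trinucleotide distributions of variant categories exactly (per-trimer
minimum across categories, deterministic under a seed and invariant to
category order), enabling fair comparisons such as synonymous versus
context-matched nonsynonymous sharing. `shared_rate_by_allele_age()` bins
germline variants by allele age with a two-sample proportion test
(`prop.test`, the standard chi-square two-proportion test) across the
500-generation threshold. `shared_rate_by_continent_count()` stratifies
ultra-rare variants (total allele count ≤ 5 by default; the cutoff is a
parameter because no canonical definition exists) by the number of
continents carrying the allele. `ancestry_cross_table()` crosses
single-ancestry germline variants with somatic donor ancestry, and
`vaf_comparison()` contrasts the tumor variant-allele-frequency
distributions of shared versus database-unique somatic calls (leaked
heterozygous germline variants cluster near VAF 0.5).

## The whitelist

`build_universe()` constructs the conservative universe: intersection of
the target interval sets minus blacklists, autosomes only, a coverage rule
(≥ 20 reads in ≥ 50% of database samples, consumed as a precomputed
per-position fraction track), and a GC-window rule excluding sites whose
surrounding 100 bases are < 30% or > 70% G+C. The window is read as 50
bases on each flank, excluding the site itself — the exact placement is a
package choice since no standard one exists. Each surviving site
contributes exactly three potential SNVs; site-alleles with germline allele
frequency ≥ 0.001 are then removed. The frequency filter removes the
specific allele by default (`af_filter_mode = "allele"`); removing the
whole site is available because the published rule can be read either way.
Coordinates are 1-based inclusive for variants and converted to/from
0-based half-open BED in exactly one place (`read_bed()` / `write_bed()`).

## The synthetic cohort generator

No public data ships with the package; every analysis is exercised on
synthetic cohorts whose *defaults encode the study conditions*:

* class rate ratios: other-transition/transversion 3.8 (germline) and 3.4
  (somatic); CpG-deamination/transversion 17.2 and 19.8. The transition
  parameter governs the non-CpG transition class; whether published ti/tv
  ratios include CpG transitions is ambiguous, and tying each parameter to
  one class keeps the generator and the estimator self-consistent.
* overall mutated fractions of the universe: 0.071 (germline) and 0.022
  (somatic), the ratios of the published unique-variant counts to the
  universe size;
* 2.3 leaked germline variants per somatic exome;
* per-context lognormal rate multipliers (SD 0.25 on the log scale) with
  cross-setting correlation 0.7, roughly matching the observed heptamer
  rank correlation of ~0.6.

The reference is a first-order Markov chain over bases whose only
dependence is the C→G transition probability, giving direct control of CpG
dinucleotide frequency; the base distribution is calibrated by
root-finding so the chain's stationary G+C content equals `gc_fraction`
exactly. Real exomes have isochores, repeats and selection; this reference
has none of them, so passing tests demonstrate correctness of the
estimators on their own assumptions, not real-data performance.

Germline presence is composed of independent per-continent origination
events with per-continent probability `1 − (1 − rate)^(1/K)`, so the
marginal presence probability equals the context rate while mutation-prone
contexts recur on more continents — the mechanism behind the
continent-count analysis. Allele counts follow a power-law spectrum
truncated so every allele frequency stays below 0.001 (the generator never
emits variants the whitelist would remove). Allele ages mix a de novo
point mass at 1 generation with a lognormal; mutation-prone contexts can
skew younger (`age_rate_bias`) and G/C alternate alleles older
(`age_gc_bias`, a nod to GC-biased gene conversion).

Somatic calls get a sample, cancer type, Beta(2,3) VAF, and a negative
binomial matched-normal depth whose log-mean is linear in GC window
content (`depth_gc_slope`; negative reproduces the GC-poor-coverage
confounder). CpG-deamination variants are assigned preferentially to
samples of cancer types with high `cancer_deam_weight`, emulating
endogenous-signature-driven cancer types. Leakage draws
Poisson(`leakage_per_exome`) germline variants per sample — from the
variants carried by the sample's own continental ancestry — with depth
drawn from the baseline depth distribution tilted by a logistic falling in
depth (midpoint 40, scale 8, hard zero from depth 200): the logistic
shapes *where* leaks appear, the Poisson calibration fixes *how many*, and
the support below the estimator's 98-read cutoff keeps recovery
well-posed.

Randomness uses one master seed with fixed per-stage substreams
(reference, rates, germline, somatic, leakage), so cohorts are bit-for-bit
reproducible and stages can be varied independently.

## Numerical and experimental choices

* Expected counts, rates and excesses are doubles throughout; only report
  rendering rounds.
* Ties in rate ranks get average ranks; degenerate strata (all ties)
  contribute zero residual signal by definition.
* Zero-size contexts are excluded, never imputed.
* Bootstrap confidence intervals for Forbes coefficients are deliberately
  not computed by default; the statistics are ratios of large counts and
  the package's focus is the point decomposition.
* Leakage recovery experiments (test suite and the acceptance script's
  companions) simulate with `depth_gc_slope = 0` and
  `depth_mean = 200, depth_dispersion = 10`. The first isolates the
  estimator from the GC confounder, which has its own diagnostic; the
  second puts roughly half the calls in the baseline stratum so that
  baseline sampling error does not dominate the per-exome signal at
  test-scale cohorts (at the default depth profile only ~6% of calls
  define the baseline). These choices affect experimental power only, not
  the estimand.
* Problem sizes: most tests run on cohorts of 3e4–2e5 reference bases
  (~1e5–6e5 potential SNVs); ratio-recovery checks use one 2e6-base cohort
  (~6e6 potential SNVs), and the acceptance script averages 20 cohorts of
  7e5 bases (~2.1e6 potential SNVs each). These sizes give Monte-Carlo
  errors comfortably inside the tolerances being checked.

## Worked example

The statistics layer reproduces the published gnomAD/TCGA totals exactly:

```{r worked-example}
f <- forbes(b = 336987, g = 5225731, s = 1629311, n = 73517652)
f
glance(f)
```

## A small end-to-end run

```{r pipeline, message = FALSE}
cfg <- run_config(
  generator = generator_config(
    exome_length = 4e4, n_somatic_samples = 8, seed = 19
  ),
  levels = c("unpartitioned", "basic_class", "trimer"),
  out_dir = tempfile("run_")
)
res <- run_pipeline(cfg)
res$decomposition
```

## Known limitations

* The generator's reference has homogeneous composition: GC window content
  varies only by sampling noise, so the GC/CpG–depth confounder is present
  but weaker than in a real exome.
* One germline database is simulated at the site level; there are no
  individual genomes, no linkage, and no population structure beyond
  independent continental origination.
* Selection, mutational signatures beyond the deamination weighting, and
  strand asymmetries are not modeled; the synonymous/nonsynonymous
  comparison is exercised with neutral labels only.
* The raw leakage estimate inherits the attenuation described above; use
  `per_exome_corrected` for an unbiased reading on the generator's own
  mechanism.
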