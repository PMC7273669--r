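# sharedvar

Many single-nucleotide variants are listed in *both* large germline exome
databases and somatic (cancer) exome call sets — same chromosome, position,
reference and alternate allele. `sharedvar` is an R package for
quantifying and explaining that overlap. It is aimed at genomicists who
work with paired germline/somatic call sets and want to know how much
sharing is chance, how much is shared chemistry of DNA mutation, and how
much could be contamination of somatic call sets by germline variants.

## The statistics

Over a whitelisted universe of `n` potential SNVs (three possible
substitutions at every eligible site), with `g` unique germline-mutated
site-alleles, `s` somatic-mutated ones and `b` shared:

* expected sharing under independence: `e = (g/n)(s/n)n = gs/n`;
* **Forbes coefficient** `F = b/e` — the fold-enrichment of observed
  sharing over chance;
* **partition-conditioned Forbes coefficient**: for a partition of the
  universe into cells `i = 1..m` (basic substitution class, trinucleotide,
  pentanucleotide, heptanucleotide contexts, pyrimidine-collapsed),
  `P(v) = b / Σᵢ eᵢ` with `eᵢ = (gᵢ/nᵢ)(sᵢ/nᵢ)nᵢ`, so each context carries
  its own rates and `Σᵢ eᵢ / b` is the fraction of sharing the context
  model explains.

Around the core statistics the package provides: whitelist construction
(target/blacklist intervals, coverage and GC-window rules, allele-frequency
cutoff), per-context mutation-rate estimation with cross-setting rank
correlations (including "controlling for the central bases" via stratified
ranking), a matched-normal read-depth estimator of germline leakage with
its GC/CpG confounder diagnostics, context-matched downsampling, and
allele-age / continent-count / ancestry / VAF characterizations. A
synthetic exome-cohort generator with configurable context-dependent rates
makes the entire pipeline testable without any data download.

## Worked example

The statistics layer reproduces the published gnomAD/TCGA comparison from
its four totals:

```r
library(sharedvar)
f <- forbes(b = 336987, g = 5225731, s = 1629311, n = 73517652)
f
#> <forbes_result>  m = 1 partition(s)
#>   b = 336,987 observed shared; expected = 115813.6
#>   coefficient = 2.910; explained fraction = 34.4%
```

Observed sharing is 2.9-fold the independence expectation of ~115,814;
chance alone explains 34.4% of shared variants. Conditioning on the
published per-class expected counts gives the successively finer story:

```r
round(336987 / 294619, 3)  # basic substitution classes
#> [1] 1.144
round(336987 / 307393, 3)  # heptanucleotide contexts
#> [1] 1.096
```

i.e. 87.4% of sharing is explained once deamination/transition/transversion
rates are modeled, 91.2% with full heptamer contexts.

A self-contained synthetic run:

```r
cfg <- run_config(
  generator = generator_config(exome_length = 4e4, n_somatic_samples = 8, seed = 19),
  levels = c("unpartitioned", "basic_class", "trimer"),
  out_dir = tempfile("run_")
)
res <- run_pipeline(cfg)
res$decomposition
#> # A tibble: 3 × 6
#>   level             m expected coefficient explained_fraction incremental
#>   <chr>         <int>    <dbl>       <dbl>              <dbl>       <dbl>
#> 1 unpartitioned     1     184.        2.57              0.389     0.389
#> 2 basic_class       3     460.        1.03              0.970     0.582
#> 3 trimer           96     462.        1.03              0.975     0.00456
```

The synthetic cohort is generated with correlated germline/somatic context
rates, so the decomposition mirrors the real-data pattern: a large jump in
explained fraction from the basic mutation classes, a marginal gain from
finer context. `run_pipeline()` also writes per-sample and per-cancer-type
Forbes tables, rate-correlation tables, the leakage estimate and the
characterization TSVs to `out_dir`.

## Documentation

The methods vignette (`vignettes/shared-variant-methods.Rmd`) describes the
model, the estimators, the generator's distributional choices and their
limitations; every exported function carries roxygen documentation.
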