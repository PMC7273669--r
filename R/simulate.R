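# Synthetic cohort generator: context-dependent rate assignment and
# simulation of germline and somatic call sets with depth-dependent
# germline leakage.

# Allele-frequency truncation of the simulated germline database: the
# generator only emits rare variants, mirroring the removal of common
# polymorphisms (AF >= 0.001) from the analysis universe.
GEN_AF_MAX <- 0.001

#' @noRd
generator_level_column <- function(config) {
  c("trimer", "trimer", "pentamer", "heptamer")[config$context_flank + 1L]
}

# Universe of all potential SNVs of a synthetic reference: every site with
# full flanks at the annotation level, three alts each, annotated with
# contexts and GC window content.
#' @noRd
generator_universe <- function(config, reference) {
  flank <- max(config$context_flank, 1L)
  sites <- purrr::map_dfr(names(reference), function(ch) {
    L <- nchar(reference[[ch]])
    if (L < 2 * flank + 1) {
      return(tibble(chrom = character(0), pos = integer(0)))
    }
    tibble(chrom = ch, pos = seq.int(flank + 1L, L - flank))
  })
  gc <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- sites$chrom == ch
    gc[idx] <- gc_window_content(reference[[ch]], sites$pos[idx], 100)
  }
  sites$gc_win <- gc
  sites$ref <- unname(substr(reference[sites$chrom], sites$pos, sites$pos))
  universe <- expand_alts(sites)
  universe <- annotate_universe(universe, reference, flank = flank)
  if (config$context_flank == 0L) {
    # flank-0 rate units: substitution type, with CpG deaminations split out
    universe$gen_context <- paste0(
      context_central(universe$trimer, 0),
      ifelse(universe$basic_class == "deamination", "@CpG", "")
    )
  } else {
    universe$gen_context <- universe[[generator_level_column(config)]]
  }
  universe
}

#' Assign per-context mutation rates for both settings
#'
#' Every collapsed context at the configured flank level receives a
#' germline and a somatic rate: the base rate of its basic substitution
#' class (transversion 1, other transition `*_titv`, CpG deamination
#' `*_deam_tv`) times a lognormal context multiplier. The log multipliers
#' of the two settings are drawn from a bivariate normal with SD
#' `context_sd_log` and Pearson correlation `cross_setting_rho`. Rates are
#' then renormalized so the expected mutated fraction of the universe
#' equals `germline_site_rate` / `somatic_site_rate`.
#'
#' @param config A [generator_config()].
#' @param universe Annotated universe (internal generator form or any tibble
#'   with `basic_class` and the context column for the configured flank).
#' @return Tibble: `context`, `basic_class`, `n`, `germline_rate`,
#'   `somatic_rate`, `germline_log_mult`, `somatic_log_mult`.
#' @export
assign_context_rates <- function(config, universe) {
  stopifnot(inherits(config, "generator_config"))
  ctx_col <- if ("gen_context" %in% names(universe)) {
    "gen_context"
  } else {
    generator_level_column(config)
  }
  if (!ctx_col %in% names(universe) || !"basic_class" %in% names(universe)) {
    abort("universe must be annotated with contexts first (see annotate_universe)")
  }
  tab <- dplyr::count(
    universe,
    context = .data[[ctx_col]], basic_class = .data$basic_class
  )

  class_weight <- function(titv, deam_tv) {
    c(deamination = deam_tv, other_transition = titv, transversion = 1)
  }
  wg <- class_weight(config$germline_titv, config$germline_deam_tv)
  ws <- class_weight(config$somatic_titv, config$somatic_deam_tv)

  with_substream(config$seed, stage = 2L, {
    m <- nrow(tab)
    a <- rnorm(m)
    b <- rnorm(m)
    rho <- config$cross_setting_rho
    sd <- config$context_sd_log
    tab$germline_log_mult <- sd * a
    tab$somatic_log_mult <- sd * (rho * a + sqrt(1 - rho^2) * b)
  })

  cls <- as.character(tab$basic_class)
  raw_g <- unname(wg[cls]) * exp(tab$germline_log_mult)
  raw_s <- unname(ws[cls]) * exp(tab$somatic_log_mult)
  n_tot <- sum(tab$n)
  lam_g <- config$germline_site_rate * n_tot / sum(tab$n * raw_g)
  lam_s <- config$somatic_site_rate * n_tot / sum(tab$n * raw_s)
  tab$germline_rate <- pmin(lam_g * raw_g, 0.9999)
  tab$somatic_rate <- pmin(lam_s * raw_s, 0.9999)
  dplyr::select(
    tab, "context", "basic_class", "n",
    "germline_rate", "somatic_rate", "germline_log_mult", "somatic_log_mult"
  )
}

#' Simulate germline and somatic call sets over a synthetic reference
#'
#' Each potential SNV mutates independently in each setting with its
#' context rate. Germline presence is composed of independent per-continent
#' origination events (so mutation-prone contexts recur on more
#' continents), allele counts follow a truncated power-law spectrum
#' (frequencies stay below 0.001), and allele ages mix de novo variants
#' with a lognormal inherited-age distribution that can shift
#' mutation-prone contexts toward younger ages. Somatic calls receive a
#' sample, cancer type, VAF and a matched-normal read depth whose mean
#' depends on GC window content; germline variants additionally leak into
#' somatic samples with a probability that falls logistically with
#' matched-normal depth (zero from depth 200 up), calibrated so each sample
#' receives `leakage_per_exome` leaked variants in expectation.
#'
#' @param config A [generator_config()].
#' @param reference Reference from [generate_reference()].
#' @param rates Rate table from [assign_context_rates()].
#' @param universe Annotated generator universe; if `NULL` it is rebuilt
#'   from the reference.
#' @return A list of class `"synthetic_cohort"`: `reference`, `universe`,
#'   `germline_calls`, `somatic_calls`, `samples`, `rates`, `config`.
#' @export
simulate_callsets <- function(config, reference, rates, universe = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(universe)) universe <- generator_universe(config, reference)
  u <- dplyr::left_join(
    universe,
    dplyr::select(
      rates, "context", "germline_rate", "somatic_rate"
    ),
    by = c(gen_context = "context")
  )

  samples <- tibble(
    sample = sprintf("SAMP%04d", seq_len(config$n_somatic_samples)),
    project = rep_len(config$cancer_types, config$n_somatic_samples),
    deam_weight = rep_len(config$cancer_deam_weight, config$n_somatic_samples)
  )

  germline_calls <- with_substream(config$seed, stage = 3L, {
    simulate_germline(config, u)
  })
  somatic_true <- with_substream(config$seed, stage = 4L, {
    samples$ancestry <- sample(
      CONTINENT_CODES[seq_len(config$n_continents)],
      config$n_somatic_samples,
      replace = TRUE
    )
    simulate_somatic(config, u, samples)
  })
  leaked <- with_substream(config$seed, stage = 5L, {
    simulate_leakage(config, u, germline_calls, samples)
  })

  somatic_calls <- dplyr::bind_rows(somatic_true, leaked)
  # a sample can acquire the same variant both somatically and by leakage;
  # keep the somatic record
  somatic_calls <- dplyr::distinct(
    dplyr::arrange(somatic_calls, dplyr::desc(.data$origin)),
    .data$sample, .data$chrom, .data$pos, .data$ref, .data$alt,
    .keep_all = TRUE
  )
  somatic_calls <- dplyr::arrange(
    somatic_calls, .data$chrom, .data$pos, .data$alt, .data$sample
  )

  structure(
    list(
      reference = reference,
      universe = universe,
      germline_calls = germline_calls,
      somatic_calls = somatic_calls,
      samples = dplyr::select(samples, -"deam_weight"),
      rates = rates,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @noRd
simulate_germline <- function(config, u) {
  n <- nrow(u)
  K <- config$n_continents
  rate <- u$germline_rate
  present <- runif(n) < rate
  g <- u[present, , drop = FALSE]
  ng <- nrow(g)
  if (ng == 0) {
    return(empty_germline(K))
  }

  # number of continents carrying the allele: Binomial(K, q) conditioned on
  # >= 1, with q chosen so the marginal presence probability is the rate
  q <- 1 - (1 - g$germline_rate)^(1 / K)
  probs <- vapply(seq_len(K), function(j) {
    choose(K, j) * q^j * (1 - q)^(K - j)
  }, numeric(ng))
  probs <- matrix(probs, nrow = ng)
  probs <- probs / rowSums(probs)
  cum <- probs
  if (K > 1) {
    for (j in 2:K) cum[, j] <- cum[, j - 1] + probs[, j]
  }
  uu <- runif(ng)
  m <- 1L + rowSums(uu > cum[, -K, drop = FALSE])

  conts <- CONTINENT_CODES[seq_len(K)]
  ac_cap <- max(1L, floor(2 * config$n_individuals * GEN_AF_MAX / K) - 1L)
  pw <- (seq_len(ac_cap))^(-config$af_shape)
  ac_mat <- matrix(0L, nrow = ng, ncol = K, dimnames = list(NULL, conts))
  # choose which continents and their allele counts
  single <- m == 1L
  if (any(single)) {
    js <- sample.int(K, sum(single), replace = TRUE)
    ac_mat[cbind(which(single), js)] <-
      sample.int(ac_cap, sum(single), replace = TRUE, prob = pw)
  }
  multi <- which(m > 1L)
  for (i in multi) {
    js <- sample.int(K, m[i])
    ac_mat[i, js] <- sample.int(ac_cap, m[i], replace = TRUE, prob = pw)
  }
  ac <- as.integer(rowSums(ac_mat))
  af <- ac / (2 * config$n_individuals)

  # allele ages: de novo point mass plus lognormal inherited ages;
  # mutation-prone contexts (high germline rate) skew younger, G/C alts
  # skew older (GC-biased gene conversion)
  lr <- log(g$germline_rate)
  z <- if (stats::sd(lr) > 0) (lr - mean(lr)) / stats::sd(lr) else rep(0, ng)
  meanlog <- config$age_meanlog - config$age_rate_bias * z +
    config$age_gc_bias * (g$alt %in% c("G", "C"))
  age <- exp(rnorm(ng, meanlog, config$age_sdlog))
  denovo <- runif(ng) < config$p_denovo
  age[denovo] <- 1
  age <- pmax(age, 1)

  filt <- ifelse(runif(ng) < config$germline_fail_rate, "RF", "PASS")

  out <- tibble(
    chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
    context = g$gen_context, basic_class = g$basic_class,
    ac = ac, af = af, age = age, filter = filt
  )
  for (j in seq_len(K)) {
    out[[paste0("ac_", tolower(conts[j]))]] <- ac_mat[, j]
  }
  out
}

#' @noRd
empty_germline <- function(K) {
  out <- tibble(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), context = character(0),
    basic_class = factor(character(0), levels = BASIC_CLASSES),
    ac = integer(0), af = numeric(0), age = numeric(0), filter = character(0)
  )
  for (j in seq_len(K)) {
    out[[paste0("ac_", tolower(CONTINENT_CODES[j]))]] <- integer(0)
  }
  out
}

#' @noRd
simulate_somatic <- function(config, u, samples) {
  n <- nrow(u)
  present <- runif(n) < u$somatic_rate
  s <- u[present, , drop = FALSE]
  ns <- nrow(s)
  if (ns == 0) {
    return(empty_somatic())
  }

  # assign each unique somatic variant to one sample; CpG-deamination
  # variants favour samples of cancer types with high deamination weight
  is_deam <- s$basic_class == "deamination"
  idx <- integer(ns)
  nsamp <- nrow(samples)
  if (any(!is_deam)) {
    idx[!is_deam] <- sample.int(nsamp, sum(!is_deam), replace = TRUE)
  }
  if (any(is_deam)) {
    w <- samples$deam_weight
    idx[is_deam] <- sample.int(nsamp, sum(is_deam),
      replace = TRUE,
      prob = if (sum(w) > 0) w else NULL
    )
  }

  mu <- config$depth_mean * exp(config$depth_gc_slope * (s$gc_win - 0.5))
  depth <- rnbinom(ns, mu = mu, size = config$depth_dispersion)
  filt <- rep("PASS", ns)
  art <- runif(ns) < config$somatic_artifact_rate
  filt[art] <- sample(c("oxog", "nonpreferredpair"), sum(art), replace = TRUE)

  tibble(
    chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
    context = s$gen_context, basic_class = s$basic_class,
    sample = samples$sample[idx],
    project = samples$project[idx],
    ancestry = samples$ancestry[idx],
    vaf = rbeta(ns, 2, 3),
    n_depth = as.integer(depth),
    filter = filt,
    origin = "somatic"
  )
}

#' @noRd
empty_somatic <- function() {
  tibble(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), context = character(0),
    basic_class = factor(character(0), levels = BASIC_CLASSES),
    sample = character(0), project = character(0), ancestry = character(0),
    vaf = numeric(0), n_depth = integer(0), filter = character(0),
    origin = character(0)
  )
}

# Germline variants leak into somatic samples. The per-call leak propensity
# falls logistically with matched-normal depth and is zero at depth >= 200;
# the number of leaked calls per sample is Poisson(leakage_per_exome), so
# the depth curve shapes *where* leaks happen while the calibration fixes
# *how many*. Leaked variants are drawn from the germline variants carried
# by the sample's own continental ancestry.
#' @noRd
simulate_leakage <- function(config, u, germline_calls, samples) {
  if (config$leakage_per_exome <= 0 || nrow(germline_calls) == 0) {
    return(empty_somatic())
  }
  n_leak <- rpois(nrow(samples), config$leakage_per_exome)
  total <- sum(n_leak)
  if (total == 0) {
    return(empty_somatic())
  }

  g <- dplyr::left_join(
    germline_calls,
    dplyr::distinct(u, .data$chrom, .data$pos, .data$gc_win),
    by = c("chrom", "pos")
  )
  rows <- vector("list", nrow(samples))
  depth_grid <- 0:199
  for (j in seq_len(nrow(samples))) {
    k <- n_leak[j]
    if (k == 0) next
    anc_col <- paste0("ac_", tolower(samples$ancestry[j]))
    w <- if (anc_col %in% names(g)) g[[anc_col]] else rep(1, nrow(g))
    if (sum(w) <= 0) w <- rep(1, nrow(g))
    pick <- sample.int(nrow(g), size = min(k, nrow(g)), prob = w)
    gv <- g[pick, , drop = FALSE]
    mu <- config$depth_mean * exp(config$depth_gc_slope * (gv$gc_win - 0.5))
    depth <- vapply(mu, function(m) {
      pmf <- dnbinom(depth_grid, mu = m, size = config$depth_dispersion) *
        plogis((config$leak_depth_midpoint - depth_grid) /
          config$leak_depth_scale)
      if (sum(pmf) <= 0) {
        return(0L)
      }
      as.integer(sample(depth_grid, 1, prob = pmf))
    }, integer(1))
    rows[[j]] <- tibble(
      chrom = gv$chrom, pos = gv$pos, ref = gv$ref, alt = gv$alt,
      context = gv$context, basic_class = gv$basic_class,
      sample = samples$sample[j],
      project = samples$project[j],
      ancestry = samples$ancestry[j],
      vaf = pmin(pmax(rnorm(nrow(gv), 0.5, 0.05), 0.05), 0.95),
      n_depth = depth,
      filter = "PASS",
      origin = "leaked_germline"
    )
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_reference()], universe
#' construction and annotation, [assign_context_rates()] and
#' [simulate_callsets()] under one master seed.
#'
#' @param config A [generator_config()].
#' @return A `"synthetic_cohort"` (see [simulate_callsets()]).
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(
#'   exome_length = 2e4, n_somatic_samples = 5, seed = 42
#' ))
#' cohort
simulate_cohort <- function(config) {
  reference <- generate_reference(config)
  universe <- generator_universe(config, reference)
  rates <- assign_context_rates(config, universe)
  simulate_callsets(config, reference, rates, universe)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf(
    "  universe: %s potential SNVs over %s bases (%d chromosomes)\n",
    format(nrow(x$universe), big.mark = ","),
    format(x$config$exome_length, big.mark = ","), x$config$n_chromosomes
  ))
  cat(sprintf(
    "  germline: %s variants; somatic: %s calls (%s leaked) across %d samples\n",
    format(nrow(x$germline_calls), big.mark = ","),
    format(nrow(x$somatic_calls), big.mark = ","),
    format(sum(x$somatic_calls$origin == "leaked_germline"), big.mark = ","),
    x$config$n_somatic_samples
  ))
  invisible(x)
}
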