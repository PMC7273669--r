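# End-to-end orchestration: simulate (or load), whitelist, annotate,
# statistics, reports.

#' Configuration of an end-to-end pipeline run
#'
#' Exactly one of `generator` (a [generator_config()] for a synthetic run)
#' or `inputs` (named list of paths: `reference`, `germline`, `somatic`,
#' plus optional `targets`/`blacklists` BED paths and a `coverage` TSV) must
#' be supplied.
#'
#' @param generator Optional [generator_config()].
#' @param inputs Optional named list of input paths.
#' @param whitelist A [whitelist_spec()] (real-input runs only; synthetic
#'   runs analyse the generator's own universe).
#' @param levels Context levels for the decomposition, coarse to fine.
#' @param analyses Character subset of
#'   `c("forbes", "rates", "leakage", "characterize")`.
#' @param out_dir Output directory for the TSV reports.
#' @param seed Seed recorded in the run log (the generator carries its own).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(generator = NULL, inputs = NULL,
                       whitelist = whitelist_spec(),
                       levels = c("unpartitioned", "basic_class", "trimer"),
                       analyses = c("forbes", "rates", "leakage", "characterize"),
                       out_dir = tempfile("sharedvar_run_"),
                       seed = 1) {
  if (is.null(generator) == is.null(inputs)) {
    abort("provide exactly one of `generator` or `inputs`")
  }
  analyses <- match.arg(
    analyses, c("forbes", "rates", "leakage", "characterize"),
    several.ok = TRUE
  )
  structure(
    list(
      generator = generator, inputs = inputs, whitelist = whitelist,
      levels = levels, analyses = analyses, out_dir = out_dir, seed = seed
    ),
    class = "run_config"
  )
}

#' Run the full shared-variant pipeline
#'
#' Simulates or loads the cohort, builds/annotates the universe, applies
#' the variant filters, and runs the requested analyses. Writes a
#' whitelist/filter summary, the decomposition table, rate-correlation,
#' leakage and characterization TSVs plus a run log of all totals to
#' `config$out_dir`. Reruns with the same configuration are bit-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`universe` totals,
#'   `decomposition`, `rates`, `correlations`, `leakage`, `characterize`,
#'   `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  max_flank <- max(c(
    1L,
    match(config$levels, c("trimer", "pentamer", "heptamer"), nomatch = 0L)
  ))

  if (!is.null(config$generator)) {
    cohort <- stage("simulate", simulate_cohort(config$generator))
    universe <- cohort$universe
    if (max_flank > max(config$generator$context_flank, 1L)) {
      universe <- stage(
        "annotate",
        annotate_universe(
          dplyr::select(
            universe, "chrom", "pos", "ref", "alt", "gc_win", "gen_context"
          ),
          cohort$reference,
          flank = max_flank
        )
      )
    }
    germline_raw <- cohort$germline_calls
    somatic_raw <- cohort$somatic_calls
    note("generator seed: %d", config$generator$seed)
  } else {
    ref <- stage("load", read_reference_fasta(config$inputs$reference))
    germline_raw <- stage("load", read_germline_sites(config$inputs$germline))
    somatic_raw <- stage("load", read_somatic_maf(config$inputs$somatic))
    spec <- config$whitelist
    if (!is.null(config$inputs$targets)) {
      spec$target_sets <- purrr::map(config$inputs$targets, read_bed)
    }
    if (!is.null(config$inputs$blacklists)) {
      spec$blacklists <- purrr::map(config$inputs$blacklists, read_bed)
    }
    if (!is.null(config$inputs$coverage)) {
      spec$coverage_track <- readr::read_tsv(
        config$inputs$coverage,
        show_col_types = FALSE, progress = FALSE
      )
    }
    universe <- stage(
      "whitelist", build_universe(ref, spec, germline = germline_raw)
    )
    stages <- attr(universe, "filter_stages")
    note(
      "whitelist stages: %s",
      paste(names(stages), stages, sep = "=", collapse = ", ")
    )
    universe <- stage(
      "annotate", annotate_universe(universe, ref, flank = max_flank)
    )
  }

  germline <- stage("filter", apply_variant_filters(
    germline_raw, "germline",
    universe = universe
  ))
  somatic <- stage("filter", apply_variant_filters(
    somatic_raw, "somatic",
    universe = universe
  ))
  note(
    "totals: n=%d potential SNVs, g=%d germline, s=%d somatic (unique site-alleles)",
    nrow(universe), nrow(distinct_site_alleles(germline)),
    nrow(distinct_site_alleles(somatic))
  )

  results <- list(paths = character(0))
  out <- function(name) file.path(config$out_dir, name)
  save_tsv <- function(df, name) {
    readr::write_tsv(df, out(name), progress = FALSE)
    results$paths <<- c(results$paths, setNames(out(name), name))
  }

  if ("forbes" %in% config$analyses) {
    decomp <- stage("forbes", forbes_decomposition(
      universe, germline, somatic,
      levels = config$levels
    ))
    results$decomposition <- decomp
    save_tsv(render_table2(decomp), "decomposition.tsv")
    b <- count_shared(germline, somatic, universe)
    note("shared variants: b=%d", b)
    per_sample <- stage(
      "forbes", per_sample_forbes(somatic, germline, universe)
    )
    save_tsv(per_sample, "per_sample_forbes.tsv")
    by_type <- stage(
      "forbes", subset_forbes(somatic, germline, universe, by = "project")
    )
    save_tsv(by_type, "forbes_by_cancer_type.tsv")
    results$per_sample <- per_sample
    results$by_type <- by_type
  }

  if ("rates" %in% config$analyses) {
    level_cols <- intersect(
      c("trimer", "pentamer", "heptamer"), names(universe)
    )
    rates <- purrr::map(
      setNames(level_cols, level_cols),
      ~ context_rates(germline, somatic, universe, level = .x)
    )
    correlations <- purrr::imap_dfr(rates, function(tab, lv) {
      rows <- list(cross_setting_correlation(tab))
      rows[[1]]$analysis <- lv
      if (lv == "trimer") {
        r2 <- cross_setting_correlation(tab, exclude_ncg = TRUE)
        r2$analysis <- "trimer_excluding_ncg"
        rows <- c(rows, list(r2))
      }
      if (lv %in% c("pentamer", "heptamer")) {
        r3 <- stratified_correlation(tab)
        r3 <- tibble(
          rho = r3$rho, p_value = NA_real_, n_contexts = r3$n_contexts,
          analysis = paste0(lv, "_controlling_central")
        )
        rows <- c(rows, list(r3))
      }
      dplyr::bind_rows(rows)
    })
    results$rates <- rates
    results$correlations <- correlations
    save_tsv(correlations, "rate_correlations.tsv")
  }

  if ("leakage" %in% config$analyses) {
    per_depth <- stage(
      "leakage", shared_rate_by_depth(somatic, germline)
    )
    n_exomes <- dplyr::n_distinct(somatic$sample)
    leak <- tryCatch(
      estimate_leakage(per_depth, n_exomes = n_exomes),
      error = function(e) {
        note("leakage: skipped (%s)", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(leak)) {
      results$leakage <- leak
      save_tsv(glance(leak), "leakage.tsv")
      note(
        "leakage: %.3f per exome (corrected %.3f) over %d exomes",
        leak$per_exome, leak$per_exome_corrected, leak$n_exomes
      )
    }
  }

  if ("characterize" %in% config$analyses) {
    if ("age" %in% names(germline)) {
      age <- stage(
        "characterize", shared_rate_by_allele_age(germline, somatic)
      )
      save_tsv(age$by_bin, "shared_rate_by_age.tsv")
      results$age <- age
    }
    if (any(grepl("^ac_", names(germline)))) {
      cont <- stage(
        "characterize", shared_rate_by_continent_count(germline, somatic)
      )
      save_tsv(cont, "shared_rate_by_continent_count.tsv")
      results$continent <- cont
      if ("ancestry" %in% names(somatic)) {
        anc <- stage("characterize", ancestry_cross_table(germline, somatic))
        save_tsv(anc, "ancestry_cross_table.tsv")
        results$ancestry <- anc
      }
    }
    if ("vaf" %in% names(somatic)) {
      vaf <- stage("characterize", vaf_comparison(somatic, germline))
      save_tsv(vaf$summary, "vaf_comparison.tsv")
      results$vaf <- vaf
    }
  }

  writeLines(log_lines, out("run_log.txt"))
  results$paths <- c(results$paths, run_log = out("run_log.txt"))
  results$log <- log_lines
  invisible(results)
}

#' Render a decomposition as a report table
#'
#' Formats a [forbes_decomposition()] result in the layout of the
#' successively-finer-contexts table: partition scheme, number of
#' partitions, expected shared count (rounded to an integer), conditioned
#' coefficient (3 decimal places), total explained percentage and
#' incremental explanatory percentage.
#'
#' @param decomposition Tibble from [forbes_decomposition()] /
#'   [explained_decomposition()].
#' @return Tibble with formatted reporting columns.
#' @export
render_table2 <- function(decomposition) {
  if (nrow(decomposition) == 0) {
    return(tibble(
      partition_scheme = character(0), n_partitions = integer(0),
      expected_shared = integer(0), conditioned_forbes = character(0),
      total_explained = character(0), incremental = character(0)
    ))
  }
  tibble(
    partition_scheme = decomposition$level,
    n_partitions = decomposition$m,
    expected_shared = as.integer(round(decomposition$expected)),
    conditioned_forbes = sprintf("%.3f", decomposition$coefficient),
    total_explained = sprintf(
      "%.1f%%", 100 * decomposition$explained_fraction
    ),
    incremental = sprintf("%.1f%%", 100 * decomposition$incremental)
  )
}
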