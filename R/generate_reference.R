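#' Generate a synthetic reference exome
#'
#' Simulates per-chromosome base sequences from a first-order Markov chain
#' whose only non-independence is a boosted (or damped) G following C,
#' giving direct control over the CpG dinucleotide frequency while the
#' stationary G+C content is calibrated to `gc_fraction` exactly.
#'
#' @param config A [generator_config()].
#' @return Named character vector of chromosome sequences ("chr1", ...),
#'   lengths as equal as possible and summing to `config$exome_length`.
#' @export
#' @examples
#' ref <- generate_reference(generator_config(exome_length = 1e4))
#' nchar(ref)
generate_reference <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$exome_length < 2 * config$context_flank + 1) {
    abort("invalid config: exome_length must be >= 2 * context_flank + 1")
  }
  probs <- calibrate_base_probs(config$gc_fraction, config$cpg_enrichment)
  lens <- chromosome_lengths(config$exome_length, config$n_chromosomes)
  with_substream(config$seed, stage = 1L, {
    seqs <- vapply(
      lens,
      function(L) markov_sequence(L, probs$p, probs$p_after_c),
      character(1)
    )
    names(seqs) <- paste0("chr", seq_along(seqs))
    seqs
  })
}

#' @noRd
chromosome_lengths <- function(total, k) {
  base <- total %/% k
  lens <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  lens
}

# Transition rows: all bases emit `p` except C, which emits `p_after_c`
# (G boosted by `enrich`, renormalized). `gc` parametrizes p; the stationary
# GC of the chain is computed and gc is tuned by root-finding so the
# stationary GC equals the target.
#' @noRd
calibrate_base_probs <- function(gc_target, enrich) {
  make <- function(gc) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    pc <- p
    pc["G"] <- pc["G"] * enrich
    pc <- pc / sum(pc)
    list(p = p, p_after_c = pc)
  }
  stationary_gc <- function(gc) {
    pr <- make(gc)
    tm <- rbind(pr$p, pr$p_after_c, pr$p, pr$p) # rows: A, C, G, T
    # stationary distribution of the 4-state chain
    e <- eigen(t(tm))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    v <- v / sum(v)
    v[2] + v[3]
  }
  if (enrich == 1) {
    return(make(gc_target))
  }
  f <- function(gc) stationary_gc(gc) - gc_target
  lo <- max(gc_target / 4, 1e-6)
  hi <- min(gc_target * 2, 1 - 1e-6)
  # widen until bracketed (enrichment shifts stationary GC modestly)
  while (f(lo) > 0 && lo > 1e-8) lo <- lo / 2
  while (f(hi) < 0 && hi < 1 - 1e-8) hi <- (hi + 1) / 2
  root <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  make(root)
}

# Sequential sampler for the two-row Markov chain; only the post-C row
# differs, so each step is a couple of scalar comparisons.
#' @noRd
markov_sequence <- function(n, p, p_after_c) {
  cum <- cumsum(p)
  cumc <- cumsum(p_after_c)
  c1 <- cum[1]; c2 <- cum[2]; c3 <- cum[3]
  d1 <- cumc[1]; d2 <- cumc[2]; d3 <- cumc[3]
  u <- runif(n)
  out <- integer(n)
  after_c <- FALSE
  for (i in seq_len(n)) {
    ui <- u[i]
    b <- if (after_c) {
      1L + (ui > d1) + (ui > d2) + (ui > d3)
    } else {
      1L + (ui > c1) + (ui > c2) + (ui > c3)
    }
    out[i] <- b
    after_c <- b == 2L
  }
  paste(BASES[out], collapse = "")
}
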