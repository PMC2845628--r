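#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the workflow with the defaults used
#' throughout: a TF qualifies with at least 30 activated targets; conserved
#' fragments are calibrated to 10% DNA coverage; de novo discovery searches
#' motif lengths 6, 8 and 10; library enrichment uses 10,000 label
#' permutations and de novo significance 100 full-discovery permutations;
#' networks use 100 bootstraps with a consensus cutoff of p < 1e-7, an
#' MI significance level of 5e-2 and a co-expression threshold of 1e-4
#' (both Bonferroni-corrected).
#'
#' @param min_targets minimum number of activated targets for a TF to enter
#'   motif analysis.
#' @param coverage_fraction proportion of (MCR-unmasked) DNA retained by each
#'   conservation mask.
#' @param motif_lengths integer vector of de novo motif lengths.
#' @param library_permutations label permutations for library enrichment
#'   p-values.
#' @param denovo_permutations full-discovery permutations for de novo
#'   significance.
#' @param significance_alpha significance level for reported motifs.
#' @param bootstraps number of bootstrap networks.
#' @param consensus_alpha consensus-support p-value cutoff.
#' @param mi_alpha MI significance level (Bonferroni-corrected over pairs).
#' @param coexpr_alpha Bonferroni-corrected Spearman threshold for
#'   co-expression target sets.
#' @param rng_seed integer seed governing all stochastic stages.
#' @param beam beam width of the coarse de novo search.
#' @param refine_top number of coarse candidates refined per motif length.
#' @param max_refine_iter cap on hill-climbing iterations during refinement.
#' @param seed_words number of over-represented words used to seed the coarse
#'   search.
#' @param dpi_tolerance Data Processing Inequality tolerance.
#' @param short_promoters `"drop"` or `"pad"` for promoters truncated at
#'   contig ends.
#' @return an object of class `dismotif_config`.
#' @export
run_config <- function(min_targets = 30L,
                       coverage_fraction = 0.10,
                       motif_lengths = c(6L, 8L, 10L),
                       library_permutations = 10000L,
                       denovo_permutations = 100L,
                       significance_alpha = 0.05,
                       bootstraps = 100L,
                       consensus_alpha = 1e-7,
                       mi_alpha = 5e-2,
                       coexpr_alpha = 1e-4,
                       rng_seed = 1L,
                       beam = 50L,
                       refine_top = 5L,
                       max_refine_iter = 100L,
                       seed_words = 500L,
                       dpi_tolerance = 0,
                       short_promoters = c("drop", "pad")) {
  cfg <- list(
    min_targets = as.integer(min_targets),
    coverage_fraction = coverage_fraction,
    motif_lengths = as.integer(motif_lengths),
    library_permutations = as.integer(library_permutations),
    denovo_permutations = as.integer(denovo_permutations),
    significance_alpha = significance_alpha,
    bootstraps = as.integer(bootstraps),
    consensus_alpha = consensus_alpha,
    mi_alpha = mi_alpha,
    coexpr_alpha = coexpr_alpha,
    rng_seed = as.integer(rng_seed),
    beam = as.integer(beam),
    refine_top = as.integer(refine_top),
    max_refine_iter = as.integer(max_refine_iter),
    seed_words = as.integer(seed_words),
    dpi_tolerance = dpi_tolerance,
    short_promoters = match.arg(short_promoters))
  probs <- c("significance_alpha", "consensus_alpha", "mi_alpha",
             "coexpr_alpha")
  for (p in probs)
    if (cfg[[p]] <= 0 || cfg[[p]] > 1)
      stop(p, " must lie in (0, 1]", call. = FALSE)
  if (cfg$coverage_fraction <= 0 || cfg$coverage_fraction >= 1)
    stop("coverage_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$min_targets < 1) stop("min_targets must be >= 1", call. = FALSE)
  if (cfg$dpi_tolerance < 0) stop("dpi_tolerance must be >= 0", call. = FALSE)
  if (any(cfg$motif_lengths < 4))
    stop("motif lengths must be >= 4", call. = FALSE)
  class(cfg) <- "dismotif_config"
  cfg
}

#' @export
print.dismotif_config <- function(x, ...) {
  cat("dismotif run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm,
                                   paste(x[[nm]], collapse = ",")))
  invisible(x)
}
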