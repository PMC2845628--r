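---
title: "Methods: integrative discriminative TFBS discovery"
author: "dismotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative discriminative TFBS discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`dismotif` predicts transcription factor binding sites (TFBSs) by chaining
four ideas that individually have long track records in regulatory
genomics:

1. **Target selection by network inference.** Co-expression alone mixes
   direct targets with indirect ones. We estimate pairwise mutual
   information (MI) between regulator and gene expression profiles, keep
   statistically significant edges, and prune likely-indirect edges with
   the Data Processing Inequality (DPI): in a dependency chain
   X → Y → Z, MI(X,Z) ≤ min(MI(X,Y), MI(Y,Z)), so in any significant
   triangle the weakest edge is the indirect-interaction suspect.
   Bootstrap resampling over samples and a consensus filter make the edge
   list robust to estimation noise. Only targets *activated* by the TF
   (positive Spearman sign) are carried forward, and only TFs with at
   least 30 such targets are analysed — below that, enrichment statistics
   and discriminative discovery lack power.

2. **Promoter assembly.** For each target gene we take the 1500-base
   window [−1000, +500) around the TSS in transcription orientation,
   drop intersecting promoters deterministically, and mask repeats and
   coding exons (the MCR set). A background of non-target promoters is
   selected at random and processed identically to the foreground at
   every later stage, so every foreground/background comparison is
   matched.

3. **Two routes to conservation.** Alignment-based per-base conservation
   scores are thresholded so that a chosen fraction (default 10%) of the
   unmasked DNA survives; this makes runs comparable across regulators
   regardless of the score distribution. Because binding sites turn over —
   they relocate and reorder while their content is preserved — linear
   alignment misses a class of genuinely conserved sites. A second,
   alignment-free route therefore enumerates 8-base seed words in the
   reference promoter and looks for occurrences matching at least 6 of 8
   positions in orthologous promoters (both strands), reporting patterns
   supported by at least 4 species. Top-ranked patterns are consumed until
   the same 10% coverage is reached, and the union of both masks is the
   combined-conservation set.

4. **Discriminative evaluation and discovery.** A motif's quality is its
   classification relative-error rate `err = (FPR + FNR)/2` at the
   optimal site-score cutoff, where a sequence is positive when its best
   PWM log-odds site reaches the cutoff. Known-motif libraries are ranked
   by err with permutation p-values; de novo discovery searches a
   discretised PWM space with the same objective. Discovery is run on
   both the conservation-free and the combined-conservation sets and the
   motif lists are merged, each motif keeping the better of its two errs —
   conservation helps some regulators and hurts others, and the merge
   keeps whichever view is sharper.

# The MI estimator

MI is estimated on the copula scale: each profile is replaced by its
midranks mapped to (0,1), which makes the estimator invariant under
strictly monotone transforms of either argument and insensitive to
expression units. Joint and marginal densities on the rank scale are
estimated with fixed-bandwidth Gaussian kernels (normal-reference
bandwidths: `sd * n^(-1/6)` for the bivariate kernel, `1.06 * sd *
n^(-1/5)` for the marginals), and

\[ \widehat{MI} = \frac{1}{n}\sum_i \log
  \frac{\hat f_{xy}(u_i, v_i)}{\hat f_x(u_i)\,\hat f_y(v_i)} \]

floored at zero. Because midranks are half-integers, all kernel values are
table lookups over the finite set of rank differences; the estimator is
deterministic and fast enough to run inside every bootstrap. On
independent data at n = 254 it has mean ≈ 0.004 nats with spread of the
same order (the calibration suite checks bias < 3 × spread).

The per-bootstrap significance threshold is the Bonferroni-corrected
quantile of a null built by shuffling one gene of randomly chosen gene
pairs within the same (resampled) matrix. When the corrected quantile is
beyond the resolution of the null sample, the tail is extrapolated with an
exponential peaks-over-threshold fit to the top 5% of the null — refusing
outright would make stringent corrections unusable at practical null
sizes.

## Consensus support

Each of B bootstraps (default 100) yields an edge set; an edge's support
is the number of bootstrap networks containing it. The null for support is
the shuffled-network null: if bootstrap *b* kept `E_b` of `P` candidate
pairs, an exchangeable edge is present with probability `E_b/P`
independently across bootstraps, so null support is Poisson-binomial. We
evaluate its upper tail exactly by dynamic programming rather than by
simulating a finite number of shuffled networks: the consensus cutoff
(p < 1e-7) sits far below the resolution of any practical empirical null
(a million simulated values cannot certify p-values below ~1e-6), while
the analytic tail of the same null model is exact at any level.

# Conservation details

**Coverage calibration.** `threshold_for_coverage()` returns the score
threshold whose retained fraction is the largest value not exceeding the
requested fraction (closest from below). Ties and score granularity are
the only sources of deviation; on continuous scores the achieved fraction
is within 1/N of the request.

**Sparse patterns.** Occurrences follow the 8-base window / ≥6-match /
≥4-species rule, with both strands searched in every species (binding is
strand-agnostic). Patterns are ranked by a z-score comparing the summed
best match quality across non-reference species against a per-species
background model: base composition of the unmasked promoter gives the
match probability of each seed position, a Poisson-binomial over the 8
positions gives per-window match-quality probabilities, and the best of
`m` windows gives the per-species null for the observed best quality.
An order-0 composition null was chosen because exact ≥6-of-8 window
probabilities under higher-order Markov models have no tractable closed
form; the synthetic generator nevertheless produces order-3 Markov
background so the null is conservative with respect to local
composition structure.

The conserved *region* contributed by a pattern is the union of the
seed's exact windows in the reference — the loci the pattern was read
from. Partial (6/8) matches elsewhere in the reference count as
occurrences for support but not as conserved regions; including them
would let chance self-matches dilute the coverage budget with
non-conserved DNA. Greedy consumption stops at the first pattern that
would overshoot the coverage budget by more than one percentage point.

# Discovery details

The coarse search evaluates, for each motif length (6, 8, 10), PWMs built
from the 500 foreground words with the highest smoothed foreground/
background frequency ratio; each word maps to a lattice matrix of smoothed
point-mass columns. The column alphabet for refinement contains the four
point masses, the six two-base equal mixtures and the uniform column
(granularity-2 lattice; a coarse but smooth cover of column space). The
top 50 candidates are kept and the best 5 per length are refined by
steepest-descent single-column replacement, re-optimising the cutoff after
every step; ties break by column index then alphabet order so the whole
procedure is deterministic and independent of input order. Refining only
the top candidates bounds the cost of the quadratic refinement loop while
leaving the beam available for merging; in the planted-motif benchmark
recovery is driven by the refinement of the first few candidates.

Significance for de novo motifs repeats the *entire* discovery on
label-permuted foreground/background pools (the permutation unit is the
whole sequence, never a window) and records each permutation's best err;
an observed motif is significant when its err beats the 5th percentile of
that null. Library p-values use the per-permutation *library minimum* err
by default — this controls selection over the library; the per-motif null
is available as an option. All permutation p-values use the add-one
estimator, so no p-value is ever zero.

# The synthetic benchmark

The generator plants exactly the structures the pipeline claims to
detect, and nothing else:

* expression: TF profiles i.i.d. normal; targets linear in the TF with
  Gaussian noise (sd 0.5 at effect 1 — strong but noisy activation);
  cascades give distal genes dependence on the TF only through the
  mediator; 254 samples mirror the scale of a large expression compendium;
* promoters: order-3 Markov background, 1500 bases, one planted site in
  90% of foreground sequences (an 8-column AP-1-like PWM with one
  degenerate column — informative but not trivially strong);
* orthologs: 40-base conserved islands around each planted site, copied
  into five species at 5% per-base substitution (highly conserved
  elements), spacers regenerated per species, and island order permuted
  per species with the turnover probability. The emitted conservation
  track scores islands high only in proportion to the species that kept
  the original order — precisely the blindness of alignment-based
  conservation to turnover. At least two islands are always present so
  that reordering is expressible.

What the benchmark does **not** emulate: the covariance structure of real
expression compendia, promoter GC/CpG structure beyond Markov order 3, indels and
island gain/loss during evolution, or heterogeneous site strength per
sequence. Passing tests therefore demonstrate correctness of the
machinery and the qualitative turnover contrast, not expected recall on
real genomes.

# Problem sizes and numerical choices

The standing benchmarks use 30 foreground / 200 background promoters for
recovery, 30/100 for the turnover contrast, 200 replicates at reduced
permutation counts (199 label permutations; 20 discovery permutations
with a single-length, beam-1 discoverer) for calibration, and one TF with
35 direct targets plus 10 cascades at 254 samples for network recovery —
sizes at which each experiment completes in minutes on one CPU while
keeping the planted effects comfortably detectable.

Other fixed choices: TRANSFAC counts are smoothed with a pseudocount of
0.5 per base per column; PWM columns are re-smoothed whenever an entry
would be zero, so log-odds are always finite; coordinates are 0-based
half-open internally with BED conventions on disk; "arbitrary"
elimination of intersecting promoters keeps the lexicographically earlier
gene id; multi-TSS genes use the 5'-most TSS in transcription
orientation; promoters truncated by contig ends are dropped by default
(padding with masked Ns is available); motif comparison uses mean
per-column symmetrised Kullback–Leibler divergence in bits with a
1.0-bit match cutoff and a minimum 4-column overlap; co-expression
Bonferroni correction is over candidate genes by default (over gene×TF
pairs as an option).

# Known limitations

* The DPI is applied with tolerance 0; correlated regulators with nearly
  equal MI can lose true edges.
* The sparse-pattern z-score null ignores overlap dependence between
  windows and higher-order composition; its absolute scale is
  approximate, though ranking is stable.
* Discovery is a heuristic over a very coarse column lattice; it finds
  strong discriminative motifs reliably but makes no optimality claim.
* Permutation significance assumes exchangeability of sequences between
  foreground and background; length or composition imbalance between the
  sets would break calibration (the pipeline's matched processing is what
  justifies the assumption).
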