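## Cross-species conservation masking. Two routes to conserved promoter
## fragments: (a) thresholding per-base alignment conservation scores,
## calibrated so a requested fraction of unmasked DNA survives; (b)
## deterministic sparse-pattern discovery across orthologous promoters
## (8-base seed windows, >= 6 matching positions per occurrence, support
## across >= 4 species), which tolerates binding-site turnover because it
## never requires colinearity. The two masks are combined by union.

#' Calibrate a conservation-score threshold to a DNA coverage fraction
#'
#' Returns the score threshold `t` such that the fraction of (unmasked)
#' bases with score `>= t` is the largest value not exceeding the requested
#' fraction (closest-from-below rule, subject to score granularity).
#'
#' @param track a [cons_track] object.
#' @param fraction requested proportion of retained DNA, in (0,1).
#' @param seqs optional [masked_seqs]; when given, only scores at unmasked
#'   positions enter the calibration.
#' @return list of class `coverage_calibration` with `threshold`,
#'   `achieved_fraction`, `requested_fraction`.
#' @export
threshold_for_coverage <- function(track, fraction, seqs = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0,1)", call. = FALSE)
  v <- unlist(lapply(names(track$scores), function(nm) {
    s <- track$scores[[nm]]
    if (!is.null(seqs) && nm %in% names(seqs)) s[!seqs$mask[[nm]]] else s
  }), use.names = FALSE)
  if (!length(v) || all(v == 0))
    stop("conservation track is all zero: threshold undefined",
         call. = FALSE)
  n <- length(v)
  tab <- rle(sort(v))      # ascending distinct values with counts
  cand <- tab$values
  frac_ge <- rev(cumsum(rev(tab$lengths))) / n
  ok <- frac_ge <= fraction
  if (!any(ok)) {
    warning("no threshold achieves coverage <= ", fraction,
            "; using the most stringent attainable")
    i <- length(cand)
  } else i <- which(ok)[1]  # cand ascending => frac_ge decreasing
  # among thresholds meeting the bound, the first (smallest score with
  # frac <= fraction) achieves the largest coverage <= fraction
  structure(list(threshold = cand[i], achieved_fraction = frac_ge[i],
                 requested_fraction = fraction),
            class = "coverage_calibration")
}

#' @export
print.coverage_calibration <- function(x, ...) {
  cat(sprintf(
    "coverage calibration: threshold %.4g, achieved %.3f (requested %.3f)\n",
    x$threshold, x$achieved_fraction, x$requested_fraction))
  invisible(x)
}

#' Alignment-based conservation mask
#'
#' Masks every base whose conservation score falls below the threshold
#' calibrated by [threshold_for_coverage()], so that approximately
#' `fraction` of the currently unmasked (MCR) bases survive.
#'
#' @param seqs a [masked_seqs] object (MCR stage).
#' @param track a [cons_track] with scores for the same sequences.
#' @param fraction requested retained DNA fraction.
#' @return a [masked_seqs] at stage `alignment-conserved`, with the
#'   calibration attached as attribute `calibration`.
#' @export
alignment_conserved_mask <- function(seqs, track, fraction = 0.10) {
  cal <- threshold_for_coverage(track, fraction, seqs)
  out <- seqs
  for (nm in names(out)) {
    s <- track$scores[[nm]]
    if (is.null(s)) s <- numeric(length(out$mask[[nm]]))
    out$mask[[nm]] <- out$mask[[nm]] | s < cal$threshold
  }
  out <- set_stage(out, "alignment-conserved")
  attr(out, "calibration") <- cal
  out
}

# P(X >= k) for X = sum of independent Bernoulli(p_ij), vectorised over rows
# of an n x w probability matrix; returns n x (w+1) matrix of upper tails.
pb_upper_tails <- function(pmat) {
  n <- nrow(pmat); w <- ncol(pmat)
  dp <- matrix(0, n, w + 1)
  dp[, 1] <- 1
  for (j in seq_len(w)) {
    p <- pmat[, j]
    dp <- cbind(dp[, 1] * (1 - p),
                dp[, -1, drop = FALSE] * (1 - p) +
                  dp[, -(w + 1), drop = FALSE] * p)
  }
  dp %*% outer(0:w, 0:w, ">=")  # column k+1 = P(X >= k)
}

# union of fixed-width windows as a 2-column (start, end) matrix
merge_windows <- function(off, width) {
  off <- sort(unique(off))
  if (length(off) == 1L) return(cbind(start = off, end = off + width))
  brk <- which(diff(off) > width)
  s <- off[c(1L, brk + 1L)]
  e <- off[c(brk, length(off))] + width
  cbind(start = s, end = e)
}

#' Sparse-pattern discovery across orthologous promoters
#'
#' Enumerates every fully unmasked 8-base seed word in the reference
#' promoter and records, in each species, windows matching the seed (or its
#' reverse complement) in at least `min_match` of `wlen` positions. A
#' pattern is reported when occurrences span at least `min_species` species
#' (the reference counts as one). Patterns are ranked by a z-score that
#' compares the summed best match quality across non-reference species with
#' its expectation under a per-species background composition model
#' (Poisson-binomial over window-match probabilities), and ties are broken
#' by seed lexicographic order.
#'
#' @param orthologs a [masked_seqs] object with the reference promoter first
#'   and one entry per ortholog species, all MCR-masked.
#' @param min_species minimum number of supporting species.
#' @param wlen seed window length.
#' @param min_match minimum matching positions per occurrence.
#' @return data.frame with columns `seed`, `z`, `support`, `n_occ`, and a
#'   list-column `intervals` of reference-coordinate matrices (`start`,
#'   `end`, 0-based half-open) covered by the pattern, sorted by decreasing
#'   `z`.
#' @export
find_sparse_patterns <- function(orthologs, min_species = 4L, wlen = 8L,
                                 min_match = 6L) {
  nsp <- length(orthologs)
  if (nsp < min_species) {
    message("gene has ", nsp, " sequences < min_species; skipped")
    return(empty_patterns())
  }
  sc <- cpp_sparse_scan(orthologs$seq, orthologs$mask, wlen, min_match)
  nseed <- length(sc$seed)
  if (!nseed) return(empty_patterns())
  present <- sc$bestq >= min_match
  support <- rowSums(present)
  keep <- support >= min_species
  if (!any(keep)) return(empty_patterns())

  # z-score: summed best-match quality across non-reference species vs the
  # background composition model (best of m windows, floored at min_match-1)
  seed_codes <- do.call(rbind, lapply(strsplit(sc$seed, ""),
                                      function(ch) match(ch, DNA_BASES)))
  qualities <- pmax(sc$bestq, min_match - 1L)
  Esum <- numeric(nseed); Vsum <- numeric(nseed); Osum <- numeric(nseed)
  for (s in seq_len(nsp)[-1]) {
    code <- orthologs$seq[[s]]
    m <- orthologs$mask[[s]]
    ok <- !m & code > 0L
    freq <- tabulate(code[ok], 4)
    freq <- (freq + 1) / sum(freq + 1)
    runs <- rle(ok)
    mw <- sum(pmax(runs$lengths[runs$values] - wlen + 1L, 0L))
    if (mw < 1) next
    pF <- matrix(freq[seed_codes], nseed, wlen)
    pR <- matrix(freq[5L - seed_codes], nseed, wlen)
    tF <- pb_upper_tails(pF)  # nseed x (wlen+1), col k+1 = P(X >= k)
    tR <- pb_upper_tails(pR)
    ks <- min_match:wlen
    pk <- 1 - (1 - tF[, ks + 1L, drop = FALSE]) *
      (1 - tR[, ks + 1L, drop = FALSE])  # both strands
    bge <- 1 - (1 - pk)^mw  # P(best >= k) over m windows
    E <- (min_match - 1) + rowSums(bge)
    pmf <- cbind(1 - bge[, 1],
                 bge[, -ncol(bge), drop = FALSE] -
                   bge[, -1, drop = FALSE],
                 bge[, ncol(bge)])
    vals <- (min_match - 1):wlen
    E2 <- as.vector(pmf %*% vals^2)
    Esum <- Esum + E
    Vsum <- Vsum + pmax(E2 - E^2, 0)
    Osum <- Osum + pmax(sc$bestq[, s], min_match - 1L)
  }
  z <- ifelse(Vsum > 0, (Osum - Esum) / sqrt(Vsum), 0)

  # reference-coordinate coverage: union of the seed's exact windows in the
  # reference (the loci the pattern was read from; partial-match windows
  # elsewhere in the reference are occurrences, not pattern regions)
  occ_ref <- sc$occ_species == 1L & sc$occ_nmatch == wlen
  ref_by_seed <- split(sc$occ_offset[occ_ref], sc$occ_seed[occ_ref])
  intervals <- lapply(seq_len(nseed), function(k) {
    off <- ref_by_seed[[as.character(k)]]
    if (is.null(off)) off <- sc$first_offset[k]
    merge_windows(off, wlen)
  })
  n_occ <- as.integer(rowSums(sc$counts))
  out <- data.frame(seed = sc$seed, z = z, support = as.integer(support),
                    n_occ = n_occ, stringsAsFactors = FALSE)
  out$intervals <- intervals
  out <- out[keep, , drop = FALSE]
  out[order(-out$z, out$seed), , drop = FALSE]
}

empty_patterns <- function() {
  out <- data.frame(seed = character(), z = numeric(), support = integer(),
                    n_occ = integer(), stringsAsFactors = FALSE)
  out$intervals <- list()
  out
}

#' Pattern-based conservation mask
#'
#' Consumes patterns greedily from the top of the z ranking; every base
#' covered by a consumed pattern's reference intervals stays unmasked.
#' Consumption stops at the first pattern whose addition would push the
#' retained fraction beyond `fraction + tolerance`; everything not covered
#' by a consumed pattern is masked.
#'
#' @param seqs a [masked_seqs] object (MCR stage).
#' @param patterns named list mapping sequence name to a pattern data.frame
#'   from [find_sparse_patterns()] (or a single data.frame applied to a
#'   single-sequence set).
#' @param fraction requested retained DNA fraction (of MCR-unmasked bases).
#' @param tolerance absolute coverage overshoot allowed before stopping.
#' @return a [masked_seqs] at stage `pattern-conserved`.
#' @export
pattern_conserved_mask <- function(seqs, patterns, fraction = 0.10,
                                   tolerance = 0.01) {
  if (is.data.frame(patterns)) {
    if (length(seqs) != 1)
      stop("a single pattern table needs a single-sequence set",
           call. = FALSE)
    patterns <- setNames(list(patterns), names(seqs))
  }
  out <- seqs
  for (nm in names(out)) {
    base_mask <- seqs$mask[[nm]]
    n <- length(base_mask)
    denom <- sum(!base_mask)
    keepvec <- logical(n)
    pat <- patterns[[nm]]
    if (is.null(pat) || !nrow(pat)) {
      if (denom > 0) warning("no patterns for sequence ", nm,
                             ": fully masked")
    } else {
      pat <- pat[order(-pat$z, pat$seed), , drop = FALSE]
      added <- 0L
      for (r in seq_len(nrow(pat))) {
        iv <- pat$intervals[[r]]
        new <- logical(n)
        for (q in seq_len(nrow(iv))) {
          lo <- max(iv[q, 1], 0L); hi <- min(iv[q, 2], n)
          if (hi > lo) new[(lo + 1):hi] <- TRUE
        }
        new <- new & !base_mask & !keepvec
        if (denom > 0 &&
            (added + sum(new)) / denom > fraction + tolerance) break
        keepvec <- keepvec | new
        added <- added + sum(new)
      }
    }
    out$mask[[nm]] <- base_mask | !keepvec
  }
  set_stage(out, "pattern-conserved")
}

#' Combine alignment- and pattern-based conservation masks
#'
#' A base is unmasked in the result iff it is unmasked in either input
#' (union of conserved regions).
#'
#' @param align,pattern [masked_seqs] objects over the same sequences.
#' @return a [masked_seqs] at stage `combined-conservation`.
#' @export
combine_conservation <- function(align, pattern) {
  if (!identical(names(align), names(pattern)))
    stop("sequence names differ between the two masks", call. = FALSE)
  out <- align
  for (nm in names(out)) {
    if (length(align$mask[[nm]]) != length(pattern$mask[[nm]]))
      stop("length mismatch for sequence ", nm, call. = FALSE)
    out$mask[[nm]] <- align$mask[[nm]] & pattern$mask[[nm]]
  }
  set_stage(out, "combined-conservation")
}
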