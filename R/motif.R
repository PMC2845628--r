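## Motif evaluation: PWM site scanning, classification relative-error rate
## of motifs on foreground vs background promoter sets, permutation nulls
## for library and de novo significance, motif comparison and merging,
## cross-set re-ranking, and region-set site enrichment.

#' Base composition of the unmasked portion of a sequence set
#'
#' @param seqs a [masked_seqs] object.
#' @return numeric vector of A,C,G,T frequencies (pseudocount-smoothed).
#' @export
base_composition <- function(seqs) {
  counts <- numeric(4)
  for (i in seq_along(seqs$seq)) {
    ok <- !seqs$mask[[i]] & seqs$seq[[i]] > 0L
    counts <- counts + tabulate(seqs$seq[[i]][ok], 4)
  }
  setNames((counts + 1) / sum(counts + 1), DNA_BASES)
}

#' Best PWM site score per sequence
#'
#' Maximum log2-odds score over both strands and all fully unmasked windows
#' (`sum(log2(p_col(base)/bg(base)))`). Sequences with no unmasked window of
#' the motif length score `-Inf`.
#'
#' @param seqs a [masked_seqs] object.
#' @param motif a [pwm] object.
#' @param bg background base composition (A,C,G,T).
#' @return numeric vector of best scores, one per sequence.
#' @export
scan_best_site <- function(seqs, motif, bg = rep(0.25, 4)) {
  lom <- pwm_log_odds(motif, bg)
  setNames(cpp_scan_best(seqs$seq, seqs$mask, lom), names(seqs))
}

#' Classification relative-error rate of a motif
#'
#' A sequence is called positive iff its best site score reaches a cutoff;
#' the cutoff is chosen to minimise the relative error
#' `err = (FPR + FNR)/2` over the finite set of attained scores (plus the
#' all-negative cutoff, so the minimised err never exceeds 0.5). The
#' background base composition for log-odds scoring is estimated from the
#' matched background set unless supplied.
#'
#' @param fg,bg_set [masked_seqs] foreground and background sets at the same
#'   processing stage.
#' @param motif a [pwm] object.
#' @param bg optional background base composition.
#' @return list with `motif`, `err`, `cutoff`, `fpr`, `fnr`, `source_set`.
#' @export
classify_set <- function(fg, bg_set, motif, bg = NULL) {
  if (!length(fg) || !length(bg_set))
    stop("foreground and background must be non-empty", call. = FALSE)
  if (fg$stage != bg_set$stage)
    stop("foreground and background stage labels differ (",
         fg$stage, " vs ", bg_set$stage, ")", call. = FALSE)
  if (is.null(bg)) bg <- base_composition(bg_set)
  sf <- scan_best_site(fg, motif, bg)
  sb <- scan_best_site(bg_set, motif, bg)
  me <- cpp_min_err(c(sf, sb), c(rep(TRUE, length(sf)),
                                 rep(FALSE, length(sb))))
  fpr <- mean(sb >= me$cutoff)
  fnr <- mean(sf < me$cutoff)
  list(motif = motif$id, err = me$err, cutoff = me$cutoff,
       fpr = fpr, fnr = fnr, source_set = fg$stage)
}

# label-permutation matrix: n x n_perm logicals, nf TRUE per column
perm_labels <- function(n, nf, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    lab <- logical(n)
    lab[sample.int(n, nf)] <- TRUE
    lab
  }, logical(n))
}

#' Library motif enrichment with permutation p-values
#'
#' Evaluates every library motif by its minimised relative error, then
#' assigns p-values by permuting the foreground/background indicator vector
#' (whole sequences, never windows). The default null records, for each
#' permutation, the minimum err over the whole library (controlling
#' library-wide selection); `null = "per-motif"` uses each motif's own
#' permutation distribution instead. The add-one estimator
#' `p = (1 + #{null <= err}) / (n_perm + 1)` avoids zero p-values.
#'
#' @param library list of [pwm] objects.
#' @param fg,bg_set [masked_seqs] sets at the same stage.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param null `"library-min"` (default) or `"per-motif"`.
#' @param bg optional background base composition.
#' @return data.frame with `motif`, `err`, `cutoff`, `p`, `source_set`,
#'   `rank`, sorted by ascending err.
#' @export
library_significance <- function(library, fg, bg_set, n_perm = 10000L,
                                 seed = 1L,
                                 null = c("library-min", "per-motif"),
                                 bg = NULL) {
  null <- match.arg(null)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!length(library)) stop("empty motif library", call. = FALSE)
  if (is.null(bg)) bg <- base_composition(bg_set)
  nf <- length(fg); nb <- length(bg_set)
  n <- nf + nb
  scoremat <- vapply(library, function(p)
    c(scan_best_site(fg, p, bg), scan_best_site(bg_set, p, bg)),
    numeric(n))
  labels0 <- c(rep(TRUE, nf), rep(FALSE, nb))
  obs <- cpp_perm_min_err(scoremat, as.matrix(labels0))[, 1]
  cutoffs <- vapply(seq_along(library), function(m)
    cpp_min_err(scoremat[, m], labels0)$cutoff, 0)
  labmat <- with_seed(seed, perm_labels(n, nf, n_perm))
  nullmat <- cpp_perm_min_err(scoremat, labmat)
  p <- if (null == "library-min") {
    nullmin <- apply(nullmat, 2, min)
    vapply(obs, function(e) (1 + sum(nullmin <= e)) / (n_perm + 1), 0)
  } else {
    vapply(seq_along(obs), function(m)
      (1 + sum(nullmat[m, ] <= obs[m])) / (n_perm + 1), 0)
  }
  out <- data.frame(motif = vapply(library, `[[`, "", "id"),
                    err = obs, cutoff = cutoffs, p = p,
                    source_set = fg$stage, stringsAsFactors = FALSE)
  out <- out[order(out$err, out$p, out$motif), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' De novo discovery significance by full-discovery permutation
#'
#' Generates `n_perm` random foreground/background pair sets by permuting
#' the sequence membership indicator, runs the full (deterministic)
#' discoverer on each, and records the best (lowest) relative error per
#' permutation. Observed motifs are significant when their err beats the
#' 5th percentile of that null (add-one p-value at or below `alpha`).
#'
#' @param fg,bg_set [masked_seqs] sets at the same stage.
#' @param discoverer function `(fg, bg_set) -> data.frame` with at least an
#'   `err` column (best motifs of one discovery run); must be deterministic
#'   given its inputs.
#' @param n_perm number of discovery permutations (>= 20).
#' @param seed integer seed.
#' @param alpha significance level.
#' @return list with `observed` (the discoverer output on the real labels,
#'   plus `p` and `significant` columns), `null` (the n_perm best errs) and
#'   `threshold` (the err below which motifs are significant at `alpha`).
#' @export
denovo_significance <- function(fg, bg_set, discoverer, n_perm = 100L,
                                seed = 1L, alpha = 0.05) {
  if (n_perm < 20)
    stop("n_perm must be >= 20 to resolve the significance percentile",
         call. = FALSE)
  nf <- length(fg); nb <- length(bg_set)
  pool_seq <- c(fg$seq, bg_set$seq)
  pool_mask <- c(fg$mask, bg_set$mask)
  observed <- discoverer(fg, bg_set)
  null <- with_seed(substream_seed(seed, "denovo-null"), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nf + nb)
      pf <- masked_seqs(pool_seq[idx[seq_len(nf)]],
                        pool_mask[idx[seq_len(nf)]], stage = fg$stage)
      pb <- masked_seqs(pool_seq[idx[nf + seq_len(nb)]],
                        pool_mask[idx[nf + seq_len(nb)]],
                        stage = bg_set$stage)
      res <- discoverer(pf, pb)
      if (nrow(res)) min(res$err) else 0.5
    }, 0)
  })
  if (nrow(observed)) {
    observed$p <- vapply(observed$err, function(e)
      (1 + sum(null <= e)) / (n_perm + 1), 0)
    observed$significant <- observed$p <= alpha
  }
  list(observed = observed, null = null,
       threshold = unname(quantile(null, alpha, type = 1)))
}

## ---- motif comparison and merging -----------------------------------------

# symmetrised Kullback-Leibler divergence per aligned column, in bits
sym_kl_bits <- function(p, q) {
  0.5 * sum(p * log2(p / q) + q * log2(q / p))
}

#' Compare two PWMs by column divergence
#'
#' Divergence is the minimum, over relative offsets with at least
#' `min_overlap` aligned columns and both orientations, of the mean
#' per-column symmetrised Kullback-Leibler divergence in bits. Motifs match
#' when the divergence is at most `cutoff_bits`.
#'
#' @param a,b [pwm] objects.
#' @param cutoff_bits similarity cutoff (1.0 bit).
#' @param min_overlap minimum aligned columns.
#' @return list with `query`, `reference`, `divergence`, `offset`,
#'   `orientation`, `is_match`.
#' @export
compare_motifs <- function(a, b, cutoff_bits = 1.0, min_overlap = 4L) {
  la <- pwm_length(a); lb <- pwm_length(b)
  best <- list(divergence = Inf, offset = NA_integer_,
               orientation = NA_character_)
  for (ori in c("forward", "reverse-complement")) {
    bm <- if (ori == "forward") b$mat else pwm_revcomp(b)$mat
    for (off in seq(-(lb - min_overlap), la - min_overlap)) {
      ia <- max(1, 1 + off):min(la, lb + off)
      if (length(ia) < min_overlap) next
      ib <- ia - off
      d <- mean(vapply(seq_along(ia), function(k)
        sym_kl_bits(a$mat[, ia[k]], bm[, ib[k]]), 0))
      if (d < best$divergence)
        best <- list(divergence = d, offset = off, orientation = ori)
    }
  }
  list(query = a$id, reference = b$id, divergence = best$divergence,
       offset = best$offset, orientation = best$orientation,
       is_match = best$divergence <= cutoff_bits)
}

#' Merge similar motifs, keeping the best classifier of each cluster
#'
#' Greedy clustering at the comparison cutoff: motifs are visited in order
#' of increasing err (ties by id); each unassigned motif founds a cluster
#' and absorbs every remaining motif within `cutoff_bits` of it. Each
#' cluster is represented by its lowest-err member.
#'
#' @param motifs list of [pwm] objects.
#' @param errs numeric vector of their relative errors.
#' @param cutoff_bits merge cutoff in bits.
#' @return list with `pwms` (representatives), `errs`, and `cluster`
#'   (integer cluster id per input motif).
#' @export
merge_similar <- function(motifs, errs, cutoff_bits = 1.0) {
  stopifnot(length(motifs) == length(errs))
  k <- length(motifs)
  if (k == 0) return(list(pwms = list(), errs = numeric(),
                          cluster = integer()))
  ids <- vapply(motifs, `[[`, "", "id")
  ord <- order(errs, ids)
  cluster <- integer(k)
  nc <- 0L
  for (i in ord) {
    if (cluster[i]) next
    nc <- nc + 1L
    cluster[i] <- nc
    for (j in ord) {
      if (cluster[j]) next
      if (compare_motifs(motifs[[i]], motifs[[j]],
                         cutoff_bits)$is_match)
        cluster[j] <- nc
    }
  }
  reps <- vapply(seq_len(nc), function(cl) {
    members <- which(cluster == cl)
    members[order(errs[members], ids[members])][1]
  }, 0L)
  list(pwms = motifs[reps], errs = errs[reps], cluster = cluster)
}

#' Merge and re-rank motif results across processing stages
#'
#' Each motif's merged err is the minimum over the stages where it was
#' evaluated; the achieving stage is recorded as `source_set`. Motifs are
#' sorted by ascending err, ties broken by smaller p, then id.
#'
#' @param results_by_set list of data.frames (columns `motif`, `err`, `p`,
#'   `cutoff`, `source_set`), one per stage.
#' @return merged data.frame with a `rank` column.
#' @export
rerank_across_sets <- function(results_by_set) {
  all <- do.call(rbind, results_by_set)
  if (is.null(all) || !nrow(all))
    return(data.frame(motif = character(), err = numeric(), p = numeric(),
                      cutoff = numeric(), source_set = character(),
                      rank = integer()))
  rows <- lapply(split(all, all$motif), function(d) {
    d <- d[order(d$err, d$p), , drop = FALSE]
    d[1, c("motif", "err", "p", "cutoff", "source_set"), drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$err, out$p, out$motif), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Site enrichment of motifs in a region set (Fisher exact test)
#'
#' Counts sequences containing at least one site (best score at or above
#' the motif's fixed, pre-trained cutoff) in foreground vs background
#' regions, and computes the one-sided hypergeometric tail p-value of the
#' 2x2 table, Bonferroni-multiplied by the number of motifs tested.
#'
#' @param motifs list of [pwm] objects.
#' @param fg_regions,bg_regions [masked_seqs] region sets.
#' @param cutoffs numeric vector of per-motif site-score cutoffs (from
#'   training), parallel to `motifs`.
#' @param bg optional background base composition (defaults to the
#'   background regions' composition).
#' @return data.frame with `motif`, `fg_hits`, `bg_hits`, `p_raw`,
#'   `p_bonferroni`.
#' @export
region_enrichment_fet <- function(motifs, fg_regions, bg_regions, cutoffs,
                                  bg = NULL) {
  if (!length(fg_regions) || !length(bg_regions))
    stop("empty region set", call. = FALSE)
  stopifnot(length(motifs) == length(cutoffs))
  if (is.null(bg)) bg <- base_composition(bg_regions)
  nf <- length(fg_regions); nb <- length(bg_regions)
  rows <- lapply(seq_along(motifs), function(m) {
    a <- sum(scan_best_site(fg_regions, motifs[[m]], bg) >= cutoffs[m])
    b <- sum(scan_best_site(bg_regions, motifs[[m]], bg) >= cutoffs[m])
    p <- stats::phyper(a - 1, a + b, nf + nb - a - b, nf,
                       lower.tail = FALSE)
    data.frame(motif = motifs[[m]]$id, fg_hits = a, bg_hits = b,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_raw * length(motifs), 1)
  out
}
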