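## De novo discriminative PWM discovery: an enumerative coarse search over a
## small discretised column space, seeded from words over-represented in the
## foreground, followed by hill-climbing refinement of single columns. The
## objective throughout is the classification relative-error rate, with the
## site cutoff re-optimised after every accepted step.

#' Discretised column alphabet for the coarse search lattice
#'
#' The lattice contains the four point-mass columns, the six equal mixtures
#' of two point masses, and the uniform column, each smoothed so all
#' entries are positive.
#'
#' @param eps smoothing floor.
#' @return list with `vectors` (4 x K matrix of probability columns) and
#'   `granularity`.
#' @export
column_alphabet <- function(eps = 0.05) {
  cols <- list()
  for (i in 1:4) {
    v <- rep(0, 4); v[i] <- 1
    cols[[length(cols) + 1]] <- v
  }
  for (i in 1:3) for (j in (i + 1):4) {
    v <- rep(0, 4); v[c(i, j)] <- 0.5
    cols[[length(cols) + 1]] <- v
  }
  cols[[length(cols) + 1]] <- rep(0.25, 4)
  m <- do.call(cbind, cols)
  m <- m * (1 - 4 * eps) + eps
  rownames(m) <- DNA_BASES
  list(vectors = m, granularity = 2L)
}

# decode a word code (big-endian base-4) to base indices
decode_word <- function(code, L) {
  out <- integer(L)
  for (j in L:1) {
    out[j] <- code %% 4 + 1
    code <- code %/% 4
  }
  out
}

# top over-represented foreground words by smoothed fg/bg frequency ratio
overrepresented_words <- function(fg, bg_set, length, n_words) {
  cf <- cpp_count_words(fg$seq, fg$mask, length)
  cb <- cpp_count_words(bg_set$seq, bg_set$mask, length)
  tf <- sum(cf); tb <- sum(cb)
  if (tf == 0) stop("no unmasked window of length ", length,
                    " in the foreground", call. = FALSE)
  score <- (cf / max(tf, 1) + 1e-9) / (cb / max(tb, 1) + 1e-9)
  score[cf == 0] <- 0
  ord <- order(-score, seq_along(score))  # ties: lexicographic word order
  codes <- ord[seq_len(min(n_words, sum(score > 0)))] - 1L
  lapply(codes, decode_word, L = length)
}

#' Coarse discriminative search for candidate PWMs
#'
#' Enumerates candidate matrices seeded from the foreground's most
#' over-represented words of the requested length (each word mapped to its
#' smoothed point-mass lattice matrix), evaluates every candidate by its
#' minimised relative error against the background, and returns the top
#' `beam` candidates. Deterministic and independent of sequence order.
#'
#' @param fg,bg_set [masked_seqs] sets at the same stage.
#' @param length motif length.
#' @param alphabet a [column_alphabet()]; its point-mass smoothing is used
#'   for the word matrices.
#' @param beam number of candidates to return.
#' @param n_seed_words number of over-represented words to evaluate.
#' @param bg optional background base composition.
#' @return list of candidates, each a list with `pwm`, `err`, `cutoff`,
#'   sorted by ascending err (ties by consensus word).
#' @export
coarse_search <- function(fg, bg_set, length, alphabet = column_alphabet(),
                          beam = 50L, n_seed_words = 500L, bg = NULL) {
  if (fg$stage != bg_set$stage)
    stop("stage labels differ", call. = FALSE)
  if (is.null(bg)) bg <- base_composition(bg_set)
  eps <- min(alphabet$vectors)
  core <- 1 - 3 * eps
  words <- overrepresented_words(fg, bg_set, length, n_seed_words)
  labels <- c(rep(TRUE, base::length(fg)), rep(FALSE, base::length(bg_set)))
  cands <- lapply(words, function(w) {
    mat <- matrix(eps, 4, length)
    mat[cbind(w, seq_len(length))] <- core
    p <- pwm(mat, id = paste0("dn_", paste(DNA_BASES[w], collapse = "")))
    sc <- c(scan_best_site(fg, p, bg), scan_best_site(bg_set, p, bg))
    me <- cpp_min_err(sc, labels)
    list(pwm = p, err = me$err, cutoff = me$cutoff)
  })
  ord <- order(vapply(cands, `[[`, 0, "err"),
               vapply(cands, function(c) c$pwm$id, ""))
  cands[ord[seq_len(min(beam, base::length(cands)))]]
}

#' Local refinement of a candidate PWM
#'
#' Steepest-descent hill climbing over single-column replacements drawn
#' from the column alphabet: at each iteration every (column, replacement)
#' pair is evaluated, the best strictly err-reducing change is accepted
#' (ties broken by column index then alphabet order), and the site cutoff
#' is re-optimised. Terminates at a local optimum or after `max_iter`
#' iterations.
#'
#' @param cand candidate list (`pwm`, `err`, `cutoff`) from
#'   [coarse_search()].
#' @param fg,bg_set [masked_seqs] sets.
#' @param alphabet a [column_alphabet()].
#' @param max_iter iteration cap.
#' @param bg optional background base composition.
#' @return refined candidate list (`pwm`, `err`, `cutoff`, `iterations`).
#' @export
refine <- function(cand, fg, bg_set, alphabet = column_alphabet(),
                   max_iter = 100L, bg = NULL) {
  if (is.null(bg)) bg <- base_composition(bg_set)
  labels <- c(rep(TRUE, length(fg)), rep(FALSE, length(bg_set)))
  seqs <- c(fg$seq, bg_set$seq)
  masks <- c(fg$mask, bg_set$mask)
  cur <- cand
  A <- alphabet$vectors
  iters <- 0L
  repeat {
    if (iters >= max_iter) break
    step <- cpp_refine_step(seqs, masks, cur$pwm$mat, A, bg, labels)
    if (step$j == 0L || step$err >= cur$err - 1e-12) break
    mat <- cur$pwm$mat
    mat[, step$j] <- A[, step$k]
    cur <- list(pwm = pwm(mat, id = cur$pwm$id), err = step$err,
                cutoff = step$cutoff)
    iters <- iters + 1L
  }
  cur$iterations <- iters
  cur
}

#' De novo discriminative motif discovery
#'
#' For each motif length, runs the coarse search and refines the top
#' candidates; refined motifs are pooled over lengths, merged at the 1.0-bit
#' comparison cutoff (keeping each cluster's best classifier), and ranked by
#' ascending err. When `significance = TRUE` the de novo permutation null is
#' run and p-values attached; motifs failing `significance_alpha` are
#' flagged, not removed (reporting with or without the p-value pruning is a
#' presentation choice).
#'
#' @param fg,bg_set [masked_seqs] sets at the same stage; at least 5 (and
#'   preferably 30 or more) foreground sequences.
#' @param config a [run_config()].
#' @param significance run the de novo permutation null.
#' @param bg optional background base composition.
#' @return list with `motifs` (data.frame: `motif`, `err`, `cutoff`,
#'   `length`, and `p`/`significant` when requested), `pwms` (named list of
#'   the discovered [pwm]s) and `lengths_searched`.
#' @export
discover <- function(fg, bg_set, config = run_config(),
                     significance = FALSE, bg = NULL) {
  if (length(fg) < 5)
    stop("refusing de novo discovery with fewer than 5 foreground ",
         "sequences", call. = FALSE)
  if (is.null(bg)) bg <- base_composition(bg_set)
  alphabet <- column_alphabet()
  run_once <- function(f, b) {
    cands <- list()
    for (L in config$motif_lengths) {
      cs <- tryCatch(
        coarse_search(f, b, L, alphabet, beam = config$beam,
                      n_seed_words = config$seed_words, bg = bg),
        error = function(e) list())
      top <- cs[seq_len(min(config$refine_top, length(cs)))]
      cands <- c(cands, lapply(top, refine, fg = f, bg_set = b,
                               alphabet = alphabet,
                               max_iter = config$max_refine_iter, bg = bg))
    }
    if (!length(cands))
      return(data.frame(motif = character(), err = numeric(),
                        cutoff = numeric(), length = integer(),
                        stringsAsFactors = FALSE))
    merged <- merge_similar(lapply(cands, `[[`, "pwm"),
                            vapply(cands, `[[`, 0, "err"))
    keep <- match(vapply(merged$pwms, `[[`, "", "id"),
                  vapply(cands, function(c) c$pwm$id, ""))
    df <- data.frame(motif = vapply(merged$pwms, `[[`, "", "id"),
                     err = merged$errs,
                     cutoff = vapply(cands[keep], `[[`, 0, "cutoff"),
                     length = vapply(merged$pwms, pwm_length, 0L),
                     stringsAsFactors = FALSE)
    df <- df[order(df$err, df$motif), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "pwms") <- setNames(merged$pwms,
                                 vapply(merged$pwms, `[[`, "", "id"))
    df
  }
  res <- run_once(fg, bg_set)
  pwms <- attr(res, "pwms")
  if (is.null(pwms)) pwms <- list()
  if (significance && nrow(res)) {
    sig <- denovo_significance(fg, bg_set,
                               function(f, b) run_once(f, b),
                               n_perm = config$denovo_permutations,
                               seed = config$rng_seed,
                               alpha = config$significance_alpha)
    res <- sig$observed
  }
  attr(res, "pwms") <- NULL
  list(motifs = res, pwms = pwms[res$motif],
       lengths_searched = config$motif_lengths)
}
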