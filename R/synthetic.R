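## Synthetic benchmark generator. Every stage of the workflow is testable
## without external data: expression matrices with planted TF->target edges
## and TF->mediator->distal cascades, order-3 Markov promoters with planted
## PWM sites, and orthologous promoters built from conserved site islands
## with regenerated spacers and optional island reordering (binding-site
## turnover). All generators are pure functions of (spec, seed).

#' Default planted motif for benchmarks
#'
#' An 8-column AP-1-like PWM with one degenerate (two-base) column,
#' consensus `TGACTCAG`.
#'
#' @return a [pwm] object.
#' @export
planted_pwm_default <- function() {
  m <- matrix(0.05, 4, 8, dimnames = list(DNA_BASES, NULL))
  cons <- c("T", "G", "A", "C", "T", "C", "A", "G")
  for (j in seq_along(cons)) m[cons[j], j] <- 0.85
  m[, 4] <- c(0.05, 0.45, 0.45, 0.05)  # C/G degenerate column
  pwm(m, id = "planted")
}

#' Specification for the synthetic benchmark
#'
#' Defaults mirror the study conditions the workflow targets: 254
#' expression samples, one TF with 35 direct activated targets plus 10
#' TF->mediator->distal cascades, 1500-base promoters carrying the planted
#' motif in 90% of foreground sequences, five ortholog species with
#' 40-base conserved site islands at 5% per-base substitution.
#'
#' @param n_samples expression samples.
#' @param n_genes total genes in the expression matrix (noise genes fill
#'   whatever the planted structure does not use).
#' @param n_targets direct activated targets of the TF.
#' @param n_cascades number of TF->mediator->distal chains.
#' @param effect_size linear effect of the regulator on each target.
#' @param noise_sd Gaussian noise standard deviation on regulated genes.
#' @param promoter_length promoter length in bases.
#' @param planted_pwm the planted binding motif.
#' @param site_frequency fraction of foreground promoters carrying at least
#'   one planted site.
#' @param species ortholog species names.
#' @param island_length conserved island length around each site.
#' @param island_subst per-base substitution rate inside islands.
#' @param turnover_rate per-species probability that island order is
#'   permuted (binding-site turnover).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 254L, n_genes = 200L,
                           n_targets = 35L, n_cascades = 10L,
                           effect_size = 1, noise_sd = 0.5,
                           promoter_length = 1500L,
                           planted_pwm = planted_pwm_default(),
                           site_frequency = 0.9,
                           species = c("mouse", "rat", "chimp", "rhesus",
                                       "dog"),
                           island_length = 40L, island_subst = 0.05,
                           turnover_rate = 0, seed = 1L) {
  if (site_frequency < 0 || site_frequency > 1)
    stop("site_frequency must be in [0,1]", call. = FALSE)
  if (promoter_length < pwm_length(planted_pwm))
    stop("promoter shorter than the planted motif", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_targets = as.integer(n_targets),
                 n_cascades = as.integer(n_cascades),
                 effect_size = effect_size, noise_sd = noise_sd,
                 promoter_length = as.integer(promoter_length),
                 planted_pwm = planted_pwm,
                 site_frequency = site_frequency,
                 species = species,
                 island_length = as.integer(island_length),
                 island_subst = island_subst,
                 turnover_rate = turnover_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate an expression matrix with planted regulatory structure
#'
#' The TF profile is drawn i.i.d. standard normal; each direct target is a
#' linear (hence monotone) function of the TF plus Gaussian noise; each
#' cascade gives the distal gene dependence on the TF only through the
#' mediator, so the Data Processing Inequality should prune the TF->distal
#' edge. All remaining genes are independent noise.
#'
#' @param spec a [synthetic_spec()].
#' @return genes x samples matrix with attributes `tf`, `direct_targets`,
#'   `cascades` (data.frame `mediator`, `distal`).
#' @export
simulate_expression <- function(spec) {
  with_seed(substream_seed(spec$seed, "expression"), {
    n <- spec$n_samples
    tf <- "TF1"
    targets <- sprintf("T%03d", seq_len(spec$n_targets))
    meds <- if (spec$n_cascades) sprintf("M%02d", seq_len(spec$n_cascades))
      else character()
    dist <- if (spec$n_cascades) sprintf("D%02d", seq_len(spec$n_cascades))
      else character()
    n_noise <- spec$n_genes - 1L - spec$n_targets - 2L * spec$n_cascades
    if (n_noise < 0) stop("n_genes too small for the planted structure",
                          call. = FALSE)
    noise <- if (n_noise) sprintf("G%03d", seq_len(n_noise)) else character()
    genes <- c(tf, targets, meds, dist, noise)
    x_tf <- rnorm(n)
    m <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
    m[tf, ] <- x_tf
    for (g in targets)
      m[g, ] <- spec$effect_size * x_tf + rnorm(n, sd = spec$noise_sd)
    for (i in seq_len(spec$n_cascades)) {
      med <- spec$effect_size * x_tf + rnorm(n, sd = spec$noise_sd)
      m[meds[i], ] <- med
      m[dist[i], ] <- spec$effect_size * med + rnorm(n, sd = spec$noise_sd)
    }
    for (g in noise) m[g, ] <- rnorm(n)
    colnames(m) <- sprintf("S%03d", seq_len(n))
    attr(m, "tf") <- tf
    attr(m, "direct_targets") <- targets
    attr(m, "cascades") <- data.frame(mediator = meds, distal = dist,
                                      stringsAsFactors = FALSE)
    m
  })
}

# order-3 Markov model drawn once per seed: list(init = 64-context start
# probs, trans = 64 x 4 matrix)
markov_model <- function(seed) {
  with_seed(substream_seed(seed, "markov"), {
    g <- matrix(rgamma(64 * 4, shape = 5), 64, 4)
    trans <- g / rowSums(g)
    list(trans = trans)
  })
}

markov_seq <- function(n, model) {
  out <- integer(n)
  out[1:3] <- sample.int(4, 3, replace = TRUE)
  tr <- model$trans
  u <- runif(n)
  for (i in 4:n) {
    ctx <- (out[i - 3] - 1L) * 16L + (out[i - 2] - 1L) * 4L + out[i - 1]
    p <- tr[ctx, ]
    out[i] <- findInterval(u[i], cumsum(p)) + 1L
    if (out[i] > 4L) out[i] <- 4L
  }
  out
}

sample_site <- function(p) {
  apply(p$mat, 2, function(col) sample.int(4, 1, prob = col))
}

#' Simulate foreground and background promoter sets with planted sites
#'
#' Background promoters are order-3 Markov sequences; foreground promoters
#' are drawn from the same model, with one site sampled from the planted
#' PWM inserted at a uniform position (random strand) in `site_frequency`
#' of the sequences. Every insertion is recorded in the truth table.
#'
#' @param spec a [synthetic_spec()].
#' @param n_fg,n_bg numbers of foreground and background promoters.
#' @return list with `fg`, `bg` ([masked_seqs], stage `conservation-free`)
#'   and `truth` (data.frame `chrom`, `start`, `end`, `strand`, 0-based
#'   half-open, promoter-local).
#' @export
simulate_promoters <- function(spec, n_fg = 30L, n_bg = 200L) {
  model <- markov_model(spec$seed)
  L <- spec$promoter_length
  W <- pwm_length(spec$planted_pwm)
  with_seed(substream_seed(spec$seed, "promoters"), {
    bg <- lapply(seq_len(n_bg), function(i) markov_seq(L, model))
    names(bg) <- sprintf("bg%04d", seq_len(n_bg))
    fg <- lapply(seq_len(n_fg), function(i) markov_seq(L, model))
    names(fg) <- sprintf("fg%03d", seq_len(n_fg))
    truth <- list()
    for (i in seq_len(n_fg)) {
      if (runif(1) > spec$site_frequency) next
      pos <- sample.int(L - W + 1L, 1)
      strand <- sample(c("+", "-"), 1)
      site <- sample_site(spec$planted_pwm)
      if (strand == "-") site <- revcomp_code(site)
      fg[[i]][pos:(pos + W - 1L)] <- site
      truth[[length(truth) + 1L]] <-
        data.frame(chrom = names(fg)[i], start = pos - 1L,
                   end = pos + W - 1L, strand = strand,
                   stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    list(fg = masked_seqs(fg, stage = "conservation-free"),
         bg = masked_seqs(bg, stage = "conservation-free"),
         truth = truth)
  })
}

#' Simulate orthologous promoters with conserved islands and turnover
#'
#' Conserved islands are the neighbourhoods of the planted sites (or, for
#' siteless promoters, randomly placed islands), copied into each species
#' with a low per-base substitution rate; spacers are regenerated per
#' species from the Markov background. With probability `turnover_rate`, a
#' species permutes its island order, destroying linear alignability while
#' preserving island content. The emitted conservation track scores island
#' bases high only in proportion to the species that kept the original
#' order, emulating alignment-based conservation's blindness to turnover.
#'
#' @param promoter integer base-code vector (a reference promoter).
#' @param truth data.frame of planted sites in this promoter (may be
#'   empty).
#' @param spec a [synthetic_spec()].
#' @param name reference sequence name (used for seeding and output).
#' @param n_random_islands islands to place when `truth` is empty.
#' @return list with `orthologs` (a [masked_seqs]: reference first, then
#'   one entry per species), `track` (numeric conservation scores over the
#'   reference) and `islands` (data.frame `start`, `end`).
#' @export
simulate_orthologs <- function(promoter, truth, spec, name = "ref",
                               n_random_islands = 2L) {
  model <- markov_model(spec$seed)
  L <- length(promoter)
  half <- spec$island_length %/% 2L
  with_seed(substream_seed(spec$seed, paste0("orth-", name)), {
    ctr <- if (nrow(truth)) (truth$start + truth$end) %/% 2L else integer()
    # at least two islands so turnover (order permutation) is expressible
    n_extra <- max(n_random_islands - length(ctr), 0L)
    if (n_extra > 0)
      ctr <- c(ctr, sample.int(L - spec$island_length, n_extra) + half)
    ctr <- sort(ctr)
    iv <- cbind(pmax(ctr - half, 0L), pmin(ctr + half, L))
    # merge overlapping islands
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- iv[1, , drop = FALSE]
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv[r, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[r, 2])
      else merged <- rbind(merged, iv[r, , drop = FALSE])
    }
    ni <- nrow(merged)
    spacers <- cbind(c(0L, merged[, 2]), c(merged[, 1], L))
    seqs <- list()
    seqs[[name]] <- promoter
    preserved <- setNames(logical(length(spec$species)), spec$species)
    for (sp in spec$species) {
      islands <- lapply(seq_len(ni), function(r) {
        s <- promoter[(merged[r, 1] + 1):merged[r, 2]]
        sub <- runif(length(s)) < spec$island_subst
        if (any(sub))
          s[sub] <- vapply(s[sub], function(b)
            sample(setdiff(1:4, b), 1), 0L)
        s
      })
      ord <- seq_len(ni)
      permuted <- runif(1) < spec$turnover_rate && ni > 1
      if (permuted) while (identical(ord, seq_len(ni)))
        ord <- sample(ni)
      preserved[sp] <- !permuted
      parts <- list()
      for (r in seq_len(ni)) {
        sl <- spacers[r, 2] - spacers[r, 1]
        parts[[2 * r - 1]] <- if (sl > 3) markov_seq(sl, model) else
          if (sl > 0) sample.int(4, sl, replace = TRUE) else integer()
        parts[[2 * r]] <- islands[[ord[r]]]
      }
      sl <- spacers[ni + 1, 2] - spacers[ni + 1, 1]
      parts[[2 * ni + 1]] <- if (sl > 3) markov_seq(sl, model) else
        if (sl > 0) sample.int(4, sl, replace = TRUE) else integer()
      seqs[[sp]] <- unlist(parts)
    }
    frac_pres <- mean(preserved)
    track <- runif(L, 0, 0.3)
    for (r in seq_len(ni)) {
      idx <- (merged[r, 1] + 1):merged[r, 2]
      track[idx] <- frac_pres * runif(length(idx), 0.8, 1) +
        (1 - frac_pres) * runif(length(idx), 0, 0.3)
    }
    list(orthologs = masked_seqs(seqs, stage = "MCR"),
         track = track,
         islands = data.frame(start = merged[, 1], end = merged[, 2]))
  })
}
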