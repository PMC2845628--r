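## End-to-end orchestration: network inference -> target sets -> promoter
## assembly and masking -> conservation -> library evaluation and de novo
## discovery on the conservation-free and combined-conservation sets ->
## merged re-ranking. Also the synthetic-bundle writer, which emits every
## input format the pipeline reads so synthetic runs exercise the real I/O
## paths.

# convert genomic mask intervals to promoter-local (transcription
# orientation) coordinates using the intervals table from
# extract_promoters()
genomic_to_local_masks <- function(mask_df, intervals) {
  if (is.null(mask_df) || !nrow(mask_df) || !nrow(intervals))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  out <- list()
  for (g in seq_len(nrow(intervals))) {
    iv <- intervals[g, ]
    hit <- mask_df[mask_df$chrom == iv$chrom & mask_df$start < iv$end &
                     iv$start < mask_df$end, , drop = FALSE]
    if (!nrow(hit)) next
    s <- pmax(hit$start, iv$start); e <- pmin(hit$end, iv$end)
    if (iv$strand == "+") {
      ls <- s - iv$start; le <- e - iv$start
    } else {
      ls <- iv$end - e; le <- iv$end - s
    }
    out[[length(out) + 1L]] <- data.frame(chrom = iv$gene, start = ls,
                                          end = le)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer())
}

# per-gene ortholog sets assembled from per-species sequence sets
ortholog_sets <- function(ref_seqs, species_seqs) {
  sets <- list()
  for (g in names(ref_seqs)) {
    seqs <- ref_seqs$seq[g]
    masks <- ref_seqs$mask[g]
    for (sp in names(species_seqs)) {
      ss <- species_seqs[[sp]]
      if (!g %in% names(ss)) next
      seqs[[paste0(sp, ":", g)]] <- ss$seq[[g]]
      masks[[paste0(sp, ":", g)]] <- ss$mask[[g]]
    }
    sets[[g]] <- masked_seqs(seqs, masks, stage = "MCR")
  }
  sets
}

# full conservation processing of one promoter set; returns the
# combined-conservation set (or NULL when inputs are missing)
conserve_set <- function(mcr, track, orth_sets, fraction, min_species) {
  if (is.null(track) || is.null(orth_sets)) return(NULL)
  aligned <- alignment_conserved_mask(mcr, track, fraction)
  patterns <- lapply(names(mcr), function(g) {
    os <- orth_sets[[g]]
    if (is.null(os)) return(empty_patterns())
    find_sparse_patterns(os, min_species = min_species)
  })
  names(patterns) <- names(mcr)
  patt <- pattern_conserved_mask(mcr, patterns, fraction)
  combine_conservation(aligned, patt)
}

#' Run the full binding-site discovery pipeline
#'
#' Infers the bootstrap-consensus regulatory network, selects TFs with at
#' least `min_targets` activated targets, assembles and masks foreground
#' and matched background promoter sets, applies alignment- and
#' pattern-based conservation when the corresponding inputs are given,
#' evaluates the motif library and runs de novo discovery on both the
#' conservation-free and the combined-conservation sets, and merges the
#' results, re-ranking motifs by the best relative error achieved in
#' either set. Deterministic given `config$rng_seed`.
#'
#' @param config a [run_config()].
#' @param inputs named list of file paths: `expression`, `tfs`,
#'   `annotation`, `genome` (required); `masks`, `conservation`,
#'   `orthologs` (named vector of per-species FASTAs), `library`
#'   (TRANSFAC) optional.
#' @param n_background background promoters to select.
#' @param min_species minimum species support for sparse patterns.
#' @param denovo_sig attach de novo permutation p-values (runs
#'   `config$denovo_permutations` full discoveries per TF and set).
#' @return object of class `pipeline_report`: per-TF ranked motif tables,
#'   per-stage coverage statistics, the consensus network, skip log and
#'   input provenance.
#' @export
run_pipeline <- function(config, inputs, n_background = 2000L,
                         min_species = 4L, denovo_sig = FALSE) {
  need <- c("expression", "tfs", "annotation", "genome")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing inputs: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  expr <- read_expression(inputs$expression)
  tfs <- read_tf_list(inputs$tfs)
  ann <- read_annotation(inputs$annotation)
  genome <- read_sequences(inputs$genome)
  mask_df <- if (!is.null(inputs$masks)) read_bed(inputs$masks) else NULL
  library_pwms <- if (!is.null(inputs$library))
    read_motif_library(inputs$library) else list()
  species_seqs <- if (!is.null(inputs$orthologs))
    lapply(inputs$orthologs, read_sequences, stage = "MCR") else NULL

  note("network inference: ", length(tfs), " regulators, ",
       nrow(expr), " genes, ", ncol(expr), " samples, ",
       config$bootstraps, " bootstraps")
  net <- bootstrap_consensus(expr, tfs, config)
  tsets <- activated_targets(net, config$min_targets)
  for (tf in setdiff(tfs, names(tsets)))
    note("skipping TF ", tf, ": fewer than ", config$min_targets,
         " activated targets")

  excluded <- unique(c(unlist(tsets), tfs,
                       unlist(lapply(tfs, function(tf)
                         coexpression_targets(expr, tf,
                                              config$coexpr_alpha)))))
  bg_cf <- build_background(ann, genome, excluded, k = n_background,
                            seed = substream_seed(config$rng_seed,
                                                  "background"))
  note("background: ", length(bg_cf), " promoters")
  bg_mcr <- mask_regions(bg_cf, genomic_to_local_masks(
    mask_df, attr(bg_cf, "intervals")))

  seq_lens_for <- function(s) setNames(lengths(s$seq), names(s))
  bg_track <- NULL
  bg_orth <- NULL
  if (!is.null(inputs$conservation) && !is.null(species_seqs)) {
    bg_track <- read_conservation_track(inputs$conservation,
                                        seq_lens_for(bg_mcr))
    bg_orth <- ortholog_sets(bg_mcr, species_seqs)
  }
  bg_comb <- conserve_set(bg_mcr, bg_track, bg_orth,
                          config$coverage_fraction, min_species)

  per_tf <- list()
  for (tf in names(tsets)) {
    tf_seed <- substream_seed(config$rng_seed, paste0("tf-", tf))
    fg_cf <- extract_promoters(ann, genome, tsets[[tf]], quiet = TRUE)
    if (!length(fg_cf)) {
      note("skipping TF ", tf, ": no promoters extracted")
      next
    }
    note("TF ", tf, ": ", length(fg_cf), " target promoters")
    fg_mcr <- mask_regions(fg_cf, genomic_to_local_masks(
      mask_df, attr(fg_cf, "intervals")))
    fg_comb <- NULL
    if (!is.null(inputs$conservation) && !is.null(species_seqs)) {
      fg_track <- read_conservation_track(inputs$conservation,
                                          seq_lens_for(fg_mcr))
      fg_orth <- ortholog_sets(fg_mcr, species_seqs)
      fg_comb <- conserve_set(fg_mcr, fg_track, fg_orth,
                              config$coverage_fraction, min_species)
    }
    sets <- list(`conservation-free` = list(fg = fg_cf, bg = bg_cf))
    if (!is.null(fg_comb) && !is.null(bg_comb))
      sets$`combined-conservation` <- list(fg = fg_comb, bg = bg_comb)

    lib_res <- list()
    dn_res <- list()
    dn_pwms <- list()
    for (sname in names(sets)) {
      fgs <- sets[[sname]]$fg; bgs <- sets[[sname]]$bg
      if (length(library_pwms))
        lib_res[[sname]] <- library_significance(
          library_pwms, fgs, bgs, n_perm = config$library_permutations,
          seed = substream_seed(tf_seed, paste0("lib-", sname)))
      dn <- discover(fgs, bgs, config, significance = denovo_sig)
      if (nrow(dn$motifs)) {
        dn$motifs$p <- if ("p" %in% names(dn$motifs)) dn$motifs$p else
          NA_real_
        dn$motifs$source_set <- sname
        dn_res[[sname]] <- dn$motifs[, c("motif", "err", "p", "cutoff",
                                         "source_set")]
        dn_pwms[sname] <- list(dn$pwms)
      }
    }
    lib_rank <- rerank_across_sets(lib_res)
    dn_rank <- rerank_across_sets(dn_res)
    if (nrow(dn_rank) && length(library_pwms)) {
      pool <- do.call(c, unname(dn_pwms))
      dn_rank$matches_known <- vapply(dn_rank$motif, function(id) {
        p <- pool[[id]]
        any(vapply(library_pwms, function(k)
          compare_motifs(p, k)$is_match, TRUE))
      }, TRUE)
    }
    stats <- data.frame(
      stage = c("conservation-free", "MCR",
                if (!is.null(fg_comb)) "combined-conservation"),
      sequences = c(length(fg_cf), length(fg_mcr),
                    if (!is.null(fg_comb)) length(fg_comb)),
      unmasked_fraction = c(unmasked_fraction(fg_cf),
                            unmasked_fraction(fg_mcr),
                            if (!is.null(fg_comb))
                              unmasked_fraction(fg_comb)))
    per_tf[[tf]] <- list(targets = tsets[[tf]], library = lib_rank,
                         denovo = dn_rank, denovo_pwms = dn_pwms,
                         stats = stats)
  }
  structure(list(config = config, network = net, per_tf = per_tf,
                 log = log,
                 provenance = data.frame(
                   input = names(unlist(inputs)),
                   path = unname(unlist(inputs)),
                   stringsAsFactors = FALSE)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d TF(s) analysed, %d consensus edges\n",
              length(x$per_tf), nrow(x$network)))
  for (tf in names(x$per_tf)) {
    p <- x$per_tf[[tf]]
    cat(sprintf("  %s: %d targets; top de novo motif: %s\n", tf,
                length(p$targets),
                if (nrow(p$denovo)) sprintf("%s (err %.3f, %s)",
                                            p$denovo$motif[1],
                                            p$denovo$err[1],
                                            p$denovo$source_set[1])
                else "none"))
  }
  invisible(x)
}

#' Write a complete synthetic input bundle
#'
#' Generates a synthetic benchmark (expression with planted structure,
#' promoters with planted sites, orthologs with conserved islands,
#' conservation track, genome, annotation, masks, motif library) and writes
#' it in the exact formats [run_pipeline()] consumes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param n_bg number of background (noise-gene) promoters.
#' @param n_decoys decoy motifs added to the TRANSFAC library alongside the
#'   planted PWM.
#' @param with_masks write a small repeat-mask BED touching some promoters.
#' @return named list of file paths (the `inputs` argument of
#'   [run_pipeline()]) plus `truth` (planted-site BED path).
#' @export
write_synthetic_bundle <- function(spec, dir, n_bg = 100L, n_decoys = 4L,
                                   with_masks = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(spec)
  targets <- attr(expr, "direct_targets")
  sim <- simulate_promoters(spec, n_fg = length(targets), n_bg = n_bg)
  noise_genes <- grep("^G", rownames(expr), value = TRUE)
  if (n_bg > length(noise_genes))
    stop("n_bg exceeds available noise genes; increase spec$n_genes",
         call. = FALSE)
  ren <- c(setNames(targets, names(sim$fg)),
           setNames(noise_genes[seq_len(n_bg)], names(sim$bg)))
  all_prom <- masked_seqs(
    c(setNames(sim$fg$seq, ren[names(sim$fg)]),
      setNames(sim$bg$seq, ren[names(sim$bg)])),
    c(setNames(sim$fg$mask, ren[names(sim$fg)]),
      setNames(sim$bg$mask, ren[names(sim$bg)])))
  truth <- sim$truth
  truth$chrom <- unname(ren[truth$chrom])

  # orthologs + conservation track per promoter
  L <- spec$promoter_length
  orth_by_species <- lapply(spec$species, function(s) list())
  names(orth_by_species) <- spec$species
  track <- list()
  for (g in names(all_prom)) {
    os <- simulate_orthologs(all_prom$seq[[g]],
                             truth[truth$chrom == g, , drop = FALSE],
                             spec, name = g)
    track[[g]] <- os$track
    for (sp in spec$species)
      orth_by_species[[sp]][[g]] <- os$orthologs$seq[[sp]]
  }

  # genome: promoters laid head to tail on one contig, alternating strand
  model <- markov_model(spec$seed)
  glist <- list()
  ann <- list()
  off <- 0L
  spacer_len <- 200L
  gi <- 0L
  with_seed(substream_seed(spec$seed, "genome"), {
    for (g in names(all_prom)) {
      gi <- gi + 1L
      sp <- markov_seq(spacer_len, model)
      glist[[length(glist) + 1L]] <- sp
      off <- off + spacer_len
      strand <- if (gi %% 3L == 0L) "-" else "+"
      pseq <- all_prom$seq[[g]]
      gseq <- if (strand == "+") pseq else revcomp_code(pseq)
      glist[[length(glist) + 1L]] <- gseq
      tss <- if (strand == "+") off + PROMOTER_UP else off + PROMOTER_DOWN
      ann[[length(ann) + 1L]] <- data.frame(gene = g, chrom = "chr1",
                                             tss = tss, strand = strand,
                                             stringsAsFactors = FALSE)
      off <- off + L
    }
    glist[[length(glist) + 1L]] <- markov_seq(spacer_len, model)
  })
  genome_code <- unlist(glist)
  ann <- do.call(rbind, ann)

  p <- function(f) file.path(dir, f)
  write_expression(expr, p("expression.tsv"))
  writeLines(attr(expr, "tf"), p("tfs.txt"))
  utils::write.table(ann, p("annotation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sequences(masked_seqs(list(chr1 = genome_code),
                              list(chr1 = logical(length(genome_code)))),
                  p("genome.fa"))
  orth_paths <- character()
  for (sp in spec$species) {
    f <- p(paste0("orthologs_", sp, ".fa"))
    write_sequences(masked_seqs(orth_by_species[[sp]]), f)
    orth_paths[sp] <- f
  }
  write_conservation_track(cons_track(track), p("conservation.bedGraph"))
  decoys <- with_seed(substream_seed(spec$seed, "decoys"), {
    lapply(seq_len(n_decoys), function(i)
      word_pwm(paste(sample(DNA_BASES, 8, replace = TRUE), collapse = ""),
               core = 0.8, id = sprintf("DECOY%02d", i)))
  })
  write_transfac(c(list(spec$planted_pwm), decoys), p("library.transfac"))
  if (nrow(truth)) {
    truth$name <- "planted_site"
    write_bed(truth, p("truth.bed"))
  }
  masks_path <- NULL
  if (with_masks) {
    some <- utils::head(names(all_prom), 3)
    iv <- ann[match(some, ann$gene), ]
    mdf <- data.frame(chrom = "chr1",
                      start = ifelse(iv$strand == "+", iv$tss - 990L,
                                     iv$tss + 940L),
                      end = ifelse(iv$strand == "+", iv$tss - 940L,
                                   iv$tss + 990L),
                      name = "repeat")
    masks_path <- p("masks.bed")
    write_bed(mdf, masks_path)
  }
  out <- list(expression = p("expression.tsv"), tfs = p("tfs.txt"),
              annotation = p("annotation.tsv"), genome = p("genome.fa"),
              conservation = p("conservation.bedGraph"),
              orthologs = orth_paths,
              library = p("library.transfac"))
  if (!is.null(masks_path)) out$masks <- masks_path
  out$truth <- if (nrow(truth)) p("truth.bed") else NULL
  out
}
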