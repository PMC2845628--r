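## Promoter set assembly: [-1000, +500) windows around annotated TSSs in
## transcription orientation, repeat/coding-exon masking (MCR), and the
## matched background promoter set.

PROMOTER_UP <- 1000L
PROMOTER_DOWN <- 500L
PROMOTER_LEN <- PROMOTER_UP + PROMOTER_DOWN

# genomic window for one TSS; 0-based half-open
promoter_interval <- function(tss, strand) {
  if (strand == "+") c(tss - PROMOTER_UP, tss + PROMOTER_DOWN)
  else c(tss - PROMOTER_DOWN, tss + PROMOTER_UP)
}

#' Extract promoter sequences for a target gene set
#'
#' Builds one 1500-base promoter per retained gene, covering
#' `[-1000, +500)` around the TSS in transcription orientation (minus-strand
#' promoters are reverse-complemented so position 0 is the upstream end).
#' Genes with multiple annotated TSSs use the 5'-most TSS in transcription
#' orientation. Promoters whose genomic windows intersect are resolved
#' deterministically by keeping the gene earlier in lexicographic id order.
#' Windows extending beyond a contig are dropped (default) or padded with
#' masked `N` bases.
#'
#' @param annotations TSS table (`gene`, `chrom`, `tss`, `strand`), see
#'   [read_annotation()].
#' @param genome a [masked_seqs] object holding the contig sequences.
#' @param targets character vector of gene ids.
#' @param short_promoters `"drop"` or `"pad"`.
#' @param quiet suppress skip messages.
#' @return a [masked_seqs] object at stage `conservation-free`, with an
#'   `intervals` attribute recording the genomic windows used.
#' @export
extract_promoters <- function(annotations, genome, targets,
                              short_promoters = c("drop", "pad"),
                              quiet = FALSE) {
  short_promoters <- match.arg(short_promoters)
  note <- function(...) if (!quiet) message(...)
  rows <- lapply(sort(unique(targets)), function(g) {
    a <- annotations[annotations$gene == g, , drop = FALSE]
    if (!nrow(a)) {
      note("skipping ", g, ": no annotated TSS")
      return(NULL)
    }
    a <- if (a$strand[1] == "+") a[which.min(a$tss), ] else
      a[which.max(a$tss), ]
    a
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows))
    return(structure(masked_seqs(list(), list()),
                     intervals = data.frame()))
  kept <- list()
  ivs <- list()
  for (r in seq_len(nrow(rows))) {
    g <- rows$gene[r]
    ch <- rows$chrom[r]
    if (!ch %in% names(genome))
      stop("unknown contig '", ch, "' for gene ", g, call. = FALSE)
    clen <- length(genome$seq[[ch]])
    iv <- promoter_interval(rows$tss[r], rows$strand[r])
    if (iv[1] < 0 || iv[2] > clen) {
      if (short_promoters == "drop") {
        note("skipping ", g, ": window outside contig")
        next
      }
    }
    overlap <- FALSE
    for (k in ivs)
      if (k$chrom == ch && iv[1] < k$end && k$start < iv[2]) {
        overlap <- TRUE
        break
      }
    if (overlap) {
      note("skipping ", g, ": promoter intersects an earlier gene")
      next
    }
    lo <- max(iv[1], 0L)
    hi <- min(iv[2], clen)
    code <- genome$seq[[ch]][(lo + 1):hi]
    mask <- genome$mask[[ch]][(lo + 1):hi]
    if (short_promoters == "pad") {
      padl <- lo - iv[1]
      padr <- iv[2] - hi
      code <- c(rep(0L, padl), code, rep(0L, padr))
      mask <- c(rep(TRUE, padl), mask, rep(TRUE, padr))
    }
    if (rows$strand[r] == "-") {
      code <- revcomp_code(code)
      mask <- rev(mask)
    }
    kept[[g]] <- list(code = code, mask = mask)
    ivs[[g]] <- list(chrom = ch, start = iv[1], end = iv[2],
                     strand = rows$strand[r])
  }
  seqs <- lapply(kept, `[[`, "code")
  masks <- lapply(kept, `[[`, "mask")
  out <- masked_seqs(seqs, masks, stage = "conservation-free")
  attr(out, "intervals") <- if (length(ivs))
    data.frame(gene = names(ivs),
               chrom = vapply(ivs, `[[`, "", "chrom"),
               start = vapply(ivs, `[[`, 0, "start"),
               end = vapply(ivs, `[[`, 0, "end"),
               strand = vapply(ivs, `[[`, "", "strand"),
               row.names = NULL, stringsAsFactors = FALSE)
    else data.frame()
  out
}

#' Mask intervals in a promoter set
#'
#' Applies repeat/coding-exon masks expressed in promoter-local 0-based
#' half-open coordinates. Overlapping intervals mask their union; intervals
#' beyond sequence bounds are clipped with a warning. The result carries the
#' `MCR` stage label.
#'
#' @param seqs a [masked_seqs] object.
#' @param masks data.frame with `chrom` (promoter name), `start`, `end`.
#' @param stage stage label for the result.
#' @return a [masked_seqs] object.
#' @export
mask_regions <- function(seqs, masks, stage = "MCR") {
  out <- seqs
  clipped <- FALSE
  if (!is.null(masks) && nrow(masks)) {
    for (r in seq_len(nrow(masks))) {
      nm <- masks$chrom[r]
      if (!nm %in% names(out)) next
      n <- length(out$mask[[nm]])
      lo <- max(masks$start[r], 0L)
      hi <- min(masks$end[r], n)
      if (lo != masks$start[r] || hi != masks$end[r]) clipped <- TRUE
      if (hi > lo) out$mask[[nm]][(lo + 1):hi] <- TRUE
    }
  }
  if (clipped) warning("mask interval(s) clipped to sequence bounds")
  set_stage(out, stage)
}

#' Build the background promoter set
#'
#' Selects `k` genes at random among annotated genes outside `excluded`,
#' keeping only promoters whose genomic windows are pairwise non-overlapping
#' (and non-overlapping with any window in `avoid`). The same seed always
#' yields the same selection. Downstream processing (MCR masking,
#' conservation) must be applied to the background exactly as to the
#' foreground; this function only performs the selection and extraction.
#'
#' @param annotations TSS table.
#' @param genome a [masked_seqs] object of contigs.
#' @param excluded character vector of gene ids never to select (all
#'   foreground target and co-expression genes).
#' @param k number of background promoters wanted.
#' @param seed integer seed for the selection.
#' @param avoid optional data.frame of genomic windows (`chrom`, `start`,
#'   `end`) the background must not intersect.
#' @return a [masked_seqs] object (stage `conservation-free`) with an
#'   `intervals` attribute.
#' @export
build_background <- function(annotations, genome, excluded, k = 2000L,
                             seed = 1L, avoid = NULL) {
  eligible <- sort(setdiff(unique(annotations$gene), excluded))
  if (!length(eligible)) {
    warning("no eligible background genes")
    return(structure(masked_seqs(list(), list()), intervals = data.frame()))
  }
  ord <- with_seed(seed, sample(eligible))
  kept <- character()
  ivs <- if (!is.null(avoid) && nrow(avoid))
    avoid[, c("chrom", "start", "end"), drop = FALSE]
    else data.frame(chrom = character(), start = numeric(), end = numeric())
  for (g in ord) {
    if (length(kept) >= k) break
    a <- annotations[annotations$gene == g, , drop = FALSE]
    a <- if (a$strand[1] == "+") a[which.min(a$tss), ] else
      a[which.max(a$tss), ]
    if (!a$chrom %in% names(genome)) next
    iv <- promoter_interval(a$tss, a$strand)
    if (iv[1] < 0 || iv[2] > length(genome$seq[[a$chrom]])) next
    hit <- ivs$chrom == a$chrom & ivs$start < iv[2] & iv[1] < ivs$end
    if (any(hit)) next
    kept <- c(kept, g)
    ivs <- rbind(ivs, data.frame(chrom = a$chrom, start = iv[1],
                                 end = iv[2]))
  }
  if (length(kept) < k)
    warning("only ", length(kept), " of ", k,
            " requested background promoters available")
  extract_promoters(annotations, genome, kept, quiet = TRUE)
}
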