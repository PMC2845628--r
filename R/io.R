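## Readers and writers for the external formats the pipeline consumes and
## emits. Sequence files are soft-masked FASTA (masked bases lowercase, N
## always masked); intervals travel as BED (0-based half-open on disk,
## promoter-local names allowed); conservation scores as wiggle/bedGraph;
## motifs as TRANSFAC flat files or MEME minimal format; tables as TSV.

#' Read a soft-masked FASTA file into a masked sequence set
#'
#' Lowercase bases and `N` are recorded as masked positions. Names must be
#' unique; order is preserved.
#'
#' @param path FASTA file.
#' @param stage processing-stage label to attach.
#' @return a [masked_seqs] object.
#' @export
read_sequences <- function(path, stage = "conservation-free") {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate sequence name '", dup[1], "' in ", path, call. = FALSE)
  chars <- as.character(ss)
  names(chars) <- nm
  masked_seqs(chars, stage = stage)
}

#' Write a masked sequence set as soft-masked FASTA
#'
#' Masked bases are written lowercase (unknown bases as `n`).
#'
#' @param x a [masked_seqs] object.
#' @param path output file.
#' @export
write_sequences <- function(x, path) {
  ss <- Biostrings::BStringSet(as.character(x))
  names(ss) <- names(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## ---- TRANSFAC / MEME motif formats ----------------------------------------

#' Read a TRANSFAC matrix flat file into a PWM library
#'
#' Records are delimited by `AC`/`ID` ... `//`. Per-position counts for
#' A, C, G, T are converted to probabilities with a pseudocount of 0.5 per
#' base per column. Accessions are retained as motif ids.
#'
#' @param path TRANSFAC matrix file.
#' @param pseudocount added to each base count per column before
#'   normalisation.
#' @return list of [pwm] objects, in file order.
#' @export
read_motif_library <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty motif library: ", path)
    return(list())
  }
  term <- grep("^//", lines)
  if (!length(term) || max(term) < length(lines))
    stop("missing // terminator in ", path, call. = FALSE)
  recs <- split(lines, cumsum(c(TRUE, grepl("^//", utils::head(lines, -1)))))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    if (!length(rec)) next
    ac <- sub("^AC\\s+", "", grep("^AC\\s", rec, value = TRUE))
    id <- sub("^ID\\s+", "", grep("^ID\\s", rec, value = TRUE))
    acc <- if (length(ac)) ac[1] else if (length(id)) id[1] else
      paste0("motif_", length(out) + 1L)
    rows <- grep("^[0-9]+\\s", rec, value = TRUE)
    if (!length(rows)) next
    counts <- t(vapply(rows, function(r) {
      f <- strsplit(trimws(r), "\\s+")[[1]]
      as.numeric(f[2:5])
    }, numeric(4)))
    if (anyNA(counts)) stop("malformed count row in record ", acc,
                            call. = FALSE)
    if (any(counts < 0)) stop("negative count in record ", acc,
                              call. = FALSE)
    mat <- t(counts) + pseudocount
    out[[length(out) + 1L]] <- pwm(sweep(mat, 2, colSums(mat), "/"), id = acc)
  }
  out
}

#' Write PWMs as a TRANSFAC matrix flat file
#'
#' @param pwms list of [pwm] objects.
#' @param path output file.
#' @param scale counts are written as probabilities times `scale`.
#' @param meta optional character vector of per-motif comment lines (written
#'   as `CC` fields).
#' @export
write_transfac <- function(pwms, path, scale = 100, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    writeLines(c(paste("AC", p$id), "XX",
                 paste("ID", p$id), "XX",
                 if (!is.null(meta)) c(paste("CC", meta[i]), "XX"),
                 "P0\tA\tC\tG\tT"), con)
    for (j in seq_len(ncol(p$mat))) {
      v <- formatC(p$mat[, j] * scale, format = "f", digits = 3)
      writeLines(paste(c(sprintf("%02d", j), v,
                         DNA_BASES[which.max(p$mat[, j])]),
                       collapse = "\t"), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms list of [pwm] objects.
#' @param path output file.
#' @param bg background base frequencies (A, C, G, T).
#' @export
write_meme <- function(pwms, path, bg = rep(0.25, 4)) {
  bg <- bg / sum(bg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, bg), collapse = " "),
               ""), con)
  for (p in pwms) {
    writeLines(c(paste("MOTIF", p$id),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         ncol(p$mat))), con)
    for (j in seq_len(ncol(p$mat)))
      writeLines(paste(sprintf("%.6f", p$mat[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

## ---- conservation tracks ---------------------------------------------------

#' Read per-base conservation scores from a wiggle/bedGraph file
#'
#' Scores must lie in `[0, 1]`; coordinates are promoter-local (sequence
#' names match the promoter set). Positions without a record get score 0.
#' Overlapping records follow last-writer-wins with a warning.
#'
#' @param path wiggle or bedGraph file.
#' @param seq_lengths named integer vector of sequence lengths.
#' @return a [cons_track] object.
#' @export
read_conservation_track <- function(path, seq_lengths) {
  fmt <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE))
    "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  sc <- as.numeric(S4Vectors::mcols(gr)$score)
  if (length(sc) && any(sc < 0 | sc > 1))
    stop("conservation score outside [0, 1] at record ",
         which(sc < 0 | sc > 1)[1], " of ", path, call. = FALSE)
  scores <- lapply(seq_lengths, function(n) numeric(n))
  names(scores) <- names(seq_lengths)
  covered <- lapply(seq_lengths, function(n) logical(n))
  overlap <- FALSE
  if (length(gr)) {
    chs <- as.character(GenomicRanges::seqnames(gr))
    st <- GenomicRanges::start(gr)  # 1-based after import
    en <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) {
      ch <- chs[i]
      if (!ch %in% names(scores)) next
      idx <- st[i]:min(en[i], seq_lengths[[ch]])
      if (any(covered[[ch]][idx])) overlap <- TRUE
      scores[[ch]][idx] <- sc[i]
      covered[[ch]][idx] <- TRUE
    }
  }
  if (overlap)
    warning("overlapping conservation records in ", path,
            "; last record wins")
  cons_track(scores)
}

#' Write a conservation track as bedGraph
#' @param track a [cons_track] object.
#' @param path output file.
#' @export
write_conservation_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(track$scores)) {
    s <- track$scores[[nm]]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- c(0L, utils::head(ends, -1))
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", nm, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

## ---- BED intervals ---------------------------------------------------------

#' Read a BED file of intervals
#'
#' @param path BED file (3-6 columns).
#' @return data.frame with `chrom`, `start` (0-based), `end` (half-open) and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- mc$name
  if (!is.null(mc$score)) df$score <- mc$score
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands != "*")) df$strand <- strands
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start` (0-based), `end` and optional
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- cbind(df$chrom, df$start, df$end,
                if (!is.null(df$name)) df$name else ".",
                if (!is.null(df$score)) df$score else 0,
                if (!is.null(df$strand)) df$strand else ".")
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- tables ----------------------------------------------------------------

#' Read a gene expression matrix from TSV
#'
#' Genes as rows (first column holds gene identifiers), header holds sample
#' identifiers. Fails on missing values, duplicated gene ids or fewer than
#' two samples.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  if (anyNA(m)) stop("missing values in expression matrix", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  m
}

#' Write a gene expression matrix as TSV
#' @param m numeric matrix, genes x samples.
#' @param path output file.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF list (one identifier per line)
#' @param path text file.
#' @return character vector.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a TSS annotation table
#'
#' TSV with columns `gene`, `chrom`, `tss` (0-based base coordinate of the
#' transcription start site) and `strand` (`+`/`-`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  df
}

#' Write a network edge table as TSV
#' @param edges data.frame with columns `tf`, `target`, `mi`, `sign`,
#'   `support`, `consensus_p`.
#' @param path output file.
#' @export
write_network <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
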