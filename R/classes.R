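#' @useDynLib dismotif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pt quantile rnorm runif sd setNames rbinom
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

STAGE_LABELS <- c("conservation-free", "MCR", "alignment-conserved",
                  "pattern-conserved", "combined-conservation", "background")

## ---- sequence encoding -----------------------------------------------------

# Encode a character DNA string: integer codes 1..4 for ACGT, 0 for N.
# Lowercase letters and N are recorded as masked.
encode_seq <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  upper <- toupper(ch)
  code <- match(upper, DNA_BASES)
  bad <- is.na(code) & upper != "N"
  if (any(bad)) {
    stop("non-nucleotide symbol '", ch[which(bad)[1]], "' at position ",
         which(bad)[1], call. = FALSE)
  }
  code[is.na(code)] <- 0L
  mask <- (ch != upper) | upper == "N"
  list(code = as.integer(code), mask = mask)
}

decode_seq <- function(code, mask) {
  ch <- c("N", DNA_BASES)[code + 1L]
  ch[mask] <- tolower(ch[mask])
  paste(ch, collapse = "")
}

revcomp_code <- function(code) {
  out <- rev(code)
  ifelse(out == 0L, 0L, 5L - out)
}

#' Construct a masked sequence set
#'
#' The central sequence container: named DNA sequences stored as integer
#' base codes together with a per-base mask bitmap and a processing-stage
#' label. Masked positions are excluded from all scanning and discovery;
#' any window overlapping a masked base is skipped.
#'
#' @param seqs named list of integer base-code vectors (1..4 = ACGT, 0 = N),
#'   or a named character vector of DNA strings (lowercase / N = masked).
#' @param masks named list of logical vectors, one per sequence. Ignored when
#'   `seqs` is character (masking is taken from case/N).
#' @param stage processing-stage label, one of
#'   `"conservation-free"`, `"MCR"`, `"alignment-conserved"`,
#'   `"pattern-conserved"`, `"combined-conservation"`, `"background"`.
#' @return an object of class `masked_seqs`.
#' @export
masked_seqs <- function(seqs, masks = NULL, stage = "conservation-free") {
  stage <- match.arg(stage, STAGE_LABELS)
  if (is.character(seqs)) {
    enc <- lapply(seqs, encode_seq)
    masks <- lapply(enc, `[[`, "mask")
    seqs <- lapply(enc, `[[`, "code")
  }
  nm <- names(seqs)
  if (length(seqs) && (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
    stop("sequences must have unique names", call. = FALSE)
  if (is.null(masks)) masks <- lapply(seqs, function(s) s == 0L)
  stopifnot(length(masks) == length(seqs))
  masks <- lapply(seq_along(seqs), function(i) {
    m <- as.logical(masks[[i]])
    stopifnot(length(m) == length(seqs[[i]]))
    m | seqs[[i]] == 0L
  })
  names(masks) <- nm
  structure(list(seq = seqs, mask = masks, stage = stage),
            class = "masked_seqs")
}

#' @export
length.masked_seqs <- function(x) length(x$seq)

#' @export
names.masked_seqs <- function(x) names(x$seq)

#' @export
`[.masked_seqs` <- function(x, i) {
  masked_seqs(x$seq[i], x$mask[i], stage = x$stage)
}

#' @export
print.masked_seqs <- function(x, ...) {
  lens <- lengths(x$seq)
  mfrac <- if (length(x)) sum(vapply(x$mask, sum, 0L)) / sum(lens) else NA
  cat(sprintf("masked_seqs: %d sequences, stage '%s'\n", length(x), x$stage))
  if (length(x))
    cat(sprintf("  lengths %d..%d, masked fraction %.3f\n",
                min(lens), max(lens), mfrac))
  invisible(x)
}

#' @export
as.character.masked_seqs <- function(x, ...) {
  vapply(seq_along(x$seq),
         function(i) decode_seq(x$seq[[i]], x$mask[[i]]), "")
}

# fraction of bases that are unmasked, per sequence or overall
unmasked_fraction <- function(x, per_seq = FALSE) {
  f <- vapply(x$mask, function(m) mean(!m), 0)
  if (per_seq) f else sum(vapply(x$mask, function(m) sum(!m), 0)) /
    sum(lengths(x$mask))
}

set_stage <- function(x, stage) {
  x$stage <- match.arg(stage, STAGE_LABELS)
  x
}

## ---- PWM -------------------------------------------------------------------

#' Construct a position weight matrix
#'
#' A PWM is a column-stochastic base-probability matrix over \{A,C,G,T\}
#' modelling a binding motif. Columns are renormalised and, when any entry is
#' zero, smoothed with `eps` so all probabilities are strictly positive.
#'
#' @param mat numeric 4 x L matrix (rows A, C, G, T) of base probabilities or
#'   non-negative weights; columns are normalised to sum to one.
#' @param id motif identifier.
#' @param eps smoothing floor applied when a column contains a zero.
#' @return an object of class `pwm` with elements `id` and `mat`.
#' @export
pwm <- function(mat, id = "motif", eps = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A,C,G,T)", call. = FALSE)
  if (any(mat < 0) || any(!is.finite(mat)))
    stop("PWM entries must be finite and non-negative", call. = FALSE)
  if (any(mat == 0)) mat <- mat + eps
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- DNA_BASES
  structure(list(id = as.character(id), mat = mat), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%d columns), consensus %s\n",
              x$id, ncol(x$mat), pwm_consensus(x)))
  invisible(x)
}

pwm_length <- function(p) ncol(p$mat)

#' Consensus string of a PWM (most probable base per column)
#' @param p a [pwm] object.
#' @return character scalar.
#' @export
pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(p$mat, 2, which.max)], collapse = "")
}

pwm_revcomp <- function(p) {
  pwm(p$mat[4:1, rev(seq_len(ncol(p$mat))), drop = FALSE], id = p$id)
}

# log2-odds matrix against a background composition
pwm_log_odds <- function(p, bg = rep(0.25, 4)) {
  bg <- bg / sum(bg)
  log2(p$mat / bg)
}

#' PWM from a consensus word
#'
#' Builds a PWM whose columns put probability `core` on the word's base and
#' spread the remainder evenly over the other three bases.
#'
#' @param word DNA word (A/C/G/T).
#' @param core probability assigned to the consensus base per column.
#' @param id motif identifier.
#' @return a [pwm] object.
#' @export
word_pwm <- function(word, core = 0.85, id = word) {
  code <- match(strsplit(toupper(word), "")[[1]], DNA_BASES)
  stopifnot(!anyNA(code))
  mat <- matrix((1 - core) / 3, 4, length(code))
  mat[cbind(code, seq_along(code))] <- core
  pwm(mat, id = id)
}

## ---- conservation track ----------------------------------------------------

#' Construct a conservation track
#'
#' Per-base conservation scores in `[0,1]` over a set of named sequences
#' (promoter-local coordinates).
#'
#' @param scores named list of numeric vectors, each in `[0,1]`.
#' @return an object of class `cons_track`.
#' @export
cons_track <- function(scores) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  for (s in scores)
    if (any(s < 0 | s > 1 | !is.finite(s)))
      stop("conservation scores must lie in [0, 1]", call. = FALSE)
  structure(list(scores = scores), class = "cons_track")
}

#' @export
print.cons_track <- function(x, ...) {
  cat(sprintf("cons_track: %d sequences, %d bases\n",
              length(x$scores), sum(lengths(x$scores))))
  invisible(x)
}

## ---- RNG plumbing ----------------------------------------------------------

# Deterministic substream seed derived from a base seed and a tag, so per-TF
# (or per-stage) results do not depend on processing order.
substream_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(paste0(tag))) h <- (h * 131 + k) %% 2147483647
  as.integer(((seed %% 2147483647) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
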