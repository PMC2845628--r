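# Independent brute-force oracles and small fixture generators used across
# the suite. Oracles are written as plain loops so they share no code path
# with the package implementations they check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

random_seqs <- function(k, n, prefix = "s") {
  x <- vapply(seq_len(k), function(i) random_dna(n), "")
  names(x) <- paste0(prefix, seq_len(k))
  masked_seqs(x)
}

random_pwm <- function(L, id = "rp") {
  m <- matrix(rgamma(4 * L, 1), 4, L)
  pwm(m, id = id)
}

# ---- brute-force best-site scan -------------------------------------------
oracle_best_site <- function(seq_chr, p, bg = rep(0.25, 4)) {
  ch <- strsplit(seq_chr, "")[[1]]
  L <- ncol(p$mat)
  n <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- -Inf
  if (n >= L) for (i in 1:(n - L + 1)) {
    win <- ch[i:(i + L - 1)]
    if (any(!win %in% BASES)) next
    sF <- 0; sR <- 0
    for (j in 1:L) {
      bF <- win[j]
      bR <- comp[[win[L - j + 1]]]
      sF <- sF + log2(p$mat[bF, j] / bg[match(bF, BASES)])
      sR <- sR + log2(p$mat[bR, j] / bg[match(bR, BASES)])
    }
    best <- max(best, sF, sR)
  }
  best
}

# ---- exhaustive cutoff enumeration for relative error ----------------------
oracle_min_err <- function(scores_fg, scores_bg) {
  cands <- c(sort(unique(c(scores_fg, scores_bg))), Inf)
  cands <- cands[is.finite(cands) | cands == Inf]
  best <- Inf
  for (cut in cands) {
    fpr <- mean(scores_bg >= cut)
    fnr <- mean(scores_fg < cut)
    best <- min(best, (fpr + fnr) / 2)
  }
  best
}

# ---- exhaustive triangle enumeration for DPI -------------------------------
oracle_dpi <- function(edges, tolerance = 0) {
  ne <- nrow(edges)
  if (ne < 3) return(edges)
  drop <- logical(ne)
  nodes <- sort(unique(c(edges$a, edges$b)))
  find_edge <- function(x, y) {
    which((edges$a == x & edges$b == y) | (edges$a == y & edges$b == x))
  }
  if (length(nodes) >= 3) {
    trip <- utils::combn(nodes, 3)
    for (t in seq_len(ncol(trip))) {
      e1 <- find_edge(trip[1, t], trip[2, t])
      e2 <- find_edge(trip[1, t], trip[3, t])
      e3 <- find_edge(trip[2, t], trip[3, t])
      if (!length(e1) || !length(e2) || !length(e3)) next
      eid <- c(e1[1], e2[1], e3[1])
      mis <- edges$mi[eid]
      w <- which.min(mis)
      if (mis[w] < (1 - tolerance) * min(mis[-w])) drop[eid[w]] <- TRUE
    }
  }
  edges[!drop, , drop = FALSE]
}

random_graph <- function(n_nodes = 20, p_edge = 0.25) {
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(a = paste0("n", pairs[keep, 1]),
             b = paste0("n", pairs[keep, 2]),
             mi = runif(sum(keep), 0.1, 2),
             stringsAsFactors = FALSE)
}

# ---- brute-force sparse-pattern enumeration --------------------------------
# all-windows x all-species enumeration on character sequences
oracle_sparse_patterns <- function(seq_chrs, wlen = 8, min_match = 6,
                                   min_species = 4) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(w) rev(unname(comp[w]))
  ref <- strsplit(seq_chrs[[1]], "")[[1]]
  seeds <- unique(vapply(1:(length(ref) - wlen + 1), function(i)
    paste(ref[i:(i + wlen - 1)], collapse = ""), ""))
  out <- list()
  for (sd in seeds) {
    sv <- strsplit(sd, "")[[1]]
    sr <- rc(sv)
    nsup <- 0
    for (sp in seq_along(seq_chrs)) {
      ch <- strsplit(seq_chrs[[sp]], "")[[1]]
      hit <- FALSE
      for (i in 1:(length(ch) - wlen + 1)) {
        win <- ch[i:(i + wlen - 1)]
        if (sum(win == sv) >= min_match || sum(win == sr) >= min_match) {
          hit <- TRUE
          break
        }
      }
      if (hit) nsup <- nsup + 1
    }
    if (nsup >= min_species) out[[sd]] <- nsup
  }
  out
}

# ---- exhaustive offset scan for motif comparison ---------------------------
oracle_compare <- function(a, b, min_overlap = 4) {
  skl <- function(p, q) 0.5 * sum(p * log2(p / q) + q * log2(q / p))
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  best <- Inf
  for (bm in list(b$mat, rc(b$mat))) {
    la <- ncol(a$mat); lb <- ncol(bm)
    for (off in -(lb - 1):(la - 1)) {
      cols <- 0; tot <- 0
      for (ja in 1:la) {
        jb <- ja - off
        if (jb >= 1 && jb <= lb) {
          cols <- cols + 1
          tot <- tot + skl(a$mat[, ja], bm[, jb])
        }
      }
      if (cols >= min_overlap) best <- min(best, tot / cols)
    }
  }
  best
}
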