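## Regulatory-network inference from expression data: rank-kernel mutual
## information, an MI significance threshold from a shuffle null, Data
## Processing Inequality pruning of indirect edges, bootstrap consensus
## networks, and Spearman co-expression target sets.

#' Mutual information between two expression profiles
#'
#' Rank (copula) transform followed by fixed-bandwidth Gaussian-kernel
#' density estimation of the joint and marginal densities on the rank scale;
#' bandwidths follow the normal-reference rule. The estimator is
#' deterministic, symmetric and invariant under strictly monotone transforms
#' of either argument. Estimates are reported in nats and floored at zero.
#'
#' @param x,y numeric vectors of equal length (at least 8 samples).
#' @return non-negative mutual information in nats.
#' @export
estimate_mi <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 8) stop("need at least 8 samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: MI set to 0")
    return(0)
  }
  cpp_mi_pairs(cbind(x, y), matrix(c(1L, 2L), 1))[1]
}

# MI for many (column a, column b) pairs of an expression matrix laid out
# samples x genes.
mi_pairs <- function(mat_sg, pairs) {
  cpp_mi_pairs(mat_sg, matrix(as.integer(pairs), ncol = 2))
}

#' MI significance threshold from a within-gene shuffle null
#'
#' Builds a null MI distribution by estimating MI between randomly paired
#' genes after shuffling one gene's samples, then returns the
#' `1 - alpha/n_pairs` quantile (Bonferroni correction over the pairs
#' tested). When `n_null` cannot resolve the corrected quantile, the tail is
#' extrapolated by an exponential peaks-over-threshold fit to the top of the
#' null (`method = "evt"`), or an error is raised (`method = "quantile"`).
#'
#' @param expr genes x samples expression matrix.
#' @param alpha significance level before correction.
#' @param n_pairs number of TF-gene pairs the threshold will be applied to.
#' @param n_null number of null MI draws.
#' @param method `"auto"` (default), `"quantile"` or `"evt"`.
#' @param index_map optional integer vector of sample indices (e.g. a
#'   bootstrap resampling map). The null is then built by shuffling genes
#'   over the *original* samples before applying the map, so the null
#'   carries the same duplicated-sample structure as the data it is
#'   compared against.
#' @return list with `threshold`, `corrected_alpha`, `method`, `null` (the
#'   sorted null sample).
#' @export
mi_significance_threshold <- function(expr, alpha, n_pairs = NULL,
                                      n_null = 1000L,
                                      method = c("auto", "quantile", "evt"),
                                      index_map = NULL) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0,1]", call. = FALSE)
  G <- nrow(expr)
  if (is.null(n_pairs)) n_pairs <- G * (G - 1) / 2
  p_corr <- alpha / n_pairs
  mat <- t(expr) # samples x genes
  n0 <- nrow(mat)
  im <- if (is.null(index_map)) seq_len(n0) else as.integer(index_map)
  shuf <- vapply(seq_len(n_null),
                 function(i) mat[sample.int(n0)[im],
                                 (i - 1L) %% G + 1L], numeric(length(im)))
  a <- sample.int(G, n_null, replace = TRUE)
  big <- cbind(mat[im, a, drop = FALSE], shuf)
  null <- cpp_mi_pairs(big, cbind(seq_len(n_null), n_null + seq_len(n_null)))
  null <- sort(null)
  resolvable <- (n_null + 1) * p_corr >= 1
  if (method == "auto") method <- if (resolvable) "quantile" else "evt"
  if (method == "quantile") {
    if (!resolvable)
      stop("n_null too small to resolve corrected quantile ",
           format(p_corr), "; increase n_null or use method = 'evt'",
           call. = FALSE)
    thr <- unname(quantile(null, 1 - p_corr, type = 1))
  } else {
    # exponential excess over the 95th percentile of the null
    u <- unname(quantile(null, 0.95, type = 1))
    exc <- null[null > u] - u
    if (length(exc) < 5 || mean(exc) == 0) {
      u <- unname(quantile(null, 0.5, type = 1))
      exc <- null[null > u] - u
    }
    beta <- mean(exc)
    k <- length(exc)
    thr <- if (p_corr >= k / length(null))
      unname(quantile(null, 1 - p_corr, type = 1))
    else u + beta * log(k / (length(null) * p_corr))
  }
  list(threshold = thr, corrected_alpha = p_corr, method = method,
       null = null)
}

#' Prune indirect edges with the Data Processing Inequality
#'
#' For every triangle of edges (A,B), (B,C), (A,C), the edge with the
#' smallest MI is flagged when its MI is below `(1 - tolerance)` times the
#' smaller of the other two; all flagged edges are removed together after
#' every triangle has been examined, so the result does not depend on edge
#' order and the operation is idempotent.
#'
#' @param edges data.frame with columns `a`, `b`, `mi` (an undirected
#'   weighted graph).
#' @param tolerance non-negative DPI tolerance; 0 applies the strict
#'   inequality.
#' @return the pruned data.frame (subset of rows of `edges`).
#' @export
apply_dpi <- function(edges, tolerance = 0) {
  stopifnot(tolerance >= 0)
  ne <- nrow(edges)
  if (ne < 3) return(edges)
  nodes <- sort(unique(c(edges$a, edges$b)))
  ia <- match(edges$a, nodes)
  ib <- match(edges$b, nodes)
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  eid <- setNames(seq_len(ne), key(ia, ib))
  adj <- vector("list", length(nodes))
  for (e in seq_len(ne)) {
    adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
    adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
  }
  drop <- logical(ne)
  for (i in seq_along(nodes)) {
    nb <- adj[[i]]
    nb <- nb[nb > i]
    if (length(nb) < 2) next
    for (p in seq_len(length(nb) - 1)) for (q in seq(p + 1, length(nb))) {
      j <- nb[p]; k <- nb[q]
      e3 <- eid[key(j, k)]
      if (is.na(e3)) next
      e1 <- eid[key(i, j)]; e2 <- eid[key(i, k)]
      mis <- c(edges$mi[e1], edges$mi[e2], edges$mi[e3])
      w <- which.min(mis)
      if (mis[w] < (1 - tolerance) * min(mis[-w]))
        drop[c(e1, e2, e3)[w]] <- TRUE
    }
  }
  edges[!drop, , drop = FALSE]
}

# Single-network inference: MI over tf-gene and tf-tf pairs, thresholding,
# DPI. mat_sg is samples x genes; tf_idx indexes genes that are regulators.
infer_network_once <- function(mat_sg, tf_idx, threshold, tolerance = 0) {
  G <- ncol(mat_sg)
  gene_idx <- seq_len(G)
  pr <- rbind(
    do.call(rbind, lapply(tf_idx, function(t) {
      others <- setdiff(gene_idx, tf_idx)
      if (length(others)) cbind(t, others) else NULL
    })),
    if (length(tf_idx) > 1) t(utils::combn(tf_idx, 2)) else NULL)
  mi <- mi_pairs(mat_sg, pr)
  keep <- mi >= threshold
  edges <- data.frame(a = pr[keep, 1], b = pr[keep, 2], mi = mi[keep])
  apply_dpi(edges, tolerance)
}

#' Bootstrap consensus network inference
#'
#' Each bootstrap resamples the samples with replacement and runs the full
#' threshold + DPI inference on the resampled matrix (with its own
#' shuffle-null MI threshold at the Bonferroni-corrected `mi_alpha`).
#' Per-edge support counts are then tested against the shuffled-network
#' null: with per-bootstrap edge frequency `p_b = E_b / P` (edges kept out
#' of `P` candidate pairs), the support of an exchangeable edge is
#' Poisson-binomial across bootstraps, and edges are kept when the exact
#' upper tail falls below `consensus_alpha`.
#'
#' @param expr genes x samples expression matrix.
#' @param tfs character vector of regulator gene ids (must be rows of
#'   `expr`).
#' @param config a [run_config] object; uses `bootstraps`, `mi_alpha`,
#'   `consensus_alpha`, `dpi_tolerance`, `rng_seed`.
#' @param n_null null MI draws per bootstrap for the threshold.
#' @return data.frame of consensus edges with columns `tf`, `target`, `mi`
#'   (on the original matrix), `sign` (Spearman sign), `support`,
#'   `consensus_p`.
#' @export
bootstrap_consensus <- function(expr, tfs, config = run_config(),
                                n_null = 500L) {
  n <- ncol(expr)
  if (n < 8) stop("fewer than 8 samples: refusing to infer", call. = FALSE)
  B <- config$bootstraps
  if (B < 1) stop("need at least 1 bootstrap", call. = FALSE)
  tf_idx <- match(tfs, rownames(expr))
  if (anyNA(tf_idx)) stop("unknown TF id: ",
                          tfs[which(is.na(tf_idx))[1]], call. = FALSE)
  G <- nrow(expr)
  Tn <- length(tf_idx)
  P <- Tn * (G - Tn) + Tn * (Tn - 1) / 2
  support <- new.env(hash = TRUE)
  Eb <- numeric(B)
  with_seed(substream_seed(config$rng_seed, "bootstrap"), {
    for (b in seq_len(B)) {
      samp <- sample.int(n, n, replace = TRUE)
      mat <- t(expr)[samp, , drop = FALSE]
      thr <- mi_significance_threshold(expr, config$mi_alpha, n_pairs = P,
                                       n_null = n_null,
                                       index_map = samp)$threshold
      net <- infer_network_once(mat, tf_idx, thr, config$dpi_tolerance)
      Eb[b] <- nrow(net)
      if (nrow(net)) {
        keys <- paste0(pmin(net$a, net$b), "_", pmax(net$a, net$b))
        for (k in keys)
          assign(k, (if (exists(k, support)) get(k, support) else 0L) + 1L,
                 support)
      }
    }
  })
  keys <- ls(support)
  if (!length(keys)) {
    return(data.frame(tf = character(), target = character(), mi = numeric(),
                      sign = integer(), support = integer(),
                      consensus_p = numeric()))
  }
  supp <- vapply(keys, function(k) get(k, support), 0L)
  # Poisson-binomial upper tail of the shuffled-network support null
  pb <- Eb / P
  tail_p <- poisbin_upper_tail(pb)
  p_edge <- tail_p[pmin(supp, B) + 1L]
  keep <- p_edge < config$consensus_alpha
  if (!any(keep)) {
    return(data.frame(tf = character(), target = character(), mi = numeric(),
                      sign = integer(), support = integer(),
                      consensus_p = numeric()))
  }
  ij <- do.call(rbind, strsplit(keys[keep], "_", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  # orient: tf first (if both are TFs, keep the smaller index as tf)
  is_tf_i <- i %in% tf_idx
  tf_g <- ifelse(is_tf_i, i, j)
  tg_g <- ifelse(is_tf_i, j, i)
  mat0 <- t(expr)
  mi0 <- mi_pairs(mat0, cbind(tf_g, tg_g))
  rho <- vapply(seq_along(tf_g), function(e)
    cor(mat0[, tf_g[e]], mat0[, tg_g[e]], method = "spearman"), 0)
  out <- data.frame(tf = rownames(expr)[tf_g],
                    target = rownames(expr)[tg_g],
                    mi = mi0,
                    sign = ifelse(rho > 0, 1L, ifelse(rho < 0, -1L, NA)),
                    support = supp[keep],
                    consensus_p = p_edge[keep],
                    stringsAsFactors = FALSE)
  out[order(out$tf, -out$mi, out$target), , drop = FALSE]
}

# exact Poisson-binomial upper tail P(S >= s) for s = 0..B, via DP
poisbin_upper_tail <- function(p) {
  B <- length(p)
  pmf <- c(1, numeric(B))
  for (pb in p) pmf <- c(pmf, 0)[1:(B + 1)] * (1 - pb) +
      c(0, pmf[1:B]) * pb
  rev(cumsum(rev(pmf)))
}

#' Activated target sets from a consensus network
#'
#' Per TF, keeps consensus targets whose Spearman sign is positive
#' (predicted activation) and returns only TFs with at least `min_targets`
#' such targets.
#'
#' @param edges consensus edge data.frame from [bootstrap_consensus()].
#' @param min_targets minimum activated-target count.
#' @return named list of character vectors (targets per qualifying TF).
#' @export
activated_targets <- function(edges, min_targets = 30L) {
  if (!nrow(edges)) return(list())
  pos <- edges[!is.na(edges$sign) & edges$sign > 0, , drop = FALSE]
  sets <- split(pos$target, pos$tf)
  sets <- lapply(sets, function(v) sort(unique(v)))
  sets[vapply(sets, length, 0L) >= min_targets]
}

# Spearman rho and two-sided p for one gene against all others (t approx)
spearman_vs_all <- function(expr, tf) {
  i <- match(tf, rownames(expr))
  if (is.na(i)) stop("unknown TF id: ", tf, call. = FALSE)
  n <- ncol(expr)
  r_tf <- rank(expr[i, ])
  r_all <- t(apply(expr, 1, rank))
  rho <- as.vector(cor(r_tf, t(r_all)))
  rho_c <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  tstat <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(gene = rownames(expr), rho = rho, p = p,
             stringsAsFactors = FALSE)[-i, , drop = FALSE]
}

#' Co-expression target set by Spearman correlation
#'
#' Targets are genes positively Spearman-correlated with the TF whose
#' Bonferroni-corrected p-value is at or below `alpha`. The correction
#' multiplies the raw p-value by the number of candidate genes
#' (`correction = "genes"`) or by genes times the number of TFs analysed
#' (`correction = "pairs"`).
#'
#' @param expr genes x samples expression matrix.
#' @param tf TF gene id.
#' @param alpha corrected significance threshold.
#' @param correction `"genes"` (default) or `"pairs"`.
#' @param n_tfs number of TFs analysed, used when `correction = "pairs"`.
#' @return character vector of target gene ids (sorted).
#' @export
coexpression_targets <- function(expr, tf, alpha = 1e-4,
                                 correction = c("genes", "pairs"),
                                 n_tfs = 1L) {
  correction <- match.arg(correction)
  st <- spearman_vs_all(expr, tf)
  mult <- nrow(st) * if (correction == "pairs") n_tfs else 1L
  keep <- st$rho > 0 & pmin(st$p * mult, 1) <= alpha
  sort(st$gene[keep])
}

#' Top-n most co-expressed genes (co-expression*)
#'
#' The `n` positively correlated genes with the smallest Spearman p-values;
#' ties are broken by gene identifier order for determinism. Used with `n`
#' equal to the size of the network-inferred target set, so co-expression
#' and network inference are compared at matched set sizes.
#'
#' @param expr genes x samples expression matrix.
#' @param tf TF gene id.
#' @param n number of targets to return.
#' @return character vector of target gene ids.
#' @export
coexpression_star <- function(expr, tf, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  st <- spearman_vs_all(expr, tf)
  st <- st[st$rho > 0, , drop = FALSE]
  if (n > nrow(st)) {
    warning("n exceeds the number of positively correlated genes; ",
            "returning all ", nrow(st))
    n <- nrow(st)
  }
  st <- st[order(st$p, st$gene), , drop = FALSE]
  st$gene[seq_len(n)]
}
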