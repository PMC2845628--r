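# Mutual information estimation, significance thresholds, DPI pruning,
# bootstrap consensus, co-expression target sets.

test_that("MI estimator is symmetric, monotone-invariant and maximal on
           self-dependence", {
  set.seed(21)
  x <- rnorm(80)
  y <- rnorm(80)
  expect_identical(estimate_mi(x, y), estimate_mi(y, x))
  expect_identical(estimate_mi(exp(x), y), estimate_mi(x, y))
  expect_equal(estimate_mi(x, -y^3), estimate_mi(x, y), tolerance = 1e-9)
  mi_self <- estimate_mi(x, x)
  for (i in 1:20) expect_lt(estimate_mi(x, sample(y)), mi_self)
  expect_warning(expect_equal(estimate_mi(rep(1, 80), x), 0), "constant")
  expect_error(estimate_mi(x[1:5], y[1:5]), "at least 8")
})

test_that("independent data falls below the 95th percentile of its own
           shuffle null", {
  set.seed(22)
  x <- sample(100)
  y <- sample(100)
  obs <- estimate_mi(x, y)
  null <- vapply(1:1000, function(i) estimate_mi(x, sample(y)), 0)
  expect_lt(obs, quantile(null, 0.95))
})

test_that("MI estimator bias on independent data is small relative to its
           spread", {
  set.seed(23)
  mis <- vapply(1:200, function(i) estimate_mi(rnorm(100), rnorm(100)), 0)
  expect_lt(mean(mis), 3 * sd(mis))
})

test_that("MI significance threshold matches the sorted-quantile oracle and
           is monotone in alpha", {
  set.seed(24)
  expr <- matrix(rnorm(50 * 40), 50, 40,
                 dimnames = list(paste0("g", 1:50), NULL))
  with_seed <- function(s, e) { set.seed(s); e }
  set.seed(1)
  t1 <- mi_significance_threshold(expr, 0.5, n_pairs = 10, n_null = 400)
  expect_equal(t1$method, "quantile")
  expect_equal(t1$threshold,
               sort(t1$null)[ceiling((1 - 0.5 / 10) * length(t1$null))],
               tolerance = 1e-12)
  set.seed(1)
  t2 <- mi_significance_threshold(expr, 0.25, n_pairs = 10, n_null = 400)
  expect_gte(t2$threshold, t1$threshold)
  # boundary: alpha 1 with a single pair keeps everything
  set.seed(1)
  t3 <- mi_significance_threshold(expr, 1, n_pairs = 1, n_null = 200)
  expect_equal(t3$threshold, min(t3$null))
  # unresolvable corrected quantile: explicit quantile method errors,
  # the extreme-value tail fit takes over under auto
  set.seed(1)
  expect_error(mi_significance_threshold(expr, 1e-4, n_pairs = 100,
                                         n_null = 100,
                                         method = "quantile"),
               "n_null")
  set.seed(1)
  t4 <- mi_significance_threshold(expr, 1e-4, n_pairs = 100, n_null = 100)
  expect_equal(t4$method, "evt")
  expect_gt(t4$threshold, max(t4$null) * 0.5)
})

test_that("DPI removes the weakest triangle edge and matches the
           brute-force oracle", {
  tri <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"),
                    mi = c(2.0, 1.5, 0.4))
  out <- apply_dpi(tri, 0)
  expect_equal(nrow(out), 2)
  expect_false(any(out$a == "A" & out$b == "C"))

  chain <- data.frame(a = c("A", "B"), b = c("B", "C"), mi = c(1, 2))
  expect_identical(apply_dpi(chain, 0), chain)

  set.seed(31)
  for (i in 1:50) {
    g <- random_graph(20, 0.25)
    out <- apply_dpi(g, 0)
    orc <- oracle_dpi(g, 0)
    expect_equal(out[order(out$a, out$b), ], orc[order(orc$a, orc$b), ],
                 ignore_attr = TRUE)
    # order independence
    perm <- g[sample(nrow(g)), , drop = FALSE]
    outp <- apply_dpi(perm, 0)
    expect_setequal(paste(outp$a, outp$b), paste(out$a, out$b))
    # idempotence
    expect_equal(nrow(apply_dpi(out, 0)), nrow(out))
  }
})

test_that("bootstrap consensus keeps persistent edges, bounds support and
           refuses tiny sample sizes", {
  spec <- synthetic_spec(seed = 33, n_targets = 10L, n_cascades = 0L,
                         n_genes = 120L)
  expr <- simulate_expression(spec)
  cfg <- run_config(bootstraps = 10L, rng_seed = 33L)
  net <- bootstrap_consensus(expr, "TF1", cfg)
  expect_true(all(net$support <= 10L))
  expect_true(all(net$mi >= 0))
  expect_true(all(net$consensus_p < cfg$consensus_alpha))
  # planted targets are persistent across all bootstraps
  planted <- net[net$target %in% attr(expr, "direct_targets"), ]
  expect_gte(nrow(planted), 9)
  expect_true(all(planted$support == 10L))
  expect_error(bootstrap_consensus(expr[, 1:5], "TF1", cfg), "fewer than 8")
})

test_that("i.i.d. noise yields an empty consensus network", {
  set.seed(34)
  expr <- matrix(rnorm(80 * 60), 80, 60,
                 dimnames = list(paste0("g", 1:80), NULL))
  cfg <- run_config(bootstraps = 10L, rng_seed = 34L)
  for (s in 1:2) {
    cfg$rng_seed <- s
    net <- bootstrap_consensus(expr, c("g1", "g2"), cfg)
    expect_equal(nrow(net), 0L)
  }
})

test_that("activated_targets applies the positive-sign and minimum-size
           rules", {
  edges <- data.frame(
    tf = rep("TF", 45),
    target = paste0("t", 1:45),
    mi = 1, sign = c(rep(1L, 40), rep(-1L, 5)),
    support = 10L, consensus_p = 1e-9)
  out <- activated_targets(edges, 30L)
  expect_equal(length(out$TF), 40)
  edges$sign <- c(rep(1L, 29), rep(-1L, 16))
  expect_length(activated_targets(edges, 30L), 0)
})

test_that("co-expression targets honour sign and threshold; planted
           correlates are recovered exactly", {
  set.seed(36)
  n <- 60
  tfx <- rnorm(n)
  expr <- rbind(TF = tfx,
                POS = tfx,            # identical profile
                NEG = -tfx)           # perfectly anti-correlated
  noise <- matrix(rnorm(500 * n), 500, n,
                  dimnames = list(paste0("g", 1:500), NULL))
  planted <- vapply(1:5, function(i) tfx + rnorm(n, sd = 0.2), numeric(n))
  rownames_planted <- paste0("p", 1:5)
  expr <- rbind(expr, t(matrix(planted, n, 5,
                               dimnames = list(NULL, rownames_planted))),
                noise)
  got <- coexpression_targets(expr, "TF", alpha = 1e-4)
  expect_true("POS" %in% got)
  expect_false("NEG" %in% got)
  expect_true(all(rownames_planted %in% got))
  # exact agreement with a direct rank-correlation oracle
  oracle <- character()
  G <- nrow(expr) - 1
  for (g in setdiff(rownames(expr), "TF")) {
    ct <- suppressWarnings(
      cor.test(rank(expr["TF", ]), rank(expr[g, ]), method = "pearson"))
    if (ct$estimate > 0 && min(ct$p.value * G, 1) <= 1e-4)
      oracle <- c(oracle, g)
  }
  expect_setequal(got, oracle)
})

test_that("co-expression* returns the top-n positively correlated genes", {
  set.seed(37)
  n <- 40
  tfx <- rnorm(n)
  expr <- rbind(TF = tfx,
                best = tfx + rnorm(n, sd = 0.05),
                mid = tfx + rnorm(n, sd = 0.8),
                t(matrix(rnorm(10 * n), n, 10,
                         dimnames = list(NULL, paste0("g", 1:10)))))
  expect_equal(coexpression_star(expr, "TF", 1), "best")
  expect_warning(allg <- coexpression_star(expr, "TF", 1000), "exceeds")
  expect_true(length(allg) < nrow(expr))
  # the Bonferroni set is contained in the same-size top-n set
  sig <- coexpression_targets(expr, "TF", alpha = 1e-2)
  star <- coexpression_star(expr, "TF", max(length(sig), 1))
  expect_true(all(sig %in% star))
})
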