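# Coverage-calibrated score thresholds, sparse-pattern discovery across
# orthologs, pattern/alignment masks and their combination.

test_that("threshold_for_coverage picks the closest-from-below threshold", {
  tr <- cons_track(list(p = c(rep(0.9, 150), rep(0.1, 1350))))
  cal <- threshold_for_coverage(tr, 0.10)
  expect_equal(cal$achieved_fraction, 0.10)
  expect_true(cal$threshold > 0.1 && cal$threshold <= 0.9)

  # near-1 boundary: with N distinct scores the closest-from-below rule
  # retains all but the minimum (retaining everything would be fraction 1)
  set.seed(51)
  tr2 <- cons_track(list(p = runif(1000)))
  cal2 <- threshold_for_coverage(tr2, 1 - 1e-6)
  expect_equal(cal2$threshold, sort(tr2$scores$p)[2])
  expect_equal(cal2$achieved_fraction, 0.999)

  expect_error(threshold_for_coverage(cons_track(list(p = rep(0, 10))),
                                      0.1),
               "all zero")
})

test_that("calibrated coverage equals the sort-and-count oracle on seeded
           tracks", {
  set.seed(52)
  for (i in 1:50) {
    v <- runif(500)
    cal <- threshold_for_coverage(cons_track(list(p = v)), 0.10)
    oracle <- sum(v >= cal$threshold) / length(v)
    expect_equal(cal$achieved_fraction, oracle)
    expect_lte(cal$achieved_fraction, 0.10)
    expect_gt(cal$achieved_fraction, 0.10 - 1 / 500 - 1e-12)
  }
})

test_that("alignment masks retain the calibrated fraction and nest across
           fractions", {
  s <- masked_seqs(c(p = strrep("ACGT", 375)), stage = "MCR")
  tr <- cons_track(list(p = c(rep(0.9, 150), rep(0.1, 1350))))
  am <- alignment_conserved_mask(s, tr, 0.10)
  expect_equal(which(!am$mask$p), 1:150)
  expect_equal(am$stage, "alignment-conserved")

  set.seed(53)
  tr2 <- cons_track(list(p = runif(1500)))
  a10 <- alignment_conserved_mask(s, tr2, 0.10)
  a20 <- alignment_conserved_mask(s, tr2, 0.20)
  expect_true(all(!a20$mask$p[!a10$mask$p]))  # 10% set nests inside 20%
})

test_that("sparse patterns require the species-support minimum", {
  set.seed(54)
  word <- "ACGTACGT"
  mk <- function(with_word, n = 120) {
    s <- random_dna(n)
    if (with_word) substr(s, 50, 57) <- word
    s
  }
  # word present in all 5 sequences
  seqs <- masked_seqs(c(ref = mk(TRUE), sp1 = mk(TRUE), sp2 = mk(TRUE),
                        sp3 = mk(TRUE), sp4 = mk(TRUE)), stage = "MCR")
  pat <- find_sparse_patterns(seqs, min_species = 5L)
  expect_true(word %in% pat$seed)
  expect_gte(pat$support[pat$seed == word], 5)

  # a seed present in fewer than min_species is not reported
  p2 <- find_sparse_patterns(
    masked_seqs(c(ref = mk(TRUE), sp1 = mk(FALSE), sp2 = mk(FALSE),
                  sp3 = mk(FALSE), sp4 = mk(FALSE)), stage = "MCR"),
    min_species = 5L)
  if (word %in% p2$seed) {
    # only if chance >=6/8 windows appear in every random sequence
    expect_gte(p2$support[p2$seed == word], 5)
  } else expect_false(word %in% p2$seed)
})

test_that("reported support matches the all-windows x all-species oracle on
           toy orthologs", {
  set.seed(55)
  for (rep in 1:8) {
    seqs <- vapply(1:4, function(i) random_dna(60), "")
    names(seqs) <- c("ref", "s1", "s2", "s3")
    ms <- masked_seqs(seqs, stage = "MCR")
    got <- find_sparse_patterns(ms, min_species = 2L)
    orc <- oracle_sparse_patterns(as.list(seqs), min_species = 2)
    expect_setequal(got$seed, names(orc))
    for (sd in got$seed)
      expect_equal(got$support[got$seed == sd], orc[[sd]])
  }
})

test_that("pattern discovery is translation-covariant under a masked
           prefix", {
  set.seed(56)
  seqs <- vapply(1:5, function(i) random_dna(100), "")
  names(seqs) <- c("ref", paste0("s", 1:4))
  base <- masked_seqs(seqs, stage = "MCR")
  shift <- masked_seqs(vapply(seqs, function(s)
    paste0("nnnnnnnnnn", s), ""), stage = "MCR")
  p1 <- find_sparse_patterns(base, min_species = 3L)
  p2 <- find_sparse_patterns(shift, min_species = 3L)
  expect_setequal(p1$seed, p2$seed)
  for (sd in p1$seed) {
    i1 <- p1$intervals[[which(p1$seed == sd)]]
    i2 <- p2$intervals[[which(p2$seed == sd)]]
    expect_equal(i2[, "start"], i1[, "start"] + 10L)
  }
})

test_that("pattern masks consume patterns greedily by z until the coverage
           budget", {
  s <- masked_seqs(c(p = strrep("A", 1500)), stage = "MCR")
  pat1 <- data.frame(seed = "AAAAAAAA", z = 5, support = 5L,
                     n_occ = 1L, stringsAsFactors = FALSE)
  pat1$intervals <- list(cbind(start = 0L, end = 150L))
  pm <- pattern_conserved_mask(s, setNames(list(pat1), "p"), 0.10)
  expect_equal(which(!pm$mask$p), 1:150)
  expect_equal(pm$stage, "pattern-conserved")

  # two disjoint 10% patterns: only the higher-z one is consumed
  pat2 <- rbind(pat1, pat1)
  pat2$z <- c(5, 4)
  pat2$intervals <- list(cbind(start = 0L, end = 150L),
                         cbind(start = 300L, end = 450L))
  pm2 <- pattern_conserved_mask(s, setNames(list(pat2), "p"), 0.10)
  expect_equal(which(!pm2$mask$p), 1:150)

  expect_warning(pm0 <- pattern_conserved_mask(
    s, setNames(list(dismotif:::empty_patterns()), "p"), 0.10),
    "fully masked")
  expect_true(all(pm0$mask$p))

  # greedy-by-z oracle on a seeded instance
  set.seed(57)
  n <- 1000
  k <- 12
  starts <- sample(0:(n - 40), k)
  pat3 <- data.frame(seed = sprintf("S%02d", 1:k),
                     z = round(runif(k, 1, 6), 3), support = 4L,
                     n_occ = 1L, stringsAsFactors = FALSE)
  pat3$intervals <- lapply(starts, function(st)
    cbind(start = st, end = st + 40L))
  sq <- masked_seqs(c(q = random_dna(n)), stage = "MCR")
  got <- pattern_conserved_mask(sq, setNames(list(pat3), "q"), 0.15)
  keep <- logical(n)
  added <- 0
  for (r in order(-pat3$z, pat3$seed)) {
    iv <- pat3$intervals[[r]]
    new <- logical(n)
    new[(iv[1, 1] + 1):iv[1, 2]] <- TRUE
    new <- new & !keep
    if ((added + sum(new)) / n > 0.15 + 0.01) break
    keep <- keep | new
    added <- added + sum(new)
  }
  expect_identical(!got$mask$q, keep)
})

test_that("combining masks is a per-base OR with the expected coverage
           bounds", {
  s <- masked_seqs(c(p = strrep("A", 1000)), stage = "MCR")
  a <- s; a$mask$p <- rep(TRUE, 1000); a$mask$p[1:100] <- FALSE
  b <- s; b$mask$p <- rep(TRUE, 1000); b$mask$p[201:300] <- FALSE
  a <- dismotif:::set_stage(a, "alignment-conserved")
  b <- dismotif:::set_stage(b, "pattern-conserved")
  cmb <- combine_conservation(a, b)
  expect_equal(sum(!cmb$mask$p), 200)
  expect_equal(cmb$stage, "combined-conservation")
  same <- combine_conservation(a, a)
  expect_equal(sum(!same$mask$p), 100)

  set.seed(58)
  for (i in 1:20) {
    a$mask$p <- runif(1000) < 0.9
    b$mask$p <- runif(1000) < 0.9
    cmb <- combine_conservation(a, b)
    expect_identical(cmb$mask$p, a$mask$p & b$mask$p)
    cov <- sum(!cmb$mask$p)
    expect_gte(cov, max(sum(!a$mask$p), sum(!b$mask$p)))
    expect_lte(cov, sum(!a$mask$p) + sum(!b$mask$p))
  }
  b2 <- b
  names(b2$seq) <- names(b2$mask) <- "x"
  expect_error(combine_conservation(a, b2), "names differ")
})
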