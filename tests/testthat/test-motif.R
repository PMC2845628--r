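# Site scanning, relative-error classification, permutation significance,
# motif comparison/merging, cross-set re-ranking, region enrichment.

test_that("best-site scores match the consensus arithmetic, strand symmetry
           and the window-enumeration oracle", {
  p <- word_pwm("ACGTAC", core = 0.85, id = "w")
  s <- masked_seqs(c(x = "TTTTACGTACTTTT"))
  sc <- scan_best_site(s, p, rep(0.25, 4))
  expect_equal(unname(sc), 6 * log2(0.85 * 4))

  rc <- masked_seqs(c(x = "AAAAGTACGTAAAA"))
  expect_equal(unname(scan_best_site(rc, p, rep(0.25, 4))), unname(sc))

  set.seed(61)
  for (i in 1:50) {
    L <- sample(4:8, 1)
    q <- random_pwm(L)
    bgc <- as.numeric(rgamma(4, 2)); bgc <- bgc / sum(bgc)
    chr <- random_dna(30)
    s2 <- masked_seqs(setNames(chr, "y"))
    expect_equal(unname(scan_best_site(s2, q, bgc)),
                 oracle_best_site(chr, q, bgc), tolerance = 1e-9)
  }

  # a fully masked sequence scores -Inf
  sm <- masked_seqs(c(z = "acgtacgtacgt"))
  expect_equal(unname(scan_best_site(sm, p)), -Inf)
})

test_that("classification error handles separable and degenerate cases and
           matches the cutoff-enumeration oracle", {
  set.seed(62)
  spec <- synthetic_spec(seed = 62, promoter_length = 120L,
                         site_frequency = 1)
  sim <- simulate_promoters(spec, n_fg = 15, n_bg = 15)
  res <- classify_set(sim$fg, sim$bg, spec$planted_pwm)
  expect_lte(res$err, 0.5)
  expect_equal(res$err, (res$fpr + res$fnr) / 2)

  # identical score multisets force err 0.5
  same <- classify_set(sim$fg, sim$fg, spec$planted_pwm)
  expect_equal(same$err, 0.5)

  # strongly separable case
  strong <- word_pwm("ACGTACGTAC", core = 0.97, id = "strong")
  fg <- masked_seqs(setNames(vapply(1:10, function(i)
    paste0(random_dna(20), "ACGTACGTAC", random_dna(20)), ""),
    paste0("f", 1:10)))
  bg <- random_seqs(10, 50, "b")
  expect_equal(classify_set(fg, bg, strong)$err, 0)

  # oracle equivalence on seeded instances
  for (i in 1:50) {
    q <- random_pwm(5)
    f2 <- random_seqs(8, 40, "f")
    b2 <- random_seqs(8, 40, "b")
    got <- classify_set(f2, b2, q, bg = rep(0.25, 4))
    orc <- oracle_min_err(scan_best_site(f2, q, rep(0.25, 4)),
                          scan_best_site(b2, q, rep(0.25, 4)))
    expect_equal(got$err, orc)
  }

  # err is invariant under strictly increasing transforms of the scores
  sf <- scan_best_site(sim$fg, spec$planted_pwm)
  sb <- scan_best_site(sim$bg, spec$planted_pwm)
  e1 <- oracle_min_err(sf, sb)
  e2 <- oracle_min_err(exp(sf / 4), exp(sb / 4))
  expect_equal(e1, e2)

  expect_error(classify_set(sim$fg, dismotif:::set_stage(sim$bg, "MCR"),
                            spec$planted_pwm),
               "stage labels differ")
})

test_that("library significance p-values obey the rank bound and
           monotonicity", {
  set.seed(63)
  spec <- synthetic_spec(seed = 63, promoter_length = 150L,
                         site_frequency = 1,
                         planted_pwm = word_pwm("ACGTACGTAC", core = 0.97,
                                                id = "strong"))
  sim <- simulate_promoters(spec, n_fg = 12, n_bg = 12)
  lib <- c(list(spec$planted_pwm),
           lapply(1:3, function(i)
             word_pwm(random_dna(8), id = paste0("D", i))))
  res <- library_significance(lib, sim$fg, sim$bg, n_perm = 200, seed = 1)
  expect_equal(res$motif[1], "strong")
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(diff(res$err) >= 0))
  # the planted motif separates perfectly: its p attains the add-one bound
  expect_equal(res$p[1], 1 / 201)
  # p is non-increasing as err decreases with the null fixed
  expect_true(all(diff(res$p[order(res$err)]) >= 0))
  expect_error(library_significance(lib, sim$fg, sim$bg, n_perm = 10),
               ">= 100")
})

test_that("de novo significance builds an n_perm null and flags planted
           structure", {
  spec <- synthetic_spec(seed = 64, promoter_length = 150L,
                         site_frequency = 1,
                         planted_pwm = word_pwm("ACGTACGTAC", core = 0.97,
                                                id = "strong"))
  sim <- simulate_promoters(spec, n_fg = 12, n_bg = 12)
  disco <- function(f, b) {
    cs <- coarse_search(f, b, 8L, beam = 1L, n_seed_words = 50L)
    data.frame(motif = cs[[1]]$pwm$id, err = cs[[1]]$err,
               stringsAsFactors = FALSE)
  }
  sig <- denovo_significance(sim$fg, sim$bg, disco, n_perm = 30, seed = 2)
  expect_length(sig$null, 30)
  expect_true(sig$observed$significant[1])
  expect_error(denovo_significance(sim$fg, sim$bg, disco, n_perm = 10),
               ">= 20")
})

test_that("motif comparison finds identity, orientation and offsets, and is
           symmetric", {
  a <- word_pwm("ACGGTTCA", id = "a")  # non-palindromic, aperiodic
  expect_equal(compare_motifs(a, a)$divergence, 0)
  expect_true(compare_motifs(a, a)$is_match)

  arc <- dismotif:::pwm_revcomp(a)
  arc$id <- "arc"
  cmp <- compare_motifs(a, arc)
  expect_equal(cmp$divergence, 0)
  expect_equal(cmp$orientation, "reverse-complement")

  # shifted motif with uniform flanks: best offset recovered
  m <- cbind(matrix(0.25, 4, 2), a$mat)
  b <- pwm(m, id = "b")
  cmp2 <- compare_motifs(a, b)
  expect_equal(cmp2$offset, -2)
  expect_lt(cmp2$divergence, 0.2)

  set.seed(65)
  for (i in 1:50) {
    x <- random_pwm(sample(4:9, 1), "x")
    y <- random_pwm(sample(4:9, 1), "y")
    dxy <- compare_motifs(x, y)$divergence
    expect_equal(dxy, compare_motifs(y, x)$divergence, tolerance = 1e-9)
    expect_equal(dxy, oracle_compare(x, y), tolerance = 1e-9)
  }

  short <- pwm(matrix(0.25, 4, 4), id = "short")
  expect_false(compare_motifs(short, a, min_overlap = 10)$is_match)
  expect_equal(compare_motifs(short, a,
                              min_overlap = 10)$divergence, Inf)
})

test_that("merging keeps the lowest-err representative per cluster", {
  a <- word_pwm("ACGTACGT", id = "a")
  a2 <- word_pwm("ACGTACGT", id = "a2")
  far <- word_pwm("GGGGCCCC", id = "far")
  out <- merge_similar(list(a, a2), c(0.2, 0.3))
  expect_length(out$pwms, 1)
  expect_equal(out$pwms[[1]]$id, "a")

  out2 <- merge_similar(list(a, far), c(0.3, 0.2))
  expect_length(out2$pwms, 2)

  # chain a~b, b~c, a!~c under greedy order fixed by err
  b <- word_pwm("ACGTACGA", id = "b")   # 1 mismatch from a
  cc <- word_pwm("ACGTATTA", id = "c")  # 2 more mismatches
  stopifnot(compare_motifs(a, b)$is_match, compare_motifs(b, cc)$is_match)
  if (!compare_motifs(a, cc)$is_match) {
    out3 <- merge_similar(list(a, b, cc), c(0.1, 0.2, 0.3))
    # a founds a cluster absorbing b; c remains separate
    expect_setequal(vapply(out3$pwms, `[[`, "", "id"), c("a", "c"))
  }
})

test_that("cross-set re-ranking takes each motif's best err and records the
           achieving stage", {
  r1 <- data.frame(motif = c("m1", "m2"), err = c(0.2, 0.4),
                   p = c(0.01, 0.2), cutoff = c(5, 6),
                   source_set = "conservation-free",
                   stringsAsFactors = FALSE)
  r2 <- data.frame(motif = c("m1", "m3"), err = c(0.3, 0.1),
                   p = c(0.02, 0.01), cutoff = c(5, 7),
                   source_set = "combined-conservation",
                   stringsAsFactors = FALSE)
  out <- rerank_across_sets(list(r1, r2))
  expect_equal(out$motif, c("m3", "m1", "m2"))
  expect_equal(out$err[out$motif == "m1"], 0.2)
  expect_equal(out$source_set[out$motif == "m1"], "conservation-free")
  expect_equal(out$source_set[out$motif == "m2"], "conservation-free")
  expect_equal(out$rank, 1:3)

  # sort-oracle agreement on random result tables
  set.seed(66)
  for (i in 1:10) {
    ids <- paste0("m", 1:50)
    mk <- function(stage) {
      pick <- sort(sample(50, 30))
      data.frame(motif = ids[pick], err = round(runif(30), 3),
                 p = round(runif(30), 3), cutoff = 1,
                 source_set = stage, stringsAsFactors = FALSE)
    }
    sets <- list(mk("conservation-free"), mk("combined-conservation"))
    out <- rerank_across_sets(sets)
    pooled <- rbind(sets[[1]], sets[[2]])
    best <- vapply(split(pooled$err, pooled$motif), min, 0)
    expect_equal(out$err, unname(best[out$motif]))
    expect_true(!is.unsorted(out$err))
  }
})

test_that("region enrichment matches the hypergeometric tail with Bonferroni
           correction", {
  set.seed(67)
  fg <- random_seqs(50, 30, "f")
  bg <- random_seqs(50, 30, "b")
  p <- word_pwm("ACGTACGT", id = "m")
  cut <- 2
  a <- sum(scan_best_site(fg, p, base_composition(bg)) >= cut)
  b <- sum(scan_best_site(bg, p, base_composition(bg)) >= cut)
  res <- region_enrichment_fet(list(p), fg, bg, cut)
  expect_equal(res$p_raw,
               phyper(a - 1, a + b, 100 - a - b, 50, lower.tail = FALSE))
  # closed-form check of the documented 50/500 vs 5/500 example
  expect_equal(phyper(49, 55, 945, 500, lower.tail = FALSE),
               sum(dhyper(50:55, 55, 945, 500)))
  # identical hit rates are not enriched one-sided
  res2 <- region_enrichment_fet(list(p, p, p), fg, fg, rep(cut, 3))
  expect_true(all(res2$p_raw >= 0.4))
  expect_equal(res2$p_bonferroni, pmin(res2$p_raw * 3, 1))
  expect_error(region_enrichment_fet(list(p), masked_seqs(list(), list()),
                                     bg, cut),
               "empty")
})
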