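# Coarse lattice search, hill-climbing refinement and the full de novo
# discovery driver.

test_that("the column alphabet contains point masses, pair mixtures and the
           uniform column", {
  ab <- column_alphabet()
  expect_equal(ncol(ab$vectors), 11)
  expect_true(all(abs(colSums(ab$vectors) - 1) < 1e-12))
  expect_true(all(ab$vectors > 0))
  expect_equal(max(ab$vectors[, 1]), 0.85)  # smoothed point mass
})

test_that("coarse search recovers a planted consensus word and is
           order-invariant", {
  set.seed(71)
  word <- "GATTACAG"
  fg_chr <- vapply(1:30, function(i)
    paste0(random_dna(30), word, random_dna(30)), "")
  names(fg_chr) <- paste0("f", 1:30)
  fg <- masked_seqs(fg_chr)
  bg <- random_seqs(60, 68, "b")
  cands <- coarse_search(fg, bg, 8L, beam = 5L, n_seed_words = 200L)
  # perfect separators include the planted word and its shifts/reverse
  # complements; the planted word itself must be among the top candidates
  expect_true(word %in% vapply(cands, function(c) pwm_consensus(c$pwm), ""))
  expect_equal(cands[[1]]$err, 0)
  expect_true(all(diff(vapply(cands, `[[`, 0, "err")) >= 0))

  one <- coarse_search(fg, bg, 8L, beam = 1L, n_seed_words = 200L)
  expect_length(one, 1)

  perm <- fg[sample(length(fg))]
  cands2 <- coarse_search(perm, bg, 8L, beam = 5L, n_seed_words = 200L)
  expect_identical(lapply(cands2, `[[`, "pwm"),
                   lapply(cands, `[[`, "pwm"))

  blank <- masked_seqs(c(z = "nnnnnnnnnnnn"))
  expect_error(coarse_search(blank, bg, 8L), "no unmasked window")
})

test_that("refinement never increases err and stops at local optima", {
  set.seed(72)
  spec <- synthetic_spec(seed = 72, promoter_length = 200L)
  sim <- simulate_promoters(spec, n_fg = 20, n_bg = 40)
  cands <- coarse_search(sim$fg, sim$bg, 8L, beam = 3L,
                         n_seed_words = 100L)
  for (cand in cands) {
    ref <- refine(cand, sim$fg, sim$bg, max_iter = 30L)
    expect_lte(ref$err, cand$err)
    # a local optimum is a fixed point
    again <- refine(ref, sim$fg, sim$bg, max_iter = 30L)
    expect_equal(again$err, ref$err)
    expect_equal(again$pwm$mat, ref$pwm$mat)
    expect_equal(again$iterations, 0L)
  }
})

test_that("refinement endpoint equals exhaustive neighbourhood descent on a
           small instance", {
  set.seed(73)
  fg <- random_seqs(8, 25, "f")
  bg <- random_seqs(8, 25, "b")
  bgc <- rep(0.25, 4)
  cand <- coarse_search(fg, bg, 6L, beam = 1L, n_seed_words = 20L,
                        bg = bgc)[[1]]
  got <- refine(cand, fg, bg, max_iter = 50L, bg = bgc)
  # oracle: steepest descent over the same single-column neighbour graph
  A <- column_alphabet()$vectors
  labels <- c(rep(TRUE, 8), rep(FALSE, 8))
  eval_err <- function(p) {
    oracle_min_err(scan_best_site(fg, p, bgc), scan_best_site(bg, p, bgc))
  }
  cur <- cand$pwm
  cur_err <- cand$err
  repeat {
    best <- NULL
    for (j in 1:6) for (k in 1:ncol(A)) {
      m <- cur$mat
      if (all(abs(m[, j] - A[, k]) < 1e-12)) next
      m[, j] <- A[, k]
      p <- pwm(m, id = "o")
      e <- eval_err(p)
      if (e < cur_err - 1e-12 && (is.null(best) || e < best$e - 1e-12))
        best <- list(p = p, e = e)
    }
    if (is.null(best)) break
    cur <- best$p
    cur_err <- best$e
  }
  expect_equal(got$err, cur_err)
  expect_equal(unname(got$pwm$mat), unname(cur$mat))
})

test_that("the discovery driver ranks motifs by err, respects bounds and
           refuses tiny foregrounds", {
  spec <- synthetic_spec(seed = 74, promoter_length = 300L)
  sim <- simulate_promoters(spec, n_fg = 15, n_bg = 30)
  cfg <- run_config(rng_seed = 74L, seed_words = 100L, beam = 10L,
                    refine_top = 2L)
  dn <- discover(sim$fg, sim$bg, cfg)
  expect_true(all(dn$motifs$err <= 0.5))
  expect_true(!is.unsorted(dn$motifs$err))
  expect_setequal(dn$lengths_searched, c(6L, 8L, 10L))
  expect_equal(names(dn$pwms), dn$motifs$motif)
  expect_error(discover(sim$fg[1:3], sim$bg, cfg), "fewer than 5")
})

test_that("recovery power increases with planted-site frequency", {
  errs <- vapply(c(0.3, 0.6, 0.9), function(freq) {
    spec <- synthetic_spec(seed = 75, site_frequency = freq,
                           promoter_length = 400L)
    sim <- simulate_promoters(spec, n_fg = 25, n_bg = 50)
    cfg <- run_config(rng_seed = 75L, seed_words = 150L, beam = 10L,
                      refine_top = 2L, motif_lengths = 8L)
    dn <- discover(sim$fg, sim$bg, cfg)
    dn$motifs$err[1]
  }, 0)
  expect_true(errs[3] < errs[1])
})

test_that("end-to-end discovery is deterministic given the seed", {
  spec <- synthetic_spec(seed = 76, promoter_length = 200L)
  sim <- simulate_promoters(spec, n_fg = 12, n_bg = 20)
  cfg <- run_config(rng_seed = 76L, seed_words = 80L, beam = 5L,
                    refine_top = 1L, motif_lengths = c(6L, 8L))
  d1 <- discover(sim$fg, sim$bg, cfg)
  d2 <- discover(sim$fg, sim$bg, cfg)
  expect_identical(d1$motifs, d2$motifs)
  expect_identical(lapply(d1$pwms, `[[`, "mat"),
                   lapply(d2$pwms, `[[`, "mat"))
})
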