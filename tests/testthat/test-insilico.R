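# In-silico module: the enhancement statistic, injections, distance sweeps,
# cooperativity, spacing perturbations and enhancer design edits.

test_that("enhancement: exact fixed points, undefined flag, monotonicity", {
  # exact additivity gives exactly 0
  expect_identical(enhancement(1, 5, 3, 7), 0)
  expect_identical(enhancement(1, 5, 3, 12), 1)
  # non-positive numerator: undefined flag (NA), never clamped
  expect_true(is.na(enhancement(1, 5, 10, 5)))
  expect_error(enhancement(1, 0, 3, 7), "hA")
  expect_error(enhancement(1, -2, 3, 7), "hA")
  # machine-precision additivity zero for random h
  set.seed(2)
  for (i in 1:50) {
    h0 <- runif(1); hA <- runif(1, 0.1, 5); hB <- runif(1, 0, 5)
    expect_lt(abs(enhancement(h0, hA, hB, hA + hB - h0)), 1e-12)
  }
  # strictly increasing in hAB, strictly decreasing in hB
  set.seed(3)
  for (i in 1:30) {
    h0 <- runif(1); hA <- runif(1, 0.5, 3); hB <- runif(1, 0, 2)
    hAB <- hA + hB + runif(1)
    e0 <- enhancement(h0, hA, hB, hAB)
    expect_gt(enhancement(h0, hA, hB, hAB + 0.5), e0)
    if (!is.na(enhancement(h0, hA, hB + 0.5, hAB)))
      expect_lt(enhancement(h0, hA, hB + 0.5, hAB), e0)
  }
})

test_that("inject_predict: degenerate cases, additivity, seed stability", {
  g <- fx_grammar()
  pred <- oracle_predictor(g)
  # motifB = NULL: hB = h0 and hAB = hA by construction
  r <- inject_predict(pred, "ACATTCCTG", NULL, task = "TEAD4",
                      n_backgrounds = 8L, seed = 1L)
  expect_identical(r$hB, r$h0)
  expect_identical(r$hAB, r$hA)
  # c = 0 grammar: interaction term vanishes exactly (shared backgrounds)
  g0 <- make_grammar(list(soft_rules = list()))
  r0 <- inject_predict(oracle_predictor(g0), "ACATTCCTG", "CCCTCAGGC",
                       task = "TEAD4", distance = 20L, n_backgrounds = 16L,
                       seed = 2L)
  expect_lt(abs(r0$hAB - r0$hA - r0$hB + r0$h0), 1e-9)
  # Monte-Carlo stability: two seeds agree within 3 x sampling s.e.
  ra <- inject_predict(pred, "ACATTCCTG", "CCCTCAGGC", task = "TEAD4",
                       distance = 10L, n_backgrounds = 64L, seed = 3L)
  rb <- inject_predict(pred, "ACATTCCTG", "CCCTCAGGC", task = "TEAD4",
                       distance = 10L, n_backgrounds = 64L, seed = 4L)
  for (h in c("h0", "hA", "hB", "hAB")) {
    se <- sd(ra$per_background[, h]) / sqrt(64)
    expect_lt(abs(ra[[h]] - rb[[h]]), 3 * (se + 1e-3))
  }
  # overlapping placement rejected
  expect_error(inject_predict(pred, "ACATTCCTG", "CCCTCAGGC", task = "TEAD4",
                              distance = -3L, n_backgrounds = 2L), "distance")
  # background motif within 150 bp (Fig 1G-style protocol) boosts the task
  rbgm <- inject_predict(pred, "CCCTCAGGC", NULL, task = "TEAD4",
                         n_backgrounds = 16L, seed = 5L,
                         background_motif = "ACATTCCTG")
  expect_gt(rbgm$hA, rbgm$h0)
})

test_that("distance sweep recovers the planted decay; flat when additive", {
  g <- fx_grammar()
  pred <- oracle_predictor(g)
  sw <- distance_sweep(pred, "ACATTCCTG", "CCCTCAGGC", task = "TEAD4",
                       distances = c(0L, 20L, 40L, 80L, 120L),
                       n_backgrounds = 32L, seed = 1L)
  # d = 0: enhancement ~ log2(1 + c) = 2
  expect_lt(abs(sw$enhancement[1] - 2), 0.15)
  # monotone decay
  expect_true(all(diff(sw$enhancement) < 0))
  # tau recovery within 25%
  fit <- fit_enhancement_decay(sw)
  expect_lt(abs(fit$tau - 40) / 40, 0.25)
  # additive grammar: |enhancement| < 0.1 everywhere
  g0 <- make_grammar(list(soft_rules = list()))
  sw0 <- distance_sweep(oracle_predictor(g0), "ACATTCCTG", "CCCTCAGGC",
                        task = "TEAD4", distances = c(0L, 40L, 120L),
                        n_backgrounds = 32L, seed = 2L)
  expect_true(all(abs(sw0$enhancement) < 0.1))
})

test_that("directionality: only the boosted task is enhanced", {
  pred <- oracle_predictor(fx_grammar())
  eT <- inject_predict(pred, "ACATTCCTG", "CCCTCAGGC", task = "TEAD4",
                       distance = 5L, n_backgrounds = 32L, seed = 1L)$enhancement
  eY <- inject_predict(pred, "ACATTCCTG", "CCCTCAGGC", task = "YAP1",
                       distance = 5L, n_backgrounds = 32L, seed = 1L)$enhancement
  eF <- inject_predict(pred, "CCCTCAGGC", "ACATTCCTG", task = "TFAP2C",
                       distance = 5L, n_backgrounds = 32L, seed = 1L)$enhancement
  expect_gt(eT, 1.5)
  expect_gt(eY, 1.5)            # indirect task tracks the driver
  expect_lt(abs(eF), 0.1)       # the partner itself is not boosted
})

test_that("double_cooperativity recovers kappa; additive grammar gives 1", {
  for (kappa in c(1, 2, 4)) {
    g <- make_grammar(list(strict_rules = list(
      list(name = "tead_double", half = "tead_single", gap = 0L,
           kappa = kappa))))
    cc <- double_cooperativity(oracle_predictor(g),
                               g$strict_rules$tead_double$whole,
                               split = 9L, task = "TEAD4",
                               n_backgrounds = 64L, seed = 1L)
    expect_lt(abs(cc$fold - kappa) / kappa, 0.2)
    if (kappa == 1) { expect_gte(cc$fold, 0.9); expect_lte(cc$fold, 1.1) }
  }
  # ESC-like grammar: lower amplitude, kappa 2
  gesc <- make_grammar(list(
    motifs = list(
      list(name = "tead_single", consensus = "ACATTCCTG", amplitude = 8,
           task = "TEAD4"),
      list(name = "tfap2c", consensus = "CCCTCAGGC", amplitude = 15,
           task = "TFAP2C")),
    strict_rules = list(list(name = "tead_double", half = "tead_single",
                             gap = 0L, kappa = 2))))
  ccesc <- double_cooperativity(oracle_predictor(gesc),
                                gesc$strict_rules$tead_double$whole,
                                split = 9L, task = "TEAD4",
                                n_backgrounds = 64L, seed = 2L)
  expect_lt(abs(ccesc$fold - 2) / 2, 0.2)
  expect_error(double_cooperativity(oracle_predictor(gesc), "ACGT", split = 8L,
                                    task = "TEAD4"), "split")
})

test_that("spacing perturbations: deletion kills cooperativity, edits invert", {
  g <- fx_grammar()
  pred <- oracle_predictor(g)
  whole <- g$strict_rules$tead_double$whole
  pp <- spacing_perturbation(pred, whole, split = 9L, edits = c(0L, -1L, 1L),
                             task = "TEAD4", n_backgrounds = 24L, seed = 1L)
  f0 <- pp$fold[pp$edit == 0]
  expect_lt(abs(f0 - 4) / 4, 0.2)
  # 1-bp deletion at the gap: fold collapses from kappa to ~1
  expect_lt(pp$fold[pp$edit == -1], 1.4)
  # 1-bp insertion also disrupts the strict spacing
  expect_lt(pp$fold[pp$edit == 1], 1.4)
  # edit size 0 reproduces the unedited sequence
  expect_identical(pp$sequence[pp$edit == 0], whole)
  # insert then delete restores the original sequence
  ins <- spacing_perturbation(pred, whole, split = 9L, edits = 1L,
                              task = "TEAD4", n_backgrounds = 2L, seed = 1L)
  redel <- spacing_perturbation(pred, ins$sequence[1], split = 10L,
                                edits = -1L, task = "TEAD4",
                                n_backgrounds = 2L, seed = 1L)
  expect_identical(redel$sequence[1], whole)
  # an edit destroying a half-site core errors
  expect_error(spacing_perturbation(pred, whole, split = 9L, edits = -5L,
                                    task = "TEAD4"), "core")
  # profiles around the motif are returned per edit
  expect_named(attr(pp, "profiles"), c("0", "-1", "1"))
})

test_that("design_minimal_mutation picks the top contributing bases", {
  # synthetic map with known contributions
  seq <- strrep("A", 20)
  score <- rep(0, 20)
  score[5:10] <- c(0.9, 0.1, 0.8, 0.0, 0.3, 0.2)
  hyp <- matrix(0.1, 20, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  hyp[5, ] <- c(0.9, -0.5, 0.1, 0.2)    # worst base at position 5 is C
  hyp[7, ] <- c(0.8, 0.3, -0.9, 0.1)    # worst base at position 7 is G
  cmap <- structure(list(seq = seq, task = "T", score = score, hyp = hyp),
                    class = "contribution_map")
  res <- design_minimal_mutation(cmap, list(start = 4L, end = 10L), k = 2L)
  expect_identical(sort(res$report$position), c(4L, 6L))   # 0-based
  expect_identical(res$report$to[res$report$position == 4L], "C")
  expect_identical(res$report$to[res$report$position == 6L], "G")
  expect_identical(substr(res$seq, 5, 5), "C")
  expect_identical(substr(res$seq, 7, 7), "G")
  # k = 0: unchanged
  expect_identical(design_minimal_mutation(cmap, list(start = 4L, end = 10L),
                                           k = 0L)$seq, seq)
  # all-equal contributions: leftmost tie-break, flagged
  flat <- cmap; flat$score <- rep(0.5, 20)
  rflat <- design_minimal_mutation(flat, list(start = 4L, end = 10L), k = 1L)
  expect_true(rflat$tie_flag)
  expect_identical(rflat$report$position, 4L)
  expect_error(design_minimal_mutation(cmap, list(start = 4L, end = 10L),
                                       k = 10L), "width")
})

test_that("oracle fixture: minimal mutation halves the prediction", {
  g <- fx_grammar()
  pred <- oracle_predictor(g)
  set.seed(12)
  seq <- synlab:::write_sub(synlab:::random_dna(1000, 0.42), 496, "ACATTCCTG")
  cm <- contribution_scores(pred, seq, "TEAD4", seed = 1L)
  res <- design_minimal_mutation(cm, list(start = 495L, end = 504L), k = 2L)
  c_wt <- predict_binding(pred, seq)$TEAD4$counts
  c_mut <- predict_binding(pred, res$seq)$TEAD4$counts
  expect_lt(c_mut, 0.5 * c_wt)
})

test_that("move_motif relocates and knocks out the original", {
  g <- fx_grammar()
  pred <- oracle_predictor(g)
  set.seed(13)
  bg <- synlab:::random_dna(1000, 0.42)
  # anchor tfap2c at 400 (0-based), tead at gap 20 to its right
  seq <- synlab:::write_sub(bg, 401, "CCCTCAGGC")
  tead_start <- 409L + 20L
  seq <- synlab:::write_sub(seq, tead_start + 1L, "ACATTCCTG")
  anchor <- list(start = 400L, end = 409L)
  inst <- list(start = tead_start, end = tead_start + 9L)
  cm <- contribution_scores(pred, seq, "TEAD4", seed = 1L)
  moved <- move_motif(seq, inst, anchor, new_gap = 60L, cmap = cm, k = 2L)
  expect_identical(nchar(moved), nchar(seq))
  # boost is monotone in distance: counts at the anchor drop
  win <- 380:440
  p_old <- predict_binding(pred, seq)$TEAD4
  p_new <- predict_binding(pred, moved)$TEAD4
  expect_lt(p_new$counts, p_old$counts)
  # same-gap move is a mutate-then-rewrite round trip: near wild type
  same <- move_motif(seq, inst, anchor, new_gap = 20L, cmap = cm, k = 2L)
  expect_identical(same, seq)
  # invalid placements error
  expect_error(move_motif(seq, inst, anchor, new_gap = 900L, cmap = cm),
               "bounds")
  expect_error(move_motif(seq, inst, anchor, new_gap = -5L, cmap = cm),
               "overlap")
})
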