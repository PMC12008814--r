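# Simulator module: grammar validation, genome planting, occupancy oracle,
# profile noise model.

test_that("make_grammar validates and builds the default grammar", {
  g <- make_grammar()
  expect_s3_class(g, "tf_grammar")
  expect_length(g$motifs, 2L)
  expect_equal(g$motifs$tead_single$consensus, "ACATTCCTG")
  expect_equal(g$motifs$tfap2c$consensus, "CCCTCAGGC")
  expect_setequal(g$tasks, c("TEAD4", "TFAP2C", "YAP1"))
  # derived double = two half-sites, instantiating the spacing-2 template
  expect_equal(g$strict_rules$tead_double$whole, "ACATTCCTGACATTCCTG")
  # kernels normalized: one strand-pair sums to 1
  expect_equal(2 * sum(g$kernel$vec), 1, tolerance = 1e-12)

  # purely additive grammar is accepted
  g0 <- make_grammar(list(
    soft_rules = list(list(task = "TEAD4", partner = "tfap2c", c = 0,
                           tau = 40, range = 150)),
    strict_rules = list(list(name = "tead_double", half = "tead_single",
                             gap = 0L, kappa = 1))))
  expect_equal(g0$strict_rules$tead_double$kappa, 1)

  # degenerate parameters are rejected with named validation errors
  expect_error(make_grammar(list(soft_rules = list(
    list(task = "TEAD4", partner = "tfap2c", c = 3, tau = 0, range = 150)))),
    "tau")
  expect_error(make_grammar(list(strict_rules = list(
    list(name = "d", half = "tead_single", gap = 0L, kappa = 0.5)))),
    "kappa")
  expect_error(make_grammar(list(kernel = list(width = 41L, sd = -1, offset = 5L))),
    "normalizable")
  expect_error(make_grammar(list(motifs = list())), "no motifs")
  expect_error(make_grammar(list(motifs = list(
    list(name = "x", consensus = "ACGTN", amplitude = 1, task = "T")))),
    "A,C,G,T")
})

test_that("simulate_genome plants at the expected density, reproducibly", {
  g <- make_grammar()
  genome <- simulate_genome(g, n_contigs = 4L, contig_len = 100000L,
                            density = 0.05, seed = 1L)
  # analytic expectation per motif: n_contigs * contig_len * density / 1000
  expected <- 4 * 100000 * 0.05 / 1000
  counts <- table(genome$truth$motif)
  for (m in names(counts))
    expect_lt(abs(counts[[m]] - expected), 4 * sqrt(expected) + 1)
  # all truth within contigs, non-overlapping
  expect_true(all(genome$truth$start >= 0))
  expect_true(all(genome$truth$end <= 100000))
  for (cn in unique(genome$truth$contig)) {
    tt <- genome$truth[genome$truth$contig == cn, ]
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1) expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  }
  # determinism
  genome2 <- simulate_genome(g, n_contigs = 4L, contig_len = 100000L,
                             density = 0.05, seed = 1L)
  expect_identical(genome$contigs, genome2$contigs)
  expect_identical(genome$truth, genome2$truth)
  # density 0 -> pure background
  g0 <- simulate_genome(g, n_contigs = 1L, contig_len = 2000L, density = 0,
                        seed = 1L)
  expect_identical(nrow(g0$truth), 0L)
  # infeasible density errors
  expect_error(simulate_genome(g, n_contigs = 1L, contig_len = 1000L,
                               density = 60, seed = 1L), "infeasible")
})

test_that("oracle_occupancy matches its closed forms", {
  g <- make_grammar()
  genome <- simulate_genome(g, n_contigs = 1L, contig_len = 50000L,
                            density = 0.02, seed = 5L)
  tr <- genome$truth
  # consensus instance with no partner in range: occupancy = A
  iso <- which(tr$mismatches == 0 & tr$boost == 1 & !tr$is_double)
  expect_gt(length(iso), 0)
  i <- iso[1]
  A <- g$motifs[[tr$motif[i]]]$amplitude
  expect_equal(oracle_occupancy(g, genome, tr[i, ]), A)
  # whole double with two consensus halves: occupancy = kappa * 2A
  dbl <- which(tr$is_double & tr$mismatches == 0 & tr$boost == 1)
  if (length(dbl))
    expect_equal(oracle_occupancy(g, genome, tr[dbl[1], ]),
                 4 * 2 * g$motifs$tead_single$amplitude)
  # brute-force check of the boost product for every TEAD4 instance
  for (i in which(tr$task == "TEAD4")) {
    partners <- tr[tr$motif == "tfap2c" & tr$contig == tr$contig[i], ]
    boost <- 1
    if (nrow(partners)) {
      d <- synlab:::edge_gap(tr$start[i], tr$end[i], partners$start, partners$end)
      keep <- d <= 150
      rel <- partners$occ_base[keep] / g$motifs$tfap2c$amplitude
      boost <- prod(1 + 3 * exp(-d[keep] / 40) * rel)
    }
    expect_equal(tr$occupancy[i], tr$occ_base[i] * boost, tolerance = 1e-12)
  }
  # unknown motif errors
  expect_error(oracle_occupancy(g, genome, list(contig = "chr1", start = 0,
                                                end = 9, motif = "nope")),
               "not in grammar")
})

test_that("closed-form soft boost: 1 + c*exp(-d/tau), 4x at d = 0", {
  g <- make_grammar()
  pred <- oracle_predictor(g)
  # neutral background with no chance matches, so the ratio is exact
  neutral <- strrep("AC", 500)
  mk <- function(gap) {
    s <- synlab:::write_sub(neutral, 401, "ACATTCCTG")
    synlab:::write_sub(s, 401 + 9 + gap, "CCCTCAGGC")
  }
  bg <- 2 * 1000 * g$depth
  cA <- predict_binding(pred, synlab:::write_sub(neutral, 401, "ACATTCCTG"))$TEAD4$counts
  for (d in c(0, 40, 120)) {
    boost <- 1 + 3 * exp(-d / 40)
    expect_equal((predict_binding(pred, mk(d))$TEAD4$counts - bg) / (cA - bg),
                 boost, tolerance = 1e-6)
  }
  # beyond range: no boost
  expect_equal((predict_binding(pred, mk(200))$TEAD4$counts - bg) / (cA - bg),
               1, tolerance = 1e-6)
})

test_that("simulate_profiles has Poisson means consistent with the grammar", {
  # zero-amplitude grammar: genome-wide mean counts ~ depth per strand
  gz <- make_grammar(list(
    motifs = list(list(name = "tead_single", consensus = "ACATTCCTG",
                       amplitude = 0, task = "TEAD4")),
    soft_rules = list(), strict_rules = list(), indirect_map = c(),
    depth = 0.1))
  genome <- simulate_genome(gz, n_contigs = 1L, contig_len = 50000L,
                            density = 0.02, seed = 2L)
  prof <- simulate_profiles(genome, gz, depth = 0.1, seed = 3L)
  m <- mean(c(prof$TEAD4$chr1$plus, prof$TEAD4$chr1$minus))
  se <- sqrt(0.1 / (2 * 50000))
  expect_lt(abs(m - 0.1), 3 * se)

  # single consensus instance, depth = 0: reads confined to kernel support
  g <- make_grammar()
  seq <- fx_pair_seq(gap = 300L)$seq
  genome1 <- structure(list(contigs = c(chr1 = seq),
                            truth = data.frame(contig = "chr1", start = 495L,
                                               end = 504L, strand = "+",
                                               motif = "tead_single",
                                               mismatches = 0L)),
                       class = "synthetic_genome")
  genome1$truth <- synlab:::annotate_truth_occupancy(g, genome1)
  prof1 <- simulate_profiles(genome1, g, depth = 0, seed = 4L)
  reads <- which(prof1$TEAD4$chr1$plus + prof1$TEAD4$chr1$minus > 0)
  half <- (g$kernel$width - 1) / 2
  support <- (495 - g$kernel$offset - half + 1):(504 + g$kernel$offset + half)
  expect_true(all(reads %in% support))

  # total reads ~ sum of occupancies + background (Poisson concentration)
  genome2 <- simulate_genome(g, n_contigs = 1L, contig_len = 100000L,
                             density = 0.05, seed = 6L)
  prof2 <- simulate_profiles(genome2, g, seed = 7L)
  for (task in c("TEAD4", "TFAP2C")) {
    keep <- genome2$truth$motif %in% synlab:::task_motifs(g, task)
    expect_total <- sum(genome2$truth$occupancy[keep]) + 2 * 100000 * g$depth
    got <- sum(prof2[[task]]$chr1$plus) + sum(prof2[[task]]$chr1$minus)
    expect_lt(abs(got - expect_total), 4 * sqrt(expect_total))
  }
  # determinism
  prof2b <- simulate_profiles(genome2, g, seed = 7L)
  expect_identical(prof2, prof2b)
})

test_that("strand symmetry: reverse-complemented contig mirrors profiles", {
  g <- make_grammar()
  genome <- simulate_genome(g, n_contigs = 1L, contig_len = 20000L,
                            density = 0.05, seed = 8L)
  L <- 20000L
  rc <- structure(list(contigs = c(chr1 = revcomp(genome$contigs[["chr1"]])),
                       truth = data.frame(
                         contig = "chr1",
                         start = L - genome$truth$end,
                         end = L - genome$truth$start,
                         strand = ifelse(genome$truth$strand == "+", "-", "+"),
                         motif = genome$truth$motif,
                         mismatches = genome$truth$mismatches)),
                  class = "synthetic_genome")
  rc$truth <- synlab:::annotate_truth_occupancy(g, rc)
  ex <- expected_profiles(genome, g)
  exrc <- expected_profiles(rc, g)
  for (task in g$tasks) {
    expect_equal(exrc[[task]]$chr1$plus, rev(ex[[task]]$chr1$minus),
                 tolerance = 1e-9)
    expect_equal(exrc[[task]]$chr1$minus, rev(ex[[task]]$chr1$plus),
                 tolerance = 1e-9)
  }
})

test_that("oracle additivity limit: c=0, kappa=1 predictions are additive", {
  g <- make_grammar(list(
    soft_rules = list(),
    strict_rules = list(list(name = "tead_double", half = "tead_single",
                             gap = 0L, kappa = 1))))
  pred <- oracle_predictor(g)
  set.seed(9)
  bg <- random_dna(1000, g$gc)
  sA <- synlab:::write_sub(bg, 201, "ACATTCCTG")
  sB <- synlab:::write_sub(bg, 601, "CCCTCAGGC")
  sAB <- synlab:::write_sub(sA, 601, "CCCTCAGGC")
  for (task in g$tasks) {
    pa <- predict_binding(pred, sA)[[task]]
    pb <- predict_binding(pred, sB)[[task]]
    p0 <- predict_binding(pred, bg)[[task]]
    pab <- predict_binding(pred, sAB)[[task]]
    expect_equal(pab$plus, pa$plus + pb$plus - p0$plus, tolerance = 1e-12)
    expect_equal(pab$counts, pa$counts + pb$counts - p0$counts,
                 tolerance = 1e-9)
  }
})

test_that("oracle predictor is deterministic and rejects bad sequences", {
  pred <- oracle_predictor(fx_grammar())
  seq <- fx_pair_seq()$seq
  expect_identical(predict_binding(pred, seq), predict_binding(pred, seq))
  expect_error(predict_binding(pred, "ACGTX"), "non-ACGT")
})

test_that("negative-binomial dispersion option changes the noise, not the mean", {
  g <- make_grammar(list(dispersion = 2))
  genome <- simulate_genome(g, n_contigs = 1L, contig_len = 50000L,
                            density = 0.05, seed = 10L)
  prof <- simulate_profiles(genome, g, seed = 11L)
  keep <- genome$truth$motif %in% synlab:::task_motifs(g, "TEAD4")
  expect_total <- sum(genome$truth$occupancy[keep]) + 2 * 50000 * g$depth
  got <- sum(prof$TEAD4$chr1$plus) + sum(prof$TEAD4$chr1$minus)
  # NB variance is larger; allow a generous band around the mean
  expect_lt(abs(got - expect_total), 10 * sqrt(expect_total))
})
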