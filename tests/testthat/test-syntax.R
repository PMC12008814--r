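# Syntax module: distance-binned contributions, percent slope, islands,
# IUPAC double-pattern scanning, variant frequency analysis.

test_that("scan_double_pattern matches the quoted spacing-2 template", {
  # core + NN + core: one pair at spacing 2 (plus its reverse complement)
  seq <- paste0(strrep("T", 30), "ACATTCCTGGCATTCC", strrep("T", 30))
  res <- scan_double_pattern(c(chrT = seq))
  plus <- res$pairs[res$pairs$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$spacing, 2L)
  expect_identical(res$spacing$count[res$spacing$spacing == 2], 1L)
  # singles require the full 9-mer pattern
  expect_gte(nrow(res$singles), 1L)
  # invalid IUPAC rejected
  expect_error(scan_double_pattern(c(a = "ACGT"), core_pattern = "RMAXTCC"),
               "IUPAC")
})

test_that("scan_double_pattern is strand-symmetric and equals brute force", {
  g <- fx_grammar()
  set.seed(51)
  base <- synlab:::random_dna(10000, 0.42)
  # plant a few doubles at known spacings
  for (off in c(1001, 3001, 5001))
    base <- synlab:::write_sub(base, off, "ACATTCCTGGCATTCC")
  base <- synlab:::write_sub(base, 7001, "GCATTCCAAAAAAATTCCTG")  # extra core-like content
  seqs <- c(chr1 = base)
  res <- scan_double_pattern(seqs)
  ref <- brute_double_scan(seqs)
  expect_equal(res$pairs$start, ref$start)
  expect_equal(res$pairs$end, ref$end)
  expect_equal(res$pairs$spacing, ref$spacing)
  expect_equal(res$pairs$strand, ref$strand)
  # reverse complement of the fixture gives an identical spacing table
  rcres <- scan_double_pattern(c(chr1 = revcomp(base)))
  expect_identical(res$spacing, rcres$spacing)
})

test_that("build_islands merges 500 bp windows and is well-behaved", {
  mk <- function(start, end, contig = "c") {
    data.frame(contig = contig, start = start, end = end, strand = "+",
               motif_name = "m", match_score = 1,
               total_contribution = 1, source = "planted",
               stringsAsFactors = FALSE)
  }
  # motifs centered at 100 and 400: one island spanning [0, 650) after clip
  inst <- rbind(mk(95, 105), mk(395, 405))
  isl <- build_islands(inst, contig_lengths = c(c = 10000))
  expect_identical(nrow(isl), 1L)
  expect_identical(isl$start, 0L)
  expect_identical(isl$end, 650L)
  expect_identical(isl$n_instances, 2L)
  # motifs 1000 bp apart: two islands
  isl2 <- build_islands(rbind(mk(95, 105), mk(1095, 1105)))
  expect_identical(nrow(isl2), 2L)
  # idempotence: islands built from island-member instances are identical
  w <- fx_small_world()
  tr <- w$genome$truth
  inst3 <- data.frame(contig = tr$contig, start = tr$start, end = tr$end,
                      strand = tr$strand, motif_name = tr$motif,
                      match_score = 1, total_contribution = 1,
                      source = "planted", stringsAsFactors = FALSE)
  isl3 <- build_islands(inst3)
  again <- build_islands(inst3)
  expect_identical(isl3[, c("contig", "start", "end")],
                   again[, c("contig", "start", "end")])
  # islands pairwise disjoint; each instance in exactly one island
  for (cn in unique(isl3$contig)) {
    ii <- isl3[isl3$contig == cn, ]
    ii <- ii[order(ii$start), ]
    if (nrow(ii) > 1) expect_true(all(ii$start[-1] >= ii$end[-nrow(ii)]))
  }
  members <- sort(unlist(isl3$members))
  expect_identical(members, seq_len(nrow(inst3)))
  # order independence
  set.seed(4)
  shuf <- inst3[sample(nrow(inst3)), ]
  isl4 <- build_islands(shuf)
  expect_identical(isl3[, c("contig", "start", "end", "n_instances")],
                   isl4[, c("contig", "start", "end", "n_instances")])
})

test_that("distance_contributions: boosted grammar decays, bins report gaps", {
  # constructed pair geometry covering every bin plus a large baseline, with
  # contributions from the grammar's analytic boost (oracle-monotone decay)
  set.seed(81)
  gaps <- c(rep(c(5, 15, 25), 15), rep(c(35, 45, 55), 15),
            rep(c(70, 100, 140), 15))
  baseline_gaps <- runif(120, 200, 5000)
  all_gaps <- c(gaps, baseline_gaps)
  starts <- cumsum(rep(8000, length(all_gaps)))
  instA <- data.frame(contig = "c", start = starts, end = starts + 9L,
                      stringsAsFactors = FALSE)
  instB <- data.frame(contig = "c", start = starts + 9L + round(all_gaps),
                      end = starts + 18L + round(all_gaps),
                      stringsAsFactors = FALSE)
  occ <- 15 * exp(-2.5 * sample(0:1, length(all_gaps), TRUE, c(0.9, 0.1)))
  instB$total_contribution <- occ * (1 + 3 * exp(-all_gaps / 40))
  res <- distance_contributions(instA, instB, bins = c(0, 30, 60, 150))
  tab <- res$table
  got <- tab$median_log2_ratio[!is.na(tab$median_log2_ratio)]
  expect_true(all(diff(got) < 0))        # strictly decreasing across bins
  expect_gt(got[1], 0)
  # empty bin reported as missing, not zero
  res2 <- distance_contributions(instA, instB, bins = c(0, 1, 30, 150))
  expect_true(is.na(res2$table$median_log2_ratio[1]) ||
                res2$table$n[1] > 0)
  # empty baseline errors with advice
  expect_error(distance_contributions(instA, instB, baseline_min_gap = 1e9),
               "baseline")
})

test_that("distance_contributions null calibration under an additive grammar", {
  # 20 seeded replicates; fraction of bins with p < 0.05 must be <= 0.1
  g0 <- make_grammar(list(soft_rules = list()))
  n_sig <- 0L; n_bins <- 0L
  set.seed(60)
  for (rep_i in 1:20) {
    nA <- 60; nB <- 200
    instA <- data.frame(contig = "c", start = sort(sample(1:200000, nA)) ,
                        end = 0L, stringsAsFactors = FALSE)
    instA$end <- instA$start + 9L
    instB <- data.frame(contig = "c", start = sort(sample(1:200000, nB)),
                        end = 0L, stringsAsFactors = FALSE)
    instB$end <- instB$start + 9L
    # contributions independent of distance (additive world): occupancy-like
    instB$total_contribution <- 15 * exp(-2.5 * sample(0:1, nB, TRUE, c(.9, .1)))
    res <- tryCatch(distance_contributions(instA, instB,
                                           bins = c(0, 30, 60, 150)),
                    error = function(e) NULL)
    if (is.null(res)) next
    p <- res$table$p_value
    n_sig <- n_sig + sum(p < 0.05, na.rm = TRUE)
    n_bins <- n_bins + sum(!is.na(p))
  }
  expect_gt(n_bins, 20)
  expect_lte(n_sig / n_bins, 0.1)
})

test_that("distance_slope: closed form, permutation null, degenerate cases", {
  # exact synthetic line: contribution = 2 - 0.01 * gap -> -5% per 10 bp
  gaps <- seq(0, 140, by = 2)
  pairs <- data.frame(gap = gaps, contribution = 2 - 0.01 * gaps)
  res <- distance_slope(pairs)
  expect_equal(res$slope_pct_per_10bp, -5, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-12)
  # permuted gaps: small slope, p > 0.05
  set.seed(71)
  noisy <- data.frame(gap = gaps,
                      contribution = 2 - 0.01 * gaps + rnorm(length(gaps), 0, 0.3))
  perm <- noisy
  perm$gap <- sample(perm$gap)
  resp <- distance_slope(perm)
  expect_gt(resp$p_value, 0.05)
  # constant contributions: slope 0
  resc <- distance_slope(data.frame(gap = gaps, contribution = rep(2, length(gaps))))
  expect_equal(resc$slope_pct_per_10bp, 0, tolerance = 1e-9)
  # non-positive intercept: percent form unavailable, flagged
  resn <- distance_slope(data.frame(gap = gaps, contribution = 0.005 * gaps - 0.5))
  expect_false(resn$percent_form)
  expect_true(is.na(resn$slope_pct_per_10bp))
  # too few pairs errors
  expect_error(distance_slope(pairs[1:5, ]), ">= 10")
})

test_that("variant_frequency_analysis filters and ranks by affinity", {
  pred <- oracle_predictor(fx_grammar())
  # counts {P1: 50, P2: 12, P3: 3}: P3 removed by the >= 10 rule
  seqs <- c(rep("ACATTCCTG", 50), rep("ACATTCCTA", 12), rep("ACATTCCGA", 3))
  tab <- variant_frequency_analysis(seqs, pred, task = "TEAD4",
                                    n_backgrounds = 8L, seed = 1L,
                                    percentile = 0.5)
  expect_false("ACATTCCGA" %in% tab$pattern)
  # consensus has the highest mean injected prediction (affinity ordering)
  expect_identical(tab$pattern[which.max(tab$mean_prediction)], "ACATTCCTG")
  expect_gt(tab$mean_prediction[tab$pattern == "ACATTCCTG"],
            tab$mean_prediction[tab$pattern == "ACATTCCTA"])
  # single unique pattern repeated 20x survives both filters
  tab1 <- variant_frequency_analysis(rep("ACATTCCTG", 20), pred,
                                     task = "TEAD4", n_backgrounds = 4L,
                                     seed = 2L)
  expect_identical(nrow(tab1), 1L)
  # nothing surviving: empty table with warning
  expect_warning(
    empty <- variant_frequency_analysis(c("AAAA", "CCCC"), pred,
                                        task = "TEAD4", n_backgrounds = 2L,
                                        seed = 3L),
    "no pattern")
  expect_identical(nrow(empty), 0L)
})
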