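# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_grammar <- function() {
  if (is.null(.fx$grammar)) .fx$grammar <- make_grammar()
  .fx$grammar
}

# small stated-world genome + profiles + oracle maps (TEAD4 task)
fx_small_world <- function() {
  if (!is.null(.fx$world)) return(.fx$world)
  g <- fx_grammar()
  genome <- simulate_genome(g, n_contigs = 2L, contig_len = 150000L,
                            density = default_planting_density(), seed = 1L)
  profiles <- simulate_profiles(genome, g, seed = 2L)
  ds <- make_training_set(genome, profiles,
                          split = c(chr1 = "train", chr2 = "train"), seed = 3L)
  pred <- oracle_predictor(g)
  idx <- which(ds$meta$motif != "background")
  cmaps <- lapply(seq_along(idx), function(k)
    contribution_scores(pred, ds$windows[[idx[k]]]$seq, "TEAD4", seed = k))
  .fx$world <- list(grammar = g, genome = genome, profiles = profiles,
                    dataset = ds, pred = pred, idx = idx, cmaps = cmaps)
  .fx$world
}

# one clean 1 kb sequence with a planted consensus single motif + partner
fx_pair_seq <- function(gap = 30L) {
  g <- fx_grammar()
  set.seed(42)
  bg <- random_dna(1000, g$gc)
  sA <- 496L                     # 1-based start of tead_single
  seq <- synlab:::write_sub(bg, sA, "ACATTCCTG")
  sB <- sA + 9L + gap
  seq <- synlab:::write_sub(seq, sB, "CCCTCAGGC")
  list(seq = seq, startA = sA - 1L, startB = sB - 1L)   # 0-based
}

overlap_bp <- function(a, b) pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))

# recall of truth instances by calls; a truth instance is recovered when a
# call covers >= 50% of it
recall_of <- function(truth, calls) {
  if (!nrow(truth)) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(i) {
    cand <- calls[calls$contig == truth$contig[i], , drop = FALSE]
    nrow(cand) > 0 &&
      any(overlap_bp(truth[i, ], cand) >= 0.5 * (truth$end[i] - truth$start[i]))
  }, logical(1)))
}

# precision of calls against truth; a call is correct when it covers >= 50%
# of some truth instance
precision_of <- function(calls, truth) {
  if (!nrow(calls)) return(NA_real_)
  mean(vapply(seq_len(nrow(calls)), function(i) {
    cand <- truth[truth$contig == calls$contig[i], , drop = FALSE]
    nrow(cand) > 0 &&
      any(overlap_bp(calls[i, ], cand) >= 0.5 * (cand$end - cand$start))
  }, logical(1)))
}

# Pearson correlation of two motifs' PWMs over their best ungapped alignment
# (both orientations), using the CWM-based aligner for the offset
aligned_pwm_pearson <- function(discovered, planted) {
  al <- synlab:::best_alignment(planted$cwm, discovered$cwm)
  m2 <- if (al$rc) synlab:::rc_matrix(discovered$pwm) else discovered$pwm
  W <- ncol(planted$pwm); Ws <- ncol(m2); off <- al$offset
  c1 <- max(1L, 1L + off); c2 <- min(W, Ws + off)
  if (c2 < c1 + 3) return(-1)
  stats::cor(as.vector(planted$pwm[, c1:c2]),
             as.vector(m2[, (c1 - off):(c2 - off)]))
}
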