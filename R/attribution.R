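# Contribution scores (gradient x input vs dinucleotide-shuffled references),
# seqlet extraction and greedy CWM/PWM motif discovery.

#' Per-base contribution scores for a predictor's counts output
#'
#' The attribution is gradient x input relative to `n_refs` dinucleotide-
#' shuffled reference sequences: per position, score = sum_b (x - mean_ref)[b]
#' * grad[b], where grad is the gradient of the task's log1p(total counts)
#' output at the observed sequence. The full "hypothetical" matrix
#' (grad centered by the reference expectation, 4 x L) is kept for CWM
#' scanning and mutation design. Deterministic under `seed`.
#'
#' @param predictor a binding predictor.
#' @param seq DNA string (predictor's window length for trained models).
#' @param task task name.
#' @param n_refs number of shuffled references (>= 1).
#' @param seed RNG seed for the shuffles.
#' @return a `contribution_map`: list(seq, task, score (length-L numeric),
#'   hyp (L x 4), refspec).
#' @export
contribution_scores <- function(predictor, seq, task, n_refs = 20L, seed = 1L) {
  if (n_refs < 1) stop("n_refs must be >= 1")
  x <- onehot(seq)
  grad <- count_score_grad(predictor, seq, task)
  refmean <- with_seed(seed, {
    acc <- matrix(0, nrow(x), 4L)
    for (i in seq_len(n_refs)) acc <- acc + onehot(dinuc_shuffle(seq))
    acc / n_refs
  })
  hyp <- grad - rowSums(refmean * grad)   # center each position by E_ref[grad]
  score <- rowSums((x - refmean) * grad)
  structure(list(seq = seq, task = task, score = score, hyp = hyp,
                 refspec = sprintf("%d dinucleotide-shuffled references, seed %d",
                                   n_refs, seed)),
            class = "contribution_map")
}

#' One-hot-masked 4 x L contribution matrix of a map
#' @noRd
cmap_matrix <- function(cmap) {
  x <- onehot(cmap$seq)
  t(x * cmap$score)    # 4 x L, observed base carries the score
}

#' Extract high-contribution seqlets from contribution maps
#'
#' Maximal runs of bases whose 7-bp moving average of |score| exceeds the
#' per-map `threshold_quantile` quantile, extended by `flank` bp and merged
#' when overlapping.
#'
#' @param cmaps a `contribution_map` or list of them.
#' @param flank extension in bp.
#' @param threshold_quantile per-map quantile in (0, 1).
#' @param smooth moving-average width (bp).
#' @return data.frame of seqlets: map index, 0-based start/end, sequence,
#'   score sum; plus a list-column of per-base scores.
#' @export
extract_seqlets <- function(cmaps, flank = 3L, threshold_quantile = 0.99,
                            smooth = 7L) {
  if (inherits(cmaps, "contribution_map")) cmaps <- list(cmaps)
  if (!length(cmaps)) stop("need at least one contribution map")
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("threshold_quantile must be in (0,1)")
  out <- list()
  for (mi in seq_along(cmaps)) {
    cm <- cmaps[[mi]]
    a <- abs(cm$score)
    sm <- as.numeric(stats::filter(a, rep(1 / smooth, smooth), sides = 2))
    sm[is.na(sm)] <- 0
    thr <- stats::quantile(sm, threshold_quantile)
    if (thr <= 0) next
    above <- sm > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    runs[, 1] <- pmax(1L, runs[, 1] - flank)
    runs[, 2] <- pmin(length(a), runs[, 2] + flank)
    # merge overlapping/adjacent runs
    merged <- list(); cur <- runs[1, ]
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      if (runs[i, 1] <= cur[2] + 1L) cur[2] <- max(cur[2], runs[i, 2])
      else { merged[[length(merged) + 1L]] <- cur; cur <- runs[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    for (m in merged) {
      s0 <- m[1] - 1L; e0 <- m[2]         # 0-based half-open
      out[[length(out) + 1L]] <- data.frame(
        map = mi, start = s0, end = e0,
        seq = substr(cm$seq, s0 + 1L, e0),
        score_sum = sum(cm$score[(s0 + 1L):e0]),
        stringsAsFactors = FALSE
      )
      out[[length(out)]]$scores <- I(list(cm$score[(s0 + 1L):e0]))
    }
  }
  if (!length(out))
    return(data.frame(map = integer(0), start = integer(0), end = integer(0),
                      seq = character(0), score_sum = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Continuous Jaccard similarity between two signed matrices
#'
#' sum(min(|a|,|b|) * sign_agreement) / sum(max(|a|,|b|)); in [-1, 1].
#' @noRd
cont_jaccard <- function(a, b) {
  den <- sum(pmax(abs(a), abs(b)))
  if (den == 0) return(0)
  sum(pmin(abs(a), abs(b)) * sign(a) * sign(b)) / den
}

#' Reverse-complement a 4 x W matrix with rows A,C,G,T
#' @noRd
rc_matrix <- function(m) m[4:1, ncol(m):1, drop = FALSE]

#' Best ungapped alignment of a seqlet matrix to a CWM
#' @noRd
best_alignment <- function(cwm, smat) {
  W <- ncol(cwm); Ws <- ncol(smat)
  best <- list(sim = -Inf, offset = 0L, rc = FALSE)
  for (rc in c(FALSE, TRUE)) {
    m <- if (rc) rc_matrix(smat) else smat
    for (off in (-Ws + 1L):(W - 1L)) {
      # columns of cwm overlapped by m shifted by off
      c1 <- max(1L, 1L + off); c2 <- min(W, Ws + off)
      if (c2 - c1 + 1L < min(5L, W, Ws)) next
      s1 <- c1 - off; s2 <- c2 - off
      sim <- cont_jaccard(cwm[, c1:c2, drop = FALSE], m[, s1:s2, drop = FALSE])
      if (sim > best$sim) best <- list(sim = sim, offset = off, rc = rc)
    }
  }
  best
}

#' Greedy clustering of seqlets into CWM/PWM motifs
#'
#' Seeds a cluster from the highest-|score| unassigned seqlet, assigns seqlets
#' whose best ungapped alignment (over offsets and both orientations) to the
#' cluster CWM exceeds `sim_threshold`, recomputes the CWM/PWM as aligned
#' averages, and repeats on unassigned seqlets. Clusters with support below
#' `min_support` are discarded; at most `max_motifs` motifs are returned,
#' sorted by total absolute contribution.
#'
#' @param seqlets from [extract_seqlets()].
#' @param min_support minimum seqlets per motif.
#' @param max_motifs maximum motifs returned.
#' @param sim_threshold continuous-Jaccard assignment threshold.
#' @param width motif window width used for aligned averaging.
#' @return list of `motif` objects (name, pwm, cwm, consensus, support).
#' @export
discover_motifs <- function(seqlets, min_support = 10L, max_motifs = 10L,
                            sim_threshold = 0.3, width = 24L) {
  if (!nrow(seqlets)) return(list())
  mats <- lapply(seq_len(nrow(seqlets)), function(i) {
    x <- onehot(seqlets$seq[i])
    t(x * seqlets$scores[[i]])
  })
  seqs <- seqlets$seq
  unassigned <- rep(TRUE, nrow(seqlets))
  motifs <- list()
  while (any(unassigned) && length(motifs) < max_motifs) {
    seed_i <- which(unassigned)[which.max(abs(seqlets$score_sum[unassigned]))]
    # initialize the cluster CWM from the seed, centered in a width-wide frame
    frame <- matrix(0, 4L, width, dimnames = list(DNA_BASES, NULL))
    fcount <- matrix(0, 4L, width)
    place <- function(frame, fcount, smat, soh, off, rc) {
      if (rc) { smat <- rc_matrix(smat); soh <- rc_matrix(soh) }
      Ws <- ncol(smat)
      c1 <- max(1L, 1L + off); c2 <- min(width, Ws + off)
      s1 <- c1 - off; s2 <- c2 - off
      frame[, c1:c2] <- frame[, c1:c2] + smat[, s1:s2, drop = FALSE]
      fcount[, c1:c2] <- fcount[, c1:c2] + soh[, s1:s2, drop = FALSE]
      list(frame = frame, fcount = fcount)
    }
    seed_off <- (width - ncol(mats[[seed_i]])) %/% 2L
    soh <- t(onehot(seqs[seed_i]))
    pl <- place(frame, fcount, mats[[seed_i]], soh, seed_off, FALSE)
    frame <- pl$frame; fcount <- pl$fcount
    members <- seed_i
    unassigned[seed_i] <- FALSE
    cwm <- frame
    for (pass in 1:2) {
      for (i in which(unassigned)) {
        al <- best_alignment(cwm, mats[[i]])
        if (al$sim >= sim_threshold) {
          pl <- place(frame, fcount, mats[[i]], t(onehot(seqs[i])), al$offset, al$rc)
          frame <- pl$frame; fcount <- pl$fcount
          members <- c(members, i)
          unassigned[i] <- FALSE
          cwm <- frame / length(members)
        }
      }
    }
    support <- length(members)
    cwm <- frame / support
    # trim flanking columns with little contribution
    mass <- colSums(abs(cwm))
    keep <- which(mass >= 0.05 * max(mass))
    if (length(keep) >= 2) {
      cols <- min(keep):max(keep)
      cwm <- cwm[, cols, drop = FALSE]
      fcount <- fcount[, cols, drop = FALSE]
    }
    if (ncol(cwm) < 5L || support < min_support) next
    pwm <- sweep(fcount + 0.1, 2L, colSums(fcount) + 0.4, "/")
    consensus <- paste(DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
    motifs[[length(motifs) + 1L]] <- new_motif(
      name = paste0("motif_", length(motifs) + 1L),
      pwm = pwm, cwm = cwm, consensus = consensus, support = support,
      total_contribution = sum(abs(frame))
    )
  }
  ord <- order(vapply(motifs, `[[`, numeric(1), "total_contribution"),
               decreasing = TRUE)
  motifs[ord]
}

#' Construct a motif object
#'
#' @param name motif name.
#' @param pwm 4 x W column-stochastic frequency matrix (rows A,C,G,T).
#' @param cwm 4 x W signed contribution matrix (may be NULL).
#' @param consensus consensus string (default: argmax of pwm columns).
#' @param support number of supporting seqlets.
#' @param total_contribution summed |contribution| over supporting seqlets.
#' @return an object of class `motif`.
#' @export
new_motif <- function(name, pwm, cwm = NULL, consensus = NULL, support = 0L,
                      total_contribution = NA_real_) {
  stopifnot(nrow(pwm) == 4L)
  if (max(abs(colSums(pwm) - 1)) > 1e-6) pwm <- sweep(pwm, 2L, colSums(pwm), "/")
  rownames(pwm) <- DNA_BASES
  if (!is.null(cwm)) rownames(cwm) <- DNA_BASES
  if (is.null(consensus))
    consensus <- paste(DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
  structure(list(name = name, pwm = pwm, cwm = cwm, consensus = consensus,
                 support = as.integer(support),
                 total_contribution = total_contribution,
                 width = ncol(pwm)),
            class = "motif")
}

#' Motif object from a consensus string (near-one-hot PWM)
#'
#' @param name motif name.
#' @param consensus ACGT consensus.
#' @param conc concentration of the consensus base (frequency).
#' @export
motif_from_consensus <- function(name, consensus, conc = 0.97) {
  M <- iupac_matrix(consensus)
  pwm <- apply(M, 2L, function(col) {
    p <- rep((1 - conc) / (4 - sum(col)), 4L)
    p[col == 1] <- conc / sum(col)
    p
  })
  rownames(pwm) <- DNA_BASES
  cwm <- sweep(M, 2L, 0.25 * colSums(M), "-")  # consensus-minus-background shape
  new_motif(name, pwm, cwm = cwm, consensus = consensus)
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif> ", x$name, " width ", x$width, " consensus ", x$consensus,
      " support ", x$support, "\n", sep = "")
  invisible(x)
}
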