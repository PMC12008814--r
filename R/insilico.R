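# In-silico experiments: motif injection into randomized backgrounds, the
# binding-enhancement statistic, distance sweeps, double-motif cooperativity,
# spacing perturbations and minimal-mutation / motif-moving enhancer design.

place_at <- function(seq, start0, what) write_sub(seq, start0 + 1L, what)

#' Four-case motif injection into randomized backgrounds
#'
#' For each seeded background the four cases are evaluated on otherwise
#' identical sequences: neither motif (h0), motif A only (hA), motif B only
#' (hB), both at the requested edge-gap distance (hAB). Each h is the mean
#' over backgrounds of the predicted read counts summed in a `window` bp
#' window centered on motif A's (intended) position. Backgrounds are shared
#' across the four cases.
#'
#' @param predictor a binding predictor.
#' @param motifA injected sequence for motif A (string).
#' @param motifB injected sequence for motif B, or NULL.
#' @param task task whose binding is measured.
#' @param distance edge gap in bp between A and B.
#' @param n_backgrounds number of randomized backgrounds.
#' @param window measurement window (bp) centered on motif A.
#' @param seed RNG seed.
#' @param orientationB "+" or "-" orientation for motif B.
#' @param side side of A on which B is placed ("right" or "left").
#' @param background_motif optional sequence planted at a seeded position
#'   within `background_motif_range` bp of the center in every background.
#' @param background_motif_range bp; see above.
#' @param gc background GC fraction.
#' @return an `injection_result`: h0, hA, hB, hAB, enhancement (NA when
#'   undefined), n_backgrounds, distance, plus per-background values.
#' @export
inject_predict <- function(predictor, motifA, motifB = NULL, task,
                           distance = 20L, n_backgrounds = 64L, window = 50L,
                           seed = 1L, orientationB = "+", side = "right",
                           background_motif = NULL,
                           background_motif_range = 150L, gc = 0.42) {
  if (n_backgrounds < 1) stop("n_backgrounds must be >= 1")
  L <- predictor_window(predictor)
  if (is.na(L) || is.null(L)) L <- 1000L
  wA <- nchar(motifA)
  startA <- (L - wA) %/% 2L
  spans <- list(c(startA, startA + wA))
  startB <- NULL
  if (!is.null(motifB)) {
    wB <- nchar(motifB)
    if (distance < 0) stop("distance must be >= 0")
    startB <- if (side == "right") startA + wA + distance else
      startA - distance - wB
    if (startB < 0 || startB + wB > L)
      stop("motif B does not fit in the window at distance ", distance)
    if (startB < startA + wA && startB + wB > startA)
      stop("motifs overlap at distance ", distance)
    spans[[2]] <- c(startB, startB + wB)
    bseq <- if (orientationB == "-") revcomp(motifB) else motifB
  }
  midA <- startA + wA %/% 2L
  wlo <- midA - window %/% 2L; whi <- wlo + window - 1L    # 0-based inclusive
  stopifnot(wlo >= 0, whi < L)
  wsum <- function(seq) {
    pred <- predict_binding(predictor, seq)[[task]]
    sum(pred$plus[(wlo + 1L):(whi + 1L)]) + sum(pred$minus[(wlo + 1L):(whi + 1L)])
  }
  vals <- with_seed(seed, {
    v <- matrix(NA_real_, n_backgrounds, 4L,
                dimnames = list(NULL, c("h0", "hA", "hB", "hAB")))
    for (b in seq_len(n_backgrounds)) {
      bg <- random_dna(L, gc)
      if (!is.null(background_motif)) {
        wM <- nchar(background_motif)
        repeat {
          off <- sample(-background_motif_range:background_motif_range, 1L)
          sM <- L %/% 2L + off
          if (sM < 0 || sM + wM > L) next
          clash <- any(vapply(spans, function(sp)
            sM < sp[2] && sM + wM > sp[1], logical(1)))
          if (!clash) break
        }
        bg <- place_at(bg, sM, background_motif)
      }
      s0 <- bg
      sA <- place_at(bg, startA, motifA)
      v[b, "h0"] <- wsum(s0)
      v[b, "hA"] <- wsum(sA)
      if (is.null(motifB)) {
        v[b, "hB"] <- v[b, "h0"]; v[b, "hAB"] <- v[b, "hA"]
      } else {
        sB <- place_at(bg, startB, bseq)
        sAB <- place_at(sA, startB, bseq)
        v[b, "hB"] <- wsum(sB)
        v[b, "hAB"] <- wsum(sAB)
      }
    }
    v
  })
  h <- colMeans(vals)
  res <- list(motifA = motifA, motifB = motifB, distance = distance,
              h0 = h[["h0"]], hA = h[["hA"]], hB = h[["hB"]], hAB = h[["hAB"]],
              n_backgrounds = n_backgrounds, window = window,
              per_background = vals,
              enhancement = if (h[["hA"]] > 0)
                enhancement(h[["h0"]], h[["hA"]], h[["hB"]], h[["hAB"]])
              else NA_real_)
  class(res) <- "injection_result"
  res
}

#' The in-silico binding enhancement statistic
#'
#' log2((hAB - (hB - h0)) / hA): the fold-change in predicted binding at
#' motif A attributable to the presence of motif B. Exactly 0 under
#' additivity (hAB = hA + hB - h0). Returns NA (the undefined flag, never
#' clamped) when the numerator is non-positive.
#'
#' @param h0,hA,hB,hAB mean windowed predicted counts of the four injection
#'   cases.
#' @return log2 ratio, or NA when undefined.
#' @export
enhancement <- function(h0, hA, hB, hAB) {
  if (hA <= 0) stop("hA must be > 0")
  num <- hAB - (hB - h0)
  if (num <= 0) return(NA_real_)
  log2(num / hA)
}

#' Enhancement versus distance curve
#'
#' Runs [inject_predict()] at each distance; by default both orientations of
#' motif B are evaluated on the same backgrounds and their h-values averaged.
#'
#' @param predictor a binding predictor.
#' @param motifA,motifB injected sequences.
#' @param task measured task.
#' @param distances edge gaps (bp).
#' @param n_backgrounds backgrounds per distance and orientation.
#' @param seed RNG seed (shared across distances).
#' @param orientations orientations of B to average over.
#' @param ... passed to [inject_predict()].
#' @return data.frame: distance, h0, hA, hB, hAB, enhancement.
#' @export
distance_sweep <- function(predictor, motifA, motifB, task, distances,
                           n_backgrounds = 64L, seed = 1L,
                           orientations = c("+", "-"), ...) {
  rows <- lapply(distances, function(d) {
    hs <- lapply(orientations, function(o)
      inject_predict(predictor, motifA, motifB, task = task, distance = d,
                     n_backgrounds = n_backgrounds, seed = seed,
                     orientationB = o, ...))
    h0 <- mean(vapply(hs, `[[`, numeric(1), "h0"))
    hA <- mean(vapply(hs, `[[`, numeric(1), "hA"))
    hB <- mean(vapply(hs, `[[`, numeric(1), "hB"))
    hAB <- mean(vapply(hs, `[[`, numeric(1), "hAB"))
    data.frame(distance = d, h0 = h0, hA = hA, hB = hB, hAB = hAB,
               enhancement = if (hA > 0) enhancement(h0, hA, hB, hAB) else NA)
  })
  do.call(rbind, rows)
}

#' Fit an exponential decay to an enhancement curve
#'
#' Linearizes 2^enhancement - 1 ~ c * exp(-d/tau) by least squares on the log
#' scale, over distances with positive linearized values.
#'
#' @param curve output of [distance_sweep()].
#' @return list(tau, c0, n_used).
#' @export
fit_enhancement_decay <- function(curve) {
  lin <- 2^curve$enhancement - 1
  keep <- is.finite(lin) & lin > 0
  if (sum(keep) < 3) stop("not enough positive enhancement values to fit decay")
  fit <- stats::lm(log(lin[keep]) ~ curve$distance[keep])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) return(list(tau = Inf, c0 = exp(unname(stats::coef(fit)[1])),
                              n_used = sum(keep)))
  list(tau = -1 / slope, c0 = exp(unname(stats::coef(fit)[1])),
       n_used = sum(keep))
}

#' Whole-versus-summed-halves cooperativity of a double motif
#'
#' Injects the whole sequence, and each half separately, into the same seeded
#' backgrounds; the additive baseline is pred(left) + pred(right) - h0
#' (background corrected once, so pure additivity gives fold exactly 1) and
#' fold = pred(whole) / additive.
#'
#' @param predictor a binding predictor.
#' @param double_sequence the whole double-motif sequence.
#' @param split 1-based index: left half is `substr(1, split)`.
#' @param task measured task.
#' @param n_backgrounds,window,seed,gc as in [inject_predict()].
#' @return a `cooperativity_result`: pred_whole, pred_additive, fold, halves.
#' @export
double_cooperativity <- function(predictor, double_sequence, split, task,
                                 n_backgrounds = 64L, window = 50L, seed = 1L,
                                 gc = 0.42) {
  wd <- nchar(double_sequence)
  if (split < 1 || split >= wd) stop("split must be inside the sequence")
  left <- substr(double_sequence, 1, split)
  right <- substr(double_sequence, split + 1, wd)
  L <- predictor_window(predictor)
  if (is.na(L) || is.null(L)) L <- 1000L
  startW <- (L - wd) %/% 2L
  midW <- startW + wd %/% 2L
  wlo <- midW - window %/% 2L; whi <- wlo + window - 1L
  wsum <- function(seq) {
    pred <- predict_binding(predictor, seq)[[task]]
    sum(pred$plus[(wlo + 1L):(whi + 1L)]) + sum(pred$minus[(wlo + 1L):(whi + 1L)])
  }
  vals <- with_seed(seed, {
    v <- matrix(NA_real_, n_backgrounds, 4L,
                dimnames = list(NULL, c("h0", "whole", "left", "right")))
    for (b in seq_len(n_backgrounds)) {
      bg <- random_dna(L, gc)
      v[b, "h0"] <- wsum(bg)
      v[b, "whole"] <- wsum(place_at(bg, startW, double_sequence))
      v[b, "left"] <- wsum(place_at(bg, startW, left))
      v[b, "right"] <- wsum(place_at(bg, startW + split, right))
    }
    v
  })
  h <- colMeans(vals)
  additive <- h[["left"]] + h[["right"]] - h[["h0"]]
  res <- list(double_sequence = double_sequence, half_left = left,
              half_right = right, split = split,
              h0 = h[["h0"]], pred_whole = h[["whole"]],
              pred_left = h[["left"]], pred_right = h[["right"]],
              pred_additive = additive,
              fold = if (additive > 0) h[["whole"]] / additive else NA_real_,
              n_backgrounds = n_backgrounds, per_background = vals)
  class(res) <- "cooperativity_result"
  res
}

#' Spacing perturbations of a double motif
#'
#' Applies insertions/deletions at the gap between the two half-sites and
#' re-runs [double_cooperativity()] per variant. Edits are given as signed
#' integers (negative = delete that many bp immediately left of the split
#' boundary, i.e. from the gap; positive = insert that many bp there);
#' 0 reproduces the unedited sequence. Insertions use the bases of
#' `insert_bases` (recycled); an edit larger than `max_edit` is rejected as
#' destroying a half-site core.
#'
#' @param predictor a binding predictor.
#' @param double_sequence the whole double-motif sequence.
#' @param split 1-based split index (end of the left half).
#' @param edits integer vector of signed edit sizes.
#' @param task measured task.
#' @param max_edit maximum |edit| allowed (gap width guard).
#' @param insert_bases bases used for insertions.
#' @param profile_flank bp of predicted profile kept around the motif.
#' @param ... passed to [double_cooperativity()].
#' @return data.frame with edit, fold, pred_whole, pred_additive; profiles in
#'   attribute "profiles" (one averaged predicted profile per edit).
#' @export
spacing_perturbation <- function(predictor, double_sequence, split, edits,
                                 task, max_edit = 2L, insert_bases = "GT",
                                 profile_flank = 75L, ...) {
  rows <- list(); profiles <- list()
  for (k in edits) {
    if (abs(k) > max_edit)
      stop("edit of ", k, " bp would destroy a half-site core (max ", max_edit, ")")
    if (k < 0) {
      if (split + k < 1) stop("deletion exceeds left half")
      edited <- paste0(substr(double_sequence, 1, split + k),
                       substr(double_sequence, split + 1, nchar(double_sequence)))
      newsplit <- split + k
    } else if (k > 0) {
      ins <- paste(rep(seq_chars(insert_bases), length.out = k), collapse = "")
      edited <- paste0(substr(double_sequence, 1, split), ins,
                       substr(double_sequence, split + 1, nchar(double_sequence)))
      newsplit <- split + k
    } else { edited <- double_sequence; newsplit <- split }
    cc <- double_cooperativity(predictor, edited, newsplit, task, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      edit = k, sequence = edited, fold = cc$fold,
      pred_whole = cc$pred_whole, pred_additive = cc$pred_additive,
      stringsAsFactors = FALSE)
    # predicted profile around the motif on one representative background
    L <- predictor_window(predictor); if (is.na(L) || is.null(L)) L <- 1000L
    startW <- (L - nchar(edited)) %/% 2L
    midW <- startW + nchar(edited) %/% 2L
    bgseq <- with_seed(child_seed(1L, "profile"), random_dna(L, 0.42))
    pred <- predict_binding(predictor, place_at(bgseq, startW, edited))[[task]]
    lo <- max(1L, midW - profile_flank); hi <- min(L, midW + profile_flank)
    profiles[[as.character(k)]] <- list(plus = pred$plus[lo:hi],
                                        minus = pred$minus[lo:hi])
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  out
}

#' Minimal-mutation design: knock out a motif with k base edits
#'
#' Identifies the `k` positions of largest positive contribution within the
#' instance span and replaces each observed base by the base with minimal
#' hypothetical contribution at that position. Ties are broken toward the
#' leftmost position (flagged in the report).
#'
#' @param cmap a `contribution_map` over the sequence.
#' @param instance list/row with `start`, `end` (0-based half-open, within the
#'   map).
#' @param k number of bases to mutate.
#' @return list(seq = edited sequence, report = per-position data.frame,
#'   tie_flag).
#' @export
design_minimal_mutation <- function(cmap, instance, k = 2L) {
  s <- instance$start; e <- instance$end
  L <- nchar(cmap$seq)
  if (s < 0 || e > L || e <= s) stop("instance span outside map")
  w <- e - s
  if (k > w) stop("k exceeds motif width")
  seq <- cmap$seq
  if (k == 0) return(list(seq = seq, report = data.frame(), tie_flag = FALSE))
  span_scores <- cmap$score[(s + 1L):e]
  tie_flag <- length(unique(span_scores)) == 1L
  ord <- order(-span_scores, seq_len(w))
  pick <- ord[seq_len(k)]
  rep_rows <- list()
  for (p in pick) {
    pos <- s + p                       # 1-based position in seq
    from <- substr(seq, pos, pos)
    hyp <- cmap$hyp[pos, ]
    to <- DNA_BASES[order(hyp, seq_along(hyp))][1]
    if (to == from) to <- DNA_BASES[order(hyp, seq_along(hyp))][2]
    seq <- write_sub(seq, pos, to)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      position = pos - 1L, from = from, to = to,
      contribution = span_scores[p], stringsAsFactors = FALSE)
  }
  list(seq = seq, report = do.call(rbind, rep_rows), tie_flag = tie_flag)
}

#' Move a motif instance to a new distance from an anchor
#'
#' Mutates the original instance (via [design_minimal_mutation()], k bases)
#' and writes the instance's original bases at the position giving the
#' requested edge gap from the anchor, on the instance's original side.
#' Total length is preserved (substitution, not insertion).
#'
#' @param sequence the sequence being edited.
#' @param instance list/row with start/end of the motif to move (0-based).
#' @param anchor list/row with start/end of the anchor motif.
#' @param new_gap requested edge gap (bp) between anchor and the moved motif.
#' @param cmap `contribution_map` over `sequence` (for the mutation step).
#' @param k bases mutated in the original instance.
#' @return the edited sequence (same length).
#' @export
move_motif <- function(sequence, instance, anchor, new_gap, cmap, k = 2L) {
  w <- instance$end - instance$start
  motif_seq <- substr(sequence, instance$start + 1L, instance$end)
  right_side <- instance$start >= anchor$end
  new_start <- if (right_side) anchor$end + new_gap else
    anchor$start - new_gap - w
  new_end <- new_start + w
  if (new_start < 0 || new_end > nchar(sequence))
    stop("requested position out of bounds")
  if (new_start < anchor$end && new_end > anchor$start)
    stop("requested position overlaps the anchor")
  same_site <- new_start == instance$start
  if (!same_site && new_start < instance$end && new_end > instance$start)
    stop("requested position overlaps the original instance")
  mut <- design_minimal_mutation(cmap, instance, k = k)
  out <- mut$seq
  out <- write_sub(out, new_start + 1L, motif_seq)
  stopifnot(nchar(out) == nchar(sequence))
  out
}
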