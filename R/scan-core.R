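# Core grammar machinery: motif matching, double-motif resolution, soft
# cooperativity boosts and expected stranded profiles. Shared by the simulator
# (applied to planted truth) and by the analytic oracle predictor (applied to
# scanned sequence matches), which keeps the two numerically consistent.

#' Scan one sequence for near-consensus matches of every grammar motif
#'
#' Matches carry up to `grammar$max_mismatch` mismatches; base occupancy is
#' `A * exp(-beta * mismatches)`. Coordinates are 0-based half-open; a `-`
#' strand instance means the motif's reverse complement appears in `seq`.
#'
#' @noRd
scan_motif_matches <- function(grammar, seq) {
  ints <- seq_ints(seq)
  L <- length(ints)
  out <- list()
  for (m in grammar$motifs) {
    w <- m$width
    if (L < w) next
    npos <- L - w + 1L
    for (strand in c("+", "-")) {
      cons <- if (strand == "+") m$consensus else revcomp(m$consensus)
      ci <- seq_ints(cons)
      mism <- rep.int(w, npos)
      for (j in seq_len(w))
        mism <- mism - (ints[j:(npos + j - 1L)] == ci[j])
      hit <- which(mism <= grammar$max_mismatch)
      if (!length(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = m$name, start = hit - 1L, end = hit - 1L + w,
        strand = strand, mismatches = mism[hit],
        occ_base = m$amplitude * exp(-grammar$beta * mism[hit]),
        task = m$task, is_double = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      occ_base = numeric(0), task = character(0),
                      is_double = logical(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand, df$motif), , drop = FALSE]
}

#' Collapse adjacent half-site matches into strictly spaced double motifs
#'
#' Two same-strand matches of a strict rule's half motif at edge gap exactly
#' `rule$gap` form a double instance with occupancy kappa * (occ_L + occ_R);
#' the constituent half matches are suppressed. Chains are consumed greedily
#' left to right.
#'
#' @noRd
resolve_doubles <- function(grammar, inst) {
  inst$h1_occ <- rep(NA_real_, nrow(inst))
  inst$h2_occ <- rep(NA_real_, nrow(inst))
  inst$h1_start <- rep(NA_integer_, nrow(inst))
  inst$h2_start <- rep(NA_integer_, nrow(inst))
  if (!length(grammar$strict_rules) || !nrow(inst)) return(inst)
  drop <- rep(FALSE, nrow(inst))
  doubles <- list()
  for (rule in grammar$strict_rules) {
    for (strand in c("+", "-")) {
      idx <- which(inst$motif == rule$half & inst$strand == strand & !drop)
      if (length(idx) < 2) next
      idx <- idx[order(inst$start[idx])]
      i <- 1L
      while (i < length(idx)) {
        a <- idx[i]; b <- idx[i + 1L]
        if (inst$start[b] - inst$end[a] == rule$gap) {
          doubles[[length(doubles) + 1L]] <- data.frame(
            motif = rule$name, start = inst$start[a], end = inst$end[b],
            strand = strand, mismatches = inst$mismatches[a] + inst$mismatches[b],
            occ_base = rule$kappa * (inst$occ_base[a] + inst$occ_base[b]),
            task = rule$task, is_double = TRUE,
            h1_occ = inst$occ_base[a], h2_occ = inst$occ_base[b],
            h1_start = inst$start[a], h2_start = inst$start[b],
            stringsAsFactors = FALSE
          )
          drop[c(a, b)] <- TRUE
          i <- i + 2L
        } else i <- i + 1L
      }
    }
  }
  res <- rbind(inst[!drop, , drop = FALSE], do.call(rbind, doubles))
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Edge gap (bp) between two 0-based half-open intervals; 0 if overlapping
#' @noRd
edge_gap <- function(s1, e1, s2, e2) pmax(0, pmax(s2 - e1, s1 - e2))

#' Apply soft distance-dependent cooperativity boosts
#'
#' For each instance whose task is named by a soft rule, the occupancy is
#' multiplied by prod(1 + c * exp(-d/tau) * rel_partner) over partner-motif
#' instances within `range` bp (edge gap d), where rel = occ/A is the partner's
#' relative affinity. Directional: only the rule's task is boosted. Returns the
#' instance table with `boost` and final `occupancy` columns, plus the partner
#' terms needed for analytic gradients.
#'
#' @noRd
apply_soft_boosts <- function(grammar, inst) {
  n <- nrow(inst)
  boost <- rep(1, n)
  partner_terms <- vector("list", n)
  if (n) {
    for (rule in grammar$soft_rules) {
      targets <- which(inst$task == rule$task & inst$motif != rule$partner)
      partners <- which(inst$motif == rule$partner)
      if (!length(targets) || !length(partners)) next
      Ap <- grammar$motifs[[rule$partner]]$amplitude
      for (i in targets) {
        d <- edge_gap(inst$start[i], inst$end[i], inst$start[partners], inst$end[partners])
        keep <- which(d <= rule$range)
        if (!length(keep)) next
        g <- rule$c * exp(-d[keep] / rule$tau) * inst$occ_base[partners[keep]] / Ap
        boost[i] <- boost[i] * prod(1 + g)
        partner_terms[[i]] <- rbind(partner_terms[[i]],
                                    cbind(j = partners[keep], g = g))
      }
    }
  }
  inst$boost <- boost
  inst$occupancy <- inst$occ_base * boost
  attr(inst, "partner_terms") <- partner_terms
  inst
}

#' Full grammar analysis of a sequence: matches, doubles, boosts
#' @noRd
grammar_analyze <- function(grammar, seq) {
  inst <- scan_motif_matches(grammar, seq)
  inst <- resolve_doubles(grammar, inst)
  apply_soft_boosts(grammar, inst)
}

#' Add a footprint kernel centered at 0-based position `center` into `vec`
#' @noRd
add_kernel <- function(vec, kernel, center) {
  half <- (length(kernel) - 1L) / 2L
  pos <- (center - half):(center + half)          # 0-based
  keep <- pos >= 0L & pos < length(vec)
  if (any(keep)) vec[pos[keep] + 1L] <- vec[pos[keep] + 1L] + kernel[keep]
  vec
}

#' Expected stranded profile of one task over a sequence of length L
#'
#' Per base: depth + sum over the task's instances of occupancy * kernel: the
#' plus-strand kernel peaks `offset` bp left of the motif span and the
#' minus-strand kernel `offset` bp right of it, for either instance
#' orientation, emulating exonuclease stop-base pileups around the protected
#' footprint (this makes simulated profiles exactly mirror-symmetric under
#' reverse complementation).
#'
#' @noRd
expected_task_profile <- function(grammar, L, inst, task, depth = grammar$depth) {
  plus <- rep(depth, L); minus <- rep(depth, L)
  keep <- inst$motif %in% task_motifs(grammar, task)
  k <- grammar$kernel
  # exonuclease stop-base pileups are anchored to genome strands and the
  # protected footprint, independent of motif orientation: plus-strand reads
  # stop at the left barrier edge, minus-strand reads at the right edge
  for (i in which(keep)) {
    occ <- inst$occupancy[i]
    plus  <- add_kernel(plus,  occ * k$vec, inst$start[i] - k$offset)
    minus <- add_kernel(minus, occ * k$vec, inst$end[i] - 1L + k$offset)
  }
  list(plus = plus, minus = minus)
}
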