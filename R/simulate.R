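# Synthetic genome and ChIP-nexus-like profile simulation.

#' Simulate a synthetic genome with planted motif instances
#'
#' Background is iid DNA at the grammar's GC fraction. For every grammar motif
#' (including derived double motifs), instances are planted at random
#' non-overlapping positions and uniformly random strands at the requested
#' density. With probability `grammar$mismatch_prob` a planted instance carries
#' 1-2 mismatches, so that affinity recovery is testable. The returned truth
#' table records final occupancies (including double-motif kappa and soft
#' boosts between planted instances).
#'
#' @param grammar a `tf_grammar`.
#' @param n_contigs number of contigs.
#' @param contig_len length of each contig (bp, >= 1000).
#' @param density planted instances per kb per motif; either a scalar
#'   (applied to every motif) or a named vector over plantable motif names
#'   (unnamed motifs get density 0).
#' @param gc background GC fraction (default: grammar's).
#' @param seed RNG seed.
#' @return an object of class `synthetic_genome`: list with `contigs` (named
#'   character vector) and `truth` (data.frame of planted instances with
#'   0-based half-open coordinates).
#' @export
simulate_genome <- function(grammar, n_contigs = 4L, contig_len = 500000L,
                            density = 0.05, gc = grammar$gc, seed = 1L) {
  stopifnot(inherits(grammar, "tf_grammar"))
  if (contig_len < 1000) stop("contig_len must be >= 1000")
  if (any(density < 0)) stop("density must be >= 0")
  plant_names <- c(names(grammar$motifs), names(grammar$strict_rules))
  dens <- if (length(density) == 1L && is.null(names(density)))
    stats::setNames(rep(density, length(plant_names)), plant_names)
  else {
    bad <- setdiff(names(density), plant_names)
    if (length(bad)) stop("density names not in grammar: ", paste(bad, collapse = ","))
    d <- stats::setNames(rep(0, length(plant_names)), plant_names)
    d[names(density)] <- density
    d
  }
  plant_seqs <- c(
    lapply(grammar$motifs, `[[`, "consensus"),
    lapply(grammar$strict_rules, `[[`, "whole")
  )
  with_seed(seed, {
    contigs <- stats::setNames(
      vapply(seq_len(n_contigs), function(i) random_dna(contig_len, gc), character(1)),
      paste0("chr", seq_len(n_contigs))
    )
    truth <- list()
    for (cn in names(contigs)) {
      occupied <- matrix(numeric(0), ncol = 2)  # planted spans, 0-based half-open
      for (mi in seq_along(plant_names)) {
        mname <- plant_names[mi]
        w <- nchar(plant_seqs[[mi]])
        n_target <- stats::rpois(1, contig_len * dens[[mname]] / 1000)
        attempts <- 0L; placed <- 0L
        while (placed < n_target && attempts < 50L * max(1L, n_target)) {
          attempts <- attempts + 1L
          s <- sample.int(contig_len - w - 1L, 1L) - 1L   # 0-based start
          e <- s + w
          # keep planted instances from interacting through pure adjacency:
          # require clear space (no overlap with existing planted spans)
          if (nrow(occupied) &&
              any(occupied[, 1] < e & occupied[, 2] > s)) next
          sq <- plant_seqs[[mi]]
          mm <- 0L
          if (stats::runif(1) < grammar$mismatch_prob) {
            mm <- sample(c(1L, 2L), 1L, prob = c(0.75, 0.25))
            pos <- sample.int(w, mm)
            ch <- seq_chars(sq)
            for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
            sq <- paste(ch, collapse = "")
          }
          strand <- sample(c("+", "-"), 1L)
          written <- if (strand == "+") sq else revcomp(sq)
          contigs[[cn]] <- write_sub(contigs[[cn]], s + 1L, written)
          occupied <- rbind(occupied, c(s, e))
          truth[[length(truth) + 1L]] <- data.frame(
            contig = cn, start = s, end = e, strand = strand,
            motif = mname, mismatches = mm, stringsAsFactors = FALSE
          )
          placed <- placed + 1L
        }
        if (placed < n_target)
          stop("infeasible planting density: placed ", placed, "/", n_target,
               " instances of ", mname, " on ", cn)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), motif = character(0),
                 mismatches = integer(0))
    truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    genome <- structure(list(contigs = contigs, truth = truth, grammar_gc = gc),
                        class = "synthetic_genome")
    genome$truth <- annotate_truth_occupancy(grammar, genome)
    genome
  })
}

#' Recompute occupancy (with doubles and boosts) for planted truth instances
#' @noRd
annotate_truth_occupancy <- function(grammar, genome) {
  truth <- genome$truth
  if (!nrow(truth)) {
    truth$occ_base <- numeric(0); truth$boost <- numeric(0)
    truth$occupancy <- numeric(0); truth$task <- character(0)
    return(truth)
  }
  out <- list()
  for (cn in unique(truth$contig)) {
    tt <- truth[truth$contig == cn, , drop = FALSE]
    seqs <- vapply(seq_len(nrow(tt)), function(i) {
      s <- substr(genome$contigs[[cn]], tt$start[i] + 1L, tt$end[i])
      if (tt$strand[i] == "-") revcomp(s) else s
    }, character(1))
    tt$occ_base <- vapply(seq_len(nrow(tt)), function(i) {
      planted_occupancy(grammar, tt$motif[i], seqs[i])
    }, numeric(1))
    tt$task <- vapply(tt$motif, function(m) {
      if (m %in% names(grammar$strict_rules)) grammar$strict_rules[[m]]$task
      else grammar$motifs[[m]]$task
    }, character(1))
    tt$is_double <- tt$motif %in% names(grammar$strict_rules)
    tt <- apply_soft_boosts(grammar, tt)
    attr(tt, "partner_terms") <- NULL
    out[[cn]] <- tt
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Base occupancy of a motif-oriented instance sequence under the grammar
#' @noRd
planted_occupancy <- function(grammar, motif_name, seq) {
  if (motif_name %in% names(grammar$strict_rules)) {
    r <- grammar$strict_rules[[motif_name]]
    hw <- r$half_width
    left <- substr(seq, 1, hw)
    right <- substr(seq, hw + r$gap + 1L, hw + r$gap + hw)
    cons <- grammar$motifs[[r$half]]$consensus
    mmL <- sum(seq_chars(left) != seq_chars(cons))
    mmR <- sum(seq_chars(right) != seq_chars(cons))
    A <- grammar$motifs[[r$half]]$amplitude
    r$kappa * (A * exp(-grammar$beta * mmL) + A * exp(-grammar$beta * mmR))
  } else {
    m <- grammar$motifs[[motif_name]]
    mm <- sum(seq_chars(seq) != seq_chars(m$consensus))
    m$amplitude * exp(-grammar$beta * mm)
  }
}

#' Analytic occupancy of a (truth) instance under the grammar
#'
#' Occupancy is A * exp(-beta * mismatches) scaled by the strict-rule
#' cooperativity (kappa * (occ_left + occ_right) for whole double motifs) and
#' by soft-syntax boosts from partner instances within range. Indirect tasks
#' read the driver task's occupancy unchanged.
#'
#' @param grammar a `tf_grammar`.
#' @param genome a `synthetic_genome`.
#' @param instance one row of the genome truth table (or a matching list with
#'   contig, start, end, strand, motif).
#' @return expected reads (numeric >= 0).
#' @export
oracle_occupancy <- function(grammar, genome, instance) {
  tr <- genome$truth
  hit <- which(tr$contig == instance$contig & tr$start == instance$start &
                 tr$end == instance$end & tr$motif == instance$motif)
  if (!length(hit)) {
    if (!instance$motif %in% c(names(grammar$motifs), names(grammar$strict_rules)))
      stop("instance motif '", instance$motif, "' not in grammar")
    stop("instance not found in genome truth")
  }
  tr$occupancy[hit[1]]
}

#' Simulate stranded base-resolution profiles for every task
#'
#' Per base and strand, counts ~ Poisson(depth + sum of truth occupancies
#' spread by the footprint kernel); with finite `grammar$dispersion` a
#' negative binomial with that size parameter is used instead.
#'
#' @param genome a `synthetic_genome`.
#' @param grammar the generating `tf_grammar`.
#' @param depth mean background reads per bp per strand.
#' @param seed RNG seed.
#' @return a `stranded_profile_set`: nested list `[[task]][[contig]]` of
#'   `list(plus, minus)` integer count vectors.
#' @export
simulate_profiles <- function(genome, grammar, depth = grammar$depth, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  draw <- function(mu) {
    if (is.finite(grammar$dispersion))
      stats::rnbinom(length(mu), size = grammar$dispersion, mu = mu)
    else stats::rpois(length(mu), mu)
  }
  with_seed(seed, {
    out <- list()
    for (task in grammar$tasks) {
      out[[task]] <- list()
      for (cn in names(genome$contigs)) {
        L <- nchar(genome$contigs[[cn]])
        inst <- genome$truth[genome$truth$contig == cn, , drop = FALSE]
        ex <- expected_task_profile(grammar, L, inst, task, depth = depth)
        out[[task]][[cn]] <- list(plus = draw(ex$plus), minus = draw(ex$minus))
      }
    }
    structure(out, class = "stranded_profile_set", depth = depth)
  })
}

#' Noise-free expected profiles for every task (same layout as simulated)
#' @export
expected_profiles <- function(genome, grammar, depth = grammar$depth) {
  out <- list()
  for (task in grammar$tasks) {
    out[[task]] <- list()
    for (cn in names(genome$contigs)) {
      L <- nchar(genome$contigs[[cn]])
      inst <- genome$truth[genome$truth$contig == cn, , drop = FALSE]
      out[[task]][[cn]] <- expected_task_profile(grammar, L, inst, task, depth = depth)
    }
  }
  structure(out, class = "stranded_profile_set", depth = depth)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> ", length(x$contigs), " contig(s), total ",
      sum(nchar(x$contigs)), " bp, ", nrow(x$truth), " planted instance(s)\n",
      sep = "")
  invisible(x)
}
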