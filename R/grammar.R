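#' Default grammar configuration
#'
#' The stated world of the synthetic benchmark: a trophoblast-like regulatory
#' grammar with a TEAD-like single motif (consensus ACATTCCTG), a TFAP2C-like
#' motif (CCCTCAGGC), a strictly spaced TEAD double motif built from two single
#' half-sites (cooperativity fold kappa), a soft distance-dependent boost of
#' TEAD binding by a nearby TFAP2C motif (factor 1 + c*exp(-d/tau) within
#' D_soft), and a YAP1-like task that indirectly tracks TEAD occupancy.
#'
#' Units: amplitudes are expected reads per consensus instance; tau and range
#' are bp; depth is expected background reads per bp per strand (ChIP-nexus
#' background is sparse: a handful of reads per kb).
#'
#' @return a nested list accepted by [make_grammar()].
#' @export
default_grammar_config <- function() {
  list(
    motifs = list(
      list(name = "tead_single", consensus = "ACATTCCTG", amplitude = 20, task = "TEAD4"),
      list(name = "tfap2c",      consensus = "CCCTCAGGC", amplitude = 15, task = "TFAP2C")
    ),
    beta = 2.5,
    max_mismatch = 2L,
    soft_rules = list(
      list(task = "TEAD4", partner = "tfap2c", c = 3, tau = 40, range = 150)
    ),
    strict_rules = list(
      list(name = "tead_double", half = "tead_single", gap = 0L, kappa = 4)
    ),
    indirect_map = c(YAP1 = "TEAD4"),
    kernel = list(width = 41L, sd = 6, offset = 5L),
    depth = 0.001,
    gc = 0.42,
    dispersion = Inf,
    mismatch_prob = 0.05
  )
}

#' Build and validate a ground-truth regulatory grammar
#'
#' A grammar holds the motif set (consensus, amplitude, task), the affinity
#' scaling `beta` (occupancy = A * exp(-beta * mismatches)), soft cooperativity
#' rules, strict double-motif rules, the indirect task map, the stranded
#' footprint kernel and background depth. It is the shared truth of the
#' simulator and of the analytic oracle predictor.
#'
#' @param config a configuration list; missing entries fall back to
#'   [default_grammar_config()] defaults.
#' @return an object of class `tf_grammar`.
#' @export
make_grammar <- function(config = list()) {
  cfg <- utils::modifyList(default_grammar_config(), config)
  # list-valued structural keys replace wholesale (modifyList merges
  # recursively, which would silently keep default motifs/rules)
  for (key in c("motifs", "soft_rules", "strict_rules", "indirect_map"))
    if (!is.null(config[[key]])) cfg[[key]] <- config[[key]]
  if (!length(cfg$motifs)) stop("grammar_validation: config names no motifs")

  motifs <- list()
  for (m in cfg$motifs) {
    if (is.null(m$name) || is.null(m$consensus) || is.null(m$amplitude))
      stop("grammar_validation: each motif needs name, consensus, amplitude")
    cons <- toupper(m$consensus)
    if (!grepl("^[ACGT]+$", cons))
      stop("grammar_validation: consensus of '", m$name,
           "' must be over {A,C,G,T} (got ", cons, ")")
    if (m$amplitude < 0) stop("grammar_validation: amplitude < 0 for ", m$name)
    m$consensus <- cons
    m$width <- nchar(cons)
    m$match <- iupac_matrix(cons)   # 4 x W consensus indicator
    motifs[[m$name]] <- m
  }
  if (is.null(cfg$beta) || cfg$beta < 0) stop("grammar_validation: beta must be >= 0")

  for (r in cfg$soft_rules) {
    if (r$c < 0) stop("grammar_validation: soft boost c < 0")
    if (r$tau <= 0) stop("grammar_validation: tau must be > 0")
    if (is.null(motifs[[r$partner]]))
      stop("grammar_validation: soft rule partner '", r$partner, "' not a motif")
  }
  for (r in cfg$strict_rules) {
    if (r$kappa < 1) stop("grammar_validation: kappa must be >= 1")
    if (r$gap < 0) stop("grammar_validation: strict rule gap must be >= 0")
    if (is.null(motifs[[r$half]]))
      stop("grammar_validation: strict rule half '", r$half, "' not a motif")
  }
  ker <- cfg$kernel
  if (ker$width < 3 || ker$width %% 2 == 0)
    stop("grammar_validation: kernel width must be odd and >= 3")
  if (ker$sd <= 0) stop("grammar_validation: kernel not normalizable (sd <= 0)")
  half <- (ker$width - 1) / 2
  k <- stats::dnorm(seq(-half, half), sd = ker$sd)
  k <- k / sum(k) / 2  # each strand's kernel carries half of the occupancy

  # derived whole-double consensus strings (half + gap spacer + half);
  # the default gap of 0 between 9-bp half-site matches corresponds to a 2-bp
  # spacing between the 7-bp cores (RMATTCCNNRMATTCCNN template)
  strict <- lapply(cfg$strict_rules, function(r) {
    hw <- motifs[[r$half]]$width
    spacer <- if (r$gap > 0)
      paste(rep(c("T", "G"), length.out = r$gap), collapse = "") else ""
    r$whole <- paste0(motifs[[r$half]]$consensus, spacer, motifs[[r$half]]$consensus)
    r$half_width <- hw
    r$task <- motifs[[r$half]]$task
    r
  })
  names(strict) <- vapply(strict, `[[`, character(1), "name")

  direct_tasks <- unique(vapply(motifs, `[[`, character(1), "task"))
  im <- cfg$indirect_map
  if (length(im)) {
    bad <- setdiff(unname(im), direct_tasks)
    if (length(bad)) stop("grammar_validation: indirect driver task(s) unknown: ",
                          paste(bad, collapse = ","))
  }
  tasks <- c(direct_tasks, names(im))

  structure(list(
    motifs = motifs, beta = cfg$beta, max_mismatch = as.integer(cfg$max_mismatch),
    soft_rules = cfg$soft_rules, strict_rules = strict,
    indirect_map = im, tasks = tasks, direct_tasks = direct_tasks,
    kernel = list(vec = k, offset = as.integer(ker$offset), width = as.integer(ker$width)),
    depth = cfg$depth, gc = cfg$gc, dispersion = cfg$dispersion,
    mismatch_prob = cfg$mismatch_prob,
    config = cfg
  ), class = "tf_grammar")
}

#' @export
print.tf_grammar <- function(x, ...) {
  cat("<tf_grammar> ", length(x$motifs), " motifs (",
      paste(names(x$motifs), collapse = ", "), "); ",
      length(x$strict_rules), " strict rule(s); ",
      length(x$soft_rules), " soft rule(s); tasks: ",
      paste(x$tasks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Map each task to the motif names whose occupancy it reads
#' @noRd
task_motifs <- function(grammar, task) {
  drv <- if (task %in% names(grammar$indirect_map)) grammar$indirect_map[[task]] else task
  direct <- names(grammar$motifs)[vapply(grammar$motifs, `[[`, character(1), "task") == drv]
  doubles <- names(grammar$strict_rules)[vapply(grammar$strict_rules, `[[`, character(1), "task") == drv]
  c(direct, doubles)
}

#' Driver (direct) task for a task name
#' @noRd
driver_task <- function(grammar, task) {
  if (task %in% names(grammar$indirect_map)) grammar$indirect_map[[task]] else task
}

#' Default planting densities of the synthetic benchmark genome
#'
#' Instances per kb per motif. The TFAP2C-like motif is planted at twice the
#' TEAD density, mirroring its greater peak abundance in the emulated system
#' and giving every task a comparable share of informative windows.
#'
#' @return named numeric vector.
#' @export
default_planting_density <- function() {
  c(tead_single = 0.05, tfap2c = 0.1, tead_double = 0.05)
}
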