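# Training datasets: fixed-width windows centered on truth instances (the
# synthetic stand-in for peaks) plus sampled background windows, one-hot
# sequences paired with per-task stranded count vectors, split by contig.

#' Build a windowed training set from a genome and simulated profiles
#'
#' Windows are centered on the midpoints of truth instances plus a fraction of
#' random background windows; each window carries the one-hot sequence and the
#' per-task stranded counts. Train/val/test are disjoint by contig. Windows
#' extending past a contig are dropped (with a message recording the count).
#'
#' @param genome a `synthetic_genome`.
#' @param profiles a `stranded_profile_set` over the same contigs.
#' @param window window width in bp.
#' @param split named character vector contig -> "train"/"val"/"test";
#'   must cover all contigs.
#' @param background_frac background windows as a fraction of instance windows.
#' @param seed RNG seed for background window placement.
#' @return a `profile_dataset`.
#' @export
make_training_set <- function(genome, profiles, window = 1000L,
                              split, background_frac = 0.1, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  cns <- names(genome$contigs)
  if (!all(cns %in% names(split)))
    stop("split must cover all contigs; missing: ",
         paste(setdiff(cns, names(split)), collapse = ","))
  if (!all(split %in% c("train", "val", "test")))
    stop("split values must be train/val/test")
  tasks <- names(profiles)
  half <- window %/% 2L

  centers <- data.frame(
    contig = genome$truth$contig,
    center = (genome$truth$start + genome$truth$end) %/% 2L,
    motif = genome$truth$motif, stringsAsFactors = FALSE
  )
  n_bg <- round(background_frac * nrow(centers))
  bg <- with_seed(seed, {
    if (n_bg > 0) {
      cn <- sample(cns, n_bg, replace = TRUE)
      data.frame(contig = cn,
                 center = vapply(cn, function(x)
                   sample.int(nchar(genome$contigs[[x]]), 1L) - 1L, integer(1)),
                 motif = "background", stringsAsFactors = FALSE)
    } else centers[0, ]
  })
  centers <- rbind(centers, bg)

  dropped <- 0L
  windows <- list(); meta <- list()
  for (i in seq_len(nrow(centers))) {
    cn <- centers$contig[i]
    L <- nchar(genome$contigs[[cn]])
    s <- centers$center[i] - half          # 0-based
    e <- s + window
    if (s < 0 || e > L) { dropped <- dropped + 1L; next }
    seq <- substr(genome$contigs[[cn]], s + 1L, e)
    Y <- list()
    for (t in tasks) {
      pr <- profiles[[t]][[cn]]
      Y[[t]] <- cbind(pr$plus[(s + 1L):e], pr$minus[(s + 1L):e])
    }
    windows[[length(windows) + 1L]] <- list(seq = seq, X = onehot(seq), Y = Y)
    meta[[length(meta) + 1L]] <- data.frame(
      contig = cn, start = s, end = e, motif = centers$motif[i],
      split = unname(split[cn]), stringsAsFactors = FALSE
    )
  }
  if (dropped > 0)
    message(dropped, " window(s) dropped (extend past contig bounds)")
  if (!length(windows)) warning("all windows dropped")
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               motif = character(0), split = character(0))
  structure(list(windows = windows, meta = meta, tasks = tasks,
                 window = as.integer(window), dropped = dropped),
            class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat("<profile_dataset> ", length(x$windows), " windows of ", x$window,
      " bp; tasks: ", paste(x$tasks, collapse = ", "), "; split: ",
      paste(names(table(x$meta$split)), table(x$meta$split),
            sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}
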