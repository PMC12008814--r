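# Genomic-context syntax analyses: contribution-vs-distance statistics, motif
# islands, IUPAC double-motif spacing scans and motif-variant analysis.

#' Contribution of partner motifs binned by distance to an anchor motif
#'
#' For every B instance, finds the nearest A instance (minimum edge gap, ties
#' to the left) and records B's total contribution against that gap. The
#' baseline is the contributions of B instances whose nearest A is more than
#' `baseline_min_gap` bp away. Per distance bin, reports the median log2
#' ratio over the baseline median and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param instancesA,instancesB MotifInstance data.frames; B must carry
#'   `total_contribution`.
#' @param bins breaks (bp) partitioning [0, baseline_min_gap], e.g.
#'   c(0, 30, 60, 150).
#' @param baseline_min_gap bp beyond which B counts as baseline.
#' @return list(table = per-bin data.frame, pairs = per-B data.frame,
#'   baseline_median, n_baseline).
#' @export
distance_contributions <- function(instancesA, instancesB,
                                   bins = c(0, 30, 60, 150),
                                   baseline_min_gap = 150) {
  stopifnot(nrow(instancesA) > 0, nrow(instancesB) > 0)
  if (!"total_contribution" %in% names(instancesB) ||
      all(is.na(instancesB$total_contribution)))
    stop("instancesB must carry total_contribution")
  gaps <- rep(NA_real_, nrow(instancesB))
  for (i in seq_len(nrow(instancesB))) {
    a <- instancesA[instancesA$contig == instancesB$contig[i], , drop = FALSE]
    if (!nrow(a)) next
    d <- edge_gap(instancesB$start[i], instancesB$end[i], a$start, a$end)
    gaps[i] <- d[order(d, a$start)][1]
  }
  pairs <- data.frame(gap = gaps,
                      contribution = instancesB$total_contribution)
  pairs <- pairs[is.finite(pairs$gap), , drop = FALSE]
  base <- pairs$contribution[pairs$gap > baseline_min_gap]
  if (!length(base))
    stop("empty baseline: simulate a larger genome or lower baseline_min_gap")
  bmed <- stats::median(base)
  rows <- list()
  for (k in seq_len(length(bins) - 1L)) {
    inb <- pairs$gap >= bins[k] & pairs$gap < bins[k + 1L]
    if (!any(inb)) {
      rows[[k]] <- data.frame(bin_lo = bins[k], bin_hi = bins[k + 1L],
                              n = 0L, median_log2_ratio = NA_real_,
                              p_value = NA_real_)
      next
    }
    v <- pairs$contribution[inb]
    p <- stats::wilcox.test(v, base, exact = FALSE)$p.value
    rows[[k]] <- data.frame(bin_lo = bins[k], bin_hi = bins[k + 1L],
                            n = sum(inb),
                            median_log2_ratio = log2(stats::median(v) / bmed),
                            p_value = p)
  }
  list(table = do.call(rbind, rows), pairs = pairs,
       baseline_median = bmed, n_baseline = length(base))
}

#' Linear distance decay of contribution, as percent per 10 bp
#'
#' Ordinary least squares of contribution on edge gap over pairs within
#' `max_gap`; the slope is expressed as 100 * 10 * b / intercept (percent of
#' the zero-distance level per 10 bp) with the coefficient's p-value.
#'
#' @param pairs data.frame with `gap` and `contribution` (e.g. the `pairs`
#'   element of [distance_contributions()]).
#' @param max_gap bp.
#' @return list(slope_pct_per_10bp, p_value, slope_raw, intercept, n,
#'   percent_form): `percent_form` is FALSE (with slope_pct NA) when the
#'   intercept is non-positive.
#' @export
distance_slope <- function(pairs, max_gap = 150) {
  d <- pairs[pairs$gap <= max_gap & is.finite(pairs$gap), , drop = FALSE]
  if (nrow(d) < 10) stop("need >= 10 pairs within max_gap")
  fit <- stats::lm(contribution ~ gap, data = d)
  co <- summary(fit)$coefficients
  b <- co["gap", "Estimate"]; a <- co["(Intercept)", "Estimate"]
  p <- co["gap", "Pr(>|t|)"]
  if (a <= 0)
    return(list(slope_pct_per_10bp = NA_real_, p_value = p, slope_raw = b,
                intercept = a, n = nrow(d), percent_form = FALSE))
  list(slope_pct_per_10bp = 100 * 10 * b / a, p_value = p, slope_raw = b,
       intercept = a, n = nrow(d), percent_form = TRUE)
}

#' Merge motif instances into motif islands
#'
#' Each island starts as a `window` bp region centered on an instance's
#' midpoint; overlapping windows are merged transitively into maximal
#' disjoint islands (clipped to contig bounds when lengths are given), so an
#' island extends whenever another motif lies within less than `window` bp.
#' Every instance belongs to exactly one island.
#'
#' @param instances MotifInstance data.frame.
#' @param window island seed width (bp).
#' @param contig_lengths optional named vector for clipping.
#' @return data.frame of islands: contig, start, end, n_instances, members
#'   (list-column of instance row indices), per-motif counts in attribute
#'   "motif_counts".
#' @export
build_islands <- function(instances, window = 500L, contig_lengths = NULL) {
  if (!nrow(instances))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), n_instances = integer(0)))
  half <- window %/% 2L
  mids <- (instances$start + instances$end) %/% 2L
  ws <- mids - half; we <- mids + half
  if (!is.null(contig_lengths)) {
    ws <- pmax(0L, ws)
    we <- pmin(unname(contig_lengths[instances$contig]), we)
  } else ws <- pmax(0L, ws)
  out <- list()
  for (cn in sort(unique(instances$contig))) {
    idx <- which(instances$contig == cn)
    o <- idx[order(ws[idx])]
    cur_s <- ws[o[1]]; cur_e <- we[o[1]]; cur_m <- o[1]
    flush <- function() {
      mot <- table(instances$motif_name[cur_m])
      df <- data.frame(contig = cn, start = as.integer(cur_s),
                       end = as.integer(cur_e),
                       n_instances = length(cur_m), stringsAsFactors = FALSE)
      df$members <- I(list(cur_m))
      df$motif_counts <- I(list(as.list(mot)))
      df
    }
    for (i in o[-1]) {
      if (ws[i] < cur_e) { cur_e <- max(cur_e, we[i]); cur_m <- c(cur_m, i) }
      else { out[[length(out) + 1L]] <- flush()
             cur_s <- ws[i]; cur_e <- we[i]; cur_m <- i }
    }
    out[[length(out) + 1L]] <- flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide IUPAC double-motif spacing scan
#'
#' Exactly matches (no mismatches) the 7-bp core of `core_pattern` on both
#' strands; consecutive same-strand core matches with an inter-core gap of at
#' most `max_gap` bp form a double occurrence. Spacing is defined on the 7-bp
#' core (the full 9-bp pattern is required only for isolated single-motif
#' calls), so a spacing of 2 corresponds to the template
#' core-NN-core. Returns the spacing frequency table and the located pairs.
#'
#' @param seqs named character vector of sequences (or a `synthetic_genome`).
#' @param core_pattern IUPAC pattern; the first `core_width` characters are
#'   the core.
#' @param max_gap maximum core spacing (bp).
#' @param core_width width of the core prefix.
#' @return list(spacing = data.frame(spacing, count), pairs = BED-like
#'   data.frame, singles = full-pattern matches).
#' @export
scan_double_pattern <- function(seqs, core_pattern = "RMATTCCWD",
                                max_gap = 23L, core_width = 7L) {
  if (inherits(seqs, "synthetic_genome")) seqs <- seqs$contigs
  if (!grepl("^[ACGTRYMKWSBDHVN]+$", toupper(core_pattern)))
    stop("invalid IUPAC character in pattern")
  core <- substr(toupper(core_pattern), 1L, core_width)
  pairs <- list(); singles <- list()
  for (cn in names(seqs)) {
    subject <- Biostrings::DNAString(seqs[[cn]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") core else revcomp(core)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                    fixed = FALSE)
      st <- BiocGenerics::start(m) - 1L           # 0-based
      if (length(st) >= 2) {
        st <- sort(st)
        gap <- st[-1] - (st[-length(st)] + core_width)
        ok <- which(gap >= 0 & gap <= max_gap)
        if (length(ok)) {
          # orient spacing 5'->3' of the motif: on '-' the genomic order is
          # reversed but the core gap is symmetric, so genomic gap is used
          pairs[[length(pairs) + 1L]] <- data.frame(
            contig = cn, start = st[ok], end = st[ok + 1L] + core_width,
            strand = strand, spacing = gap[ok], stringsAsFactors = FALSE)
        }
      }
      fp <- if (strand == "+") toupper(core_pattern) else
        revcomp(toupper(core_pattern))
      sm <- Biostrings::matchPattern(Biostrings::DNAString(fp), subject,
                                     fixed = FALSE)
      if (length(sm))
        singles[[length(singles) + 1L]] <- data.frame(
          contig = cn, start = BiocGenerics::start(sm) - 1L,
          end = BiocGenerics::end(sm), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), spacing = integer(0))
  pairs <- pairs[order(pairs$contig, pairs$start, pairs$strand), , drop = FALSE]
  rownames(pairs) <- NULL
  singles <- if (length(singles)) do.call(rbind, singles) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  spacing <- data.frame(spacing = 0:max_gap,
                        count = vapply(0:max_gap, function(s)
                          sum(pairs$spacing == s), integer(1)))
  list(spacing = spacing, pairs = pairs, singles = singles)
}

#' Frequency and predicted affinity of identical motif sequence variants
#'
#' Groups identical instance sequences, keeps patterns occurring at least
#' `min_count` times and at or above the `percentile` quantile of pattern
#' counts (mode "top"; mode "above" keeps everything above the
#' 1 - percentile quantile instead), injects each surviving pattern into
#' randomized backgrounds and reports its frequency and mean windowed
#' prediction.
#'
#' @param sequences character vector of instance sequences (oriented).
#' @param predictor a binding predictor.
#' @param task measured task.
#' @param n_backgrounds backgrounds per pattern.
#' @param seed RNG seed.
#' @param min_count minimum occurrences.
#' @param percentile count-quantile cutoff.
#' @param mode "top" (count >= quantile(percentile)) or "above"
#'   (count >= quantile(1 - percentile)).
#' @return data.frame: pattern, frequency, mean_prediction (sorted by
#'   frequency); empty with a warning when nothing survives.
#' @export
variant_frequency_analysis <- function(sequences, predictor, task,
                                       n_backgrounds = 64L, seed = 1L,
                                       min_count = 10L, percentile = 0.9,
                                       mode = c("top", "above")) {
  mode <- match.arg(mode)
  tab <- sort(table(sequences), decreasing = TRUE)
  q <- if (mode == "top") stats::quantile(as.numeric(tab), percentile)
       else stats::quantile(as.numeric(tab), 1 - percentile)
  keep <- tab[as.numeric(tab) >= min_count & as.numeric(tab) >= q]
  if (!length(keep)) {
    warning("no pattern survives the frequency filters")
    return(data.frame(pattern = character(0), frequency = integer(0),
                      mean_prediction = numeric(0)))
  }
  preds <- vapply(names(keep), function(pat)
    inject_predict(predictor, pat, NULL, task = task,
                   n_backgrounds = n_backgrounds,
                   seed = child_seed(seed, pat))$hA, numeric(1))
  data.frame(pattern = names(keep), frequency = as.integer(keep),
             mean_prediction = unname(preds), stringsAsFactors = FALSE,
             row.names = NULL)
}
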