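# independent brute-force PWM scanner (no shared code with pwm_scan)
brute_pwm_scores <- function(seq, pwm, background, pseudocount = 0.01) {
  pwm <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  LO <- log2(pwm) - log2(background)
  ch <- strsplit(seq, "")[[1]]
  w <- ncol(LO)
  n <- nchar(seq) - w + 1L
  fwd <- numeric(n); rev_ <- numeric(n)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (p in seq_len(n)) {
    s1 <- 0; s2 <- 0
    for (j in seq_len(w)) {
      s1 <- s1 + LO[ch[p + j - 1], j]
      s2 <- s2 + LO[comp[ch[p + w - j]], j]
    }
    fwd[p] <- s1; rev_[p] <- s2
  }
  list(fwd = fwd, rev = rev_)
}


# independent regex-based IUPAC double scanner (oracle for scan_double_pattern)
brute_double_scan <- function(seqs, core = "RMATTCC", max_gap = 23L) {
  iu <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
          M = "[AC]", K = "[GT]", W = "[AT]", S = "[CG]", B = "[CGT]",
          D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  rx <- function(p) paste(iu[strsplit(p, "")[[1]]], collapse = "")
  core_w <- nchar(core)
  out <- list()
  for (cn in names(seqs)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") core else revcomp(core)
      # overlapping matches via lookahead
      mm <- gregexpr(paste0("(?=", rx(pat), ")"), seqs[[cn]], perl = TRUE)[[1]]
      st <- as.integer(mm)
      st <- st[st > 0] - 1L
      if (length(st) >= 2) {
        st <- sort(st)
        gap <- st[-1] - (st[-length(st)] + core_w)
        ok <- which(gap >= 0 & gap <= max_gap)
        if (length(ok))
          out[[length(out) + 1L]] <- data.frame(
            contig = cn, start = st[ok], end = st[ok + 1L] + core_w,
            strand = strand, spacing = gap[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      spacing = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), ]
}



# exhaustive dedup oracle: enumerate all subsets; a valid result is an
# independent set (no reciprocal >= 50% overlap) where every excluded
# instance conflicts with a kept instance of better-or-equal score
brute_dedup <- function(df, key = df$match_score) {
  n <- nrow(df)
  conflict <- function(i, j) {
    ov <- max(0, min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]))
    ov >= 0.5 * (df$end[i] - df$start[i]) &&
      ov >= 0.5 * (df$end[j] - df$start[j])
  }
  best <- NULL
  for (bits in 0:(2^n - 1)) {
    keep <- which(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(keep) > 1)
      for (a in seq_along(keep)) for (b in seq_along(keep))
        if (a < b && conflict(keep[a], keep[b])) ok <- FALSE
    for (e in setdiff(seq_len(n), keep)) {
      if (!any(vapply(keep, function(k)
        conflict(e, k) && key[k] >= key[e], logical(1)))) ok <- FALSE
    }
    if (ok && (is.null(best) || sum(key[keep]) > sum(key[best]))) best <- keep
  }
  df[sort(best), ]
}
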