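#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate alphabet -> allowed bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  W = c("A", "T"), S = c("C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", M = "K", K = "M",
  W = "W", S = "S", B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Split a DNA string into a character vector of bases
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Integer encoding of a DNA string (A=1, C=2, G=3, T=4)
#' @noRd
seq_ints <- function(x) {
  ints <- match(seq_chars(toupper(x)), DNA_BASES)
  if (anyNA(ints)) {
    bad <- which(is.na(ints))[1]
    stop("non-ACGT base '", seq_chars(toupper(x))[bad], "' at position ", bad)
  }
  ints
}

#' Reverse complement of a DNA (possibly IUPAC) string
#'
#' @param x a DNA string.
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  ch <- rev(seq_chars(toupper(x)))
  out <- IUPAC_COMPLEMENT[ch]
  if (anyNA(out)) stop("cannot complement character(s): ",
                       paste(unique(ch[is.na(out)]), collapse = ","))
  paste(out, collapse = "")
}

#' One-hot encode a DNA string as an L x 4 matrix (columns A,C,G,T)
#' @noRd
onehot <- function(x) {
  ints <- if (is.character(x) && length(x) == 1L) seq_ints(x) else x
  m <- matrix(0, length(ints), 4L, dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(ints), ints)] <- 1
  m
}

#' 4 x W allowed-base match matrix for an IUPAC pattern
#' @noRd
iupac_matrix <- function(pattern) {
  ch <- seq_chars(toupper(pattern))
  m <- matrix(0, 4L, length(ch), dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(ch)) {
    allowed <- IUPAC_CODES[[ch[j]]]
    if (is.null(allowed)) stop("invalid IUPAC character '", ch[j], "'")
    m[allowed, j] <- 1
  }
  m
}

#' Random iid DNA with a given GC fraction
#' @noRd
random_dna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Evaluate code under a fixed RNG seed, restoring RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Derive a child seed from a base seed and a stage label (stays < 2^31)
#' @noRd
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Dinucleotide-preserving shuffle of a DNA sequence
#'
#' Implements the Altschul-Erickson Eulerian-path shuffle: the returned sequence
#' has exactly the same dinucleotide (and hence mononucleotide) counts as the
#' input. Used to build reference sequences for contribution scores.
#'
#' @param x DNA string (ACGT).
#' @return shuffled DNA string.
#' @export
dinuc_shuffle <- function(x) {
  ch <- seq_chars(toupper(x))
  n <- length(ch)
  if (n <= 3L) return(x)
  verts <- unique(ch)
  last <- ch[n]
  # edge lists: for each vertex, the multiset of successors
  succ <- split(ch[-1], ch[-n])
  # choose random "last" edges for each non-terminal vertex such that following
  # last edges from every vertex reaches the terminal vertex (connectivity)
  nonterm <- setdiff(verts, last)
  repeat {
    last_edge <- vapply(nonterm, function(v) {
      s <- succ[[v]]
      s[sample.int(length(s), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in nonterm) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !(cur %in% nonterm)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the remaining edges, appending the designated last edge
  for (v in verts) {
    s <- succ[[v]]
    if (v %in% nonterm) {
      i <- match(last_edge[[v]], s)
      s <- s[-i]
      succ[[v]] <- c(if (length(s)) s[sample.int(length(s))] else character(0),
                     last_edge[[v]])
    } else {
      succ[[v]] <- if (length(s)) s[sample.int(length(s))] else character(0)
    }
  }
  # walk
  out <- character(n)
  out[1] <- ch[1]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- succ[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Count dinucleotides of a sequence (16-long named vector)
#' @noRd
dinuc_counts <- function(x) {
  ch <- seq_chars(toupper(x))
  if (length(ch) < 2) return(integer(0))
  di <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  table(factor(di, levels = lv))
}

#' Write a substring into a sequence (1-based start), returning the new string
#' @noRd
write_sub <- function(seq, at, what) {
  w <- nchar(what)
  stopifnot(at >= 1, at + w - 1 <= nchar(seq))
  paste0(substr(seq, 1, at - 1), what, substr(seq, at + w, nchar(seq)))
}
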