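# Readers/writers for the standard plain-text formats: FASTA, BED-like
# instance tables, bedGraph coverage, MEME minimal motifs (+ JSON CWM
# sidecar) and the JSON run configuration.

COORD_HEADER <- "# coordinates: 0-based, half-open (BED convention)"

#' Read a FASTA file into a named character vector
#'
#' Sequences are case-folded to upper; non-ACGTN characters and duplicate
#' contig names are rejected.
#'
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        # locate the offending character for the error message
        lines <- readLines(path)
        cur <- ""
        for (i in seq_along(lines)) {
          if (startsWith(lines[i], ">")) { cur <- sub("^>\\s*", "", lines[i]); next }
          bad <- regexpr("[^ACGTNacgtn]", lines[i])
          if (bad > 0)
            stop("contig '", sub("\\s.*$", "", cur), "' has invalid character '",
                 substr(lines[i], bad, bad), "' at position ", bad, call. = FALSE)
        }
        stop("FASTA contains invalid sequence characters", call. = FALSE)
      }
    })
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms))
    stop("duplicate contig name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ","))
  out <- stats::setNames(toupper(as.character(ss)), nms)
  for (i in seq_along(out)) {
    bad <- regmatches(out[i], regexpr("[^ACGTN]", out[i]))
    if (length(bad) && nzchar(bad))
      stop("contig '", nms[i], "' has non-ACGTN character '", bad,
           "' at position ", regexpr("[^ACGTN]", out[i]))
  }
  out
}

#' Write sequences as FASTA (80-column wrapped)
#'
#' @param seqs named character vector (or `synthetic_genome`).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "synthetic_genome")) seqs <- seqs$contigs
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write motif instances as BED6+3
#'
#' Columns: chrom, start, end, name, score (0-1000 scaled match score),
#' strand, motif_name, total_contribution, source. Sorted by (contig, start)
#' on write; a header comment records the coordinate convention.
#'
#' @param instances MotifInstance data.frame.
#' @param path output path.
#' @export
write_instances_bed <- function(instances, path) {
  x <- instances[order(instances$contig, instances$start), , drop = FALSE]
  sc <- x$match_score
  mx <- if (nrow(x) && any(is.finite(sc))) max(sc[is.finite(sc)]) else 1
  score <- ifelse(is.finite(sc) & mx > 0, round(1000 * sc / mx), 0L)
  writeLines(COORD_HEADER, path)
  if (nrow(x)) {
    df <- data.frame(x$contig, x$start, x$end, x$motif_name, score, x$strand,
                     x$motif_name, x$total_contribution, x$source)
    data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Read motif instances written by [write_instances_bed()]
#'
#' Coordinates are validated (end > start, reported with line numbers) and
#' optionally checked against contig lengths.
#'
#' @param path BED path.
#' @param contig_lengths optional named vector for bounds checking.
#' @export
read_instances_bed <- function(path, contig_lengths = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body)) return(empty_instances())
  dt <- data.table::fread(text = lines[body], sep = "\t", header = FALSE)
  bad <- which(dt[[3]] <= dt[[2]])
  if (length(bad))
    stop("end <= start at line ", body[bad[1]], " of ", path)
  if (!all(dt[[6]] %in% c("+", "-")))
    stop("invalid strand value in ", path)
  if (!is.null(contig_lengths)) {
    over <- which(dt[[3]] > contig_lengths[dt[[1]]])
    if (length(over))
      stop("coordinate past contig end at line ", body[over[1]], " of ", path)
  }
  res <- data.frame(contig = as.character(dt[[1]]), start = dt[[2]],
                    end = dt[[3]], strand = as.character(dt[[6]]),
                    motif_name = as.character(dt[[7]]),
                    match_score = dt[[5]] / 1000,
                    total_contribution = as.numeric(dt[[8]]),
                    source = as.character(dt[[9]]), stringsAsFactors = FALSE)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Write a genome's truth table as BED6+2 (motif_name, occupancy)
#' @param genome a `synthetic_genome`.
#' @param path output path.
#' @export
write_truth_bed <- function(genome, path) {
  tr <- genome$truth
  writeLines(COORD_HEADER, path)
  if (nrow(tr)) {
    mx <- max(tr$occupancy)
    df <- data.frame(tr$contig, tr$start, tr$end, tr$motif,
                     round(1000 * tr$occupancy / mx), tr$strand,
                     tr$motif, tr$occupancy)
    data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a stranded profile set as bedGraph files (one per task and strand)
#'
#' @param profiles a `stranded_profile_set`.
#' @param dir output directory.
#' @param tasks subset of tasks (default all).
#' @return paths written.
#' @export
write_profiles_bedgraph <- function(profiles, dir, tasks = names(profiles)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in tasks) for (strand in c("plus", "minus")) {
    path <- file.path(dir, paste0(t, "_", strand, ".bedGraph"))
    writeLines(COORD_HEADER, path)
    for (cn in names(profiles[[t]])) {
      v <- profiles[[t]][[cn]][[strand]]
      r <- rle(v)
      e <- cumsum(r$lengths); s <- e - r$lengths
      keep <- r$values != 0
      if (any(keep))
        data.table::fwrite(data.frame(cn, s[keep], e[keep], r$values[keep]),
                           path, sep = "\t", append = TRUE, col.names = FALSE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write motifs in MEME minimal format (frequency PWMs)
#'
#' @param motifs list of `motif` objects.
#' @param path output path.
#' @param background length-4 base frequencies.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
               ""), con)
  for (m in motifs) {
    writeLines(c(paste("MOTIF", m$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         m$width, max(1L, m$support))), con)
    for (j in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read MEME minimal format motifs
#' @param path MEME file path.
#' @return list of `motif` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF ", lines)
  motifs <- list()
  for (i in idx) {
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    hdr <- i + which(grepl("letter-probability matrix", lines[(i + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    pwm <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    dimnames(pwm) <- NULL
    motifs[[name]] <- new_motif(name, t(pwm))
  }
  motifs
}

#' Write / read motif CWMs as a JSON sidecar
#'
#' @param motifs list of `motif` objects.
#' @param path JSON path.
#' @export
write_motif_json <- function(motifs, path) {
  x <- lapply(motifs, function(m)
    list(name = m$name, consensus = m$consensus, support = m$support,
         pwm = m$pwm, cwm = m$cwm))
  jsonlite::write_json(x, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_motif_json
#' @export
read_motif_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(length(x$name)), function(i)
    new_motif(x$name[i], matrix(unlist(x$pwm[i]), nrow = 4),
              cwm = if (!is.null(x$cwm)) matrix(unlist(x$cwm[i]), nrow = 4),
              consensus = x$consensus[i], support = x$support[i]))
}

#' Resolve a run configuration, filling defaults and seeds
#'
#' Unknown top-level keys are rejected. Every stochastic stage gets an
#' explicit seed after resolution (derived from `seed` when absent, with a
#' message).
#'
#' @param config a list (e.g. from [read_config()]).
#' @return resolved config list.
#' @export
resolve_config <- function(config = list()) {
  defaults <- list(
    grammar = list(), seed = 1L,
    genome = list(n_contigs = 4L, contig_len = 500000L, density = 0.05),
    predictor = "oracle",
    window = 1000L,
    split = NULL,
    background_frac = 0.1,
    hyperparams = list(),
    seeds = list(),
    n_backgrounds = 64L,
    distances = c(0L, 10L, 20L, 40L, 80L, 120L),
    version = as.character(utils::packageVersion("synlab"))
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ","))
  cfg <- utils::modifyList(defaults, config)
  for (s in c("genome", "profiles", "training", "backgrounds", "attribution")) {
    if (is.null(cfg$seeds[[s]])) {
      cfg$seeds[[s]] <- child_seed(cfg$seed, s)
      message("config: seed for stage '", s, "' defaulted to ", cfg$seeds[[s]])
    }
  }
  cfg
}

#' Read a JSON run configuration file
#' @param path JSON path.
#' @export
read_config <- function(path) {
  resolve_config(jsonlite::read_json(path, simplifyVector = TRUE))
}
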