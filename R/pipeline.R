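# End-to-end pipeline: simulate -> train (or oracle) -> evaluate ->
# attribute -> discover -> scan -> islands -> in-silico syntax statistics,
# with a manifest recording inputs, seeds and the config hash.

stage_log <- function(run, stage, ...) {
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste0(..., collapse = ""))
  message(msg)
  cat(msg, "\n", file = file.path(run, "pipeline.log"), append = TRUE)
}

#' Run the full pipeline into a run directory
#'
#' Stages: simulate genome and profiles; build predictor (analytic oracle or
#' trained model); evaluate; contribution maps over instance windows; motif
#' discovery; CWM + PWM scanning; islands; double-pattern spacing scan;
#' injection distance sweep and double-motif cooperativity. All outputs are
#' plain text; a manifest.json records seeds, config and package version.
#' Rerunning with the same config reproduces deterministic outputs.
#'
#' @param config list accepted by [resolve_config()].
#' @param out_dir run directory (created).
#' @param n_attr_windows number of instance windows attributed (scaled for
#'   CPU budgets).
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, n_attr_windows = 30L) {
  cfg <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- normalizePath(out_dir)

  stage <- "simulate"
  tryCatch({
    grammar <- make_grammar(cfg$grammar)
    genome <- simulate_genome(grammar, n_contigs = cfg$genome$n_contigs,
                              contig_len = cfg$genome$contig_len,
                              density = cfg$genome$density,
                              seed = cfg$seeds$genome)
    profiles <- simulate_profiles(genome, grammar, seed = cfg$seeds$profiles)
    write_fasta(genome, file.path(run, "genome.fa"))
    write_truth_bed(genome, file.path(run, "truth.bed"))
    write_profiles_bedgraph(profiles, file.path(run, "profiles"))
    stage_log(run, stage, nrow(genome$truth), " truth instances")

    stage <- "predictor"
    split <- cfg$split
    if (is.null(split)) {
      cns <- names(genome$contigs)
      split <- stats::setNames(rep("train", length(cns)), cns)
      if (length(cns) >= 3) { split[length(cns) - 1L] <- "val"
                              split[length(cns)] <- "test" }
      else if (length(cns) == 2) split[2] <- "val"
    } else split <- unlist(split)
    dataset <- make_training_set(genome, profiles, window = cfg$window,
                                 split = split, seed = cfg$seeds$training)
    predictor <- if (identical(cfg$predictor, "oracle")) {
      oracle_predictor(grammar, window = cfg$window)
    } else {
      hp <- do.call(bpnet_hyperparams, cfg$hyperparams)
      m <- train_model(dataset, hp, seed = cfg$seeds$training)
      save_model(m, file.path(run, "model"))
      m
    }
    stage_log(run, stage, cfg$predictor)

    stage <- "evaluate"
    eval_split <- if (any(dataset$meta$split == "test")) "test" else "train"
    report <- evaluate_model(predictor, dataset, split = eval_split)
    jsonlite::write_json(
      list(split = eval_split, counts_spearman = as.list(report$counts_spearman),
           median_jsd = lapply(report$jsd, `[[`, "median"),
           auprc = report$auprc),
      file.path(run, "evaluation.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    stage_log(run, stage, eval_split)

    stage <- "attribute"
    task0 <- grammar$direct_tasks[1]
    idx <- which(dataset$meta$motif != "background")
    idx <- utils::head(idx, n_attr_windows)
    cmaps <- lapply(seq_along(idx), function(k)
      contribution_scores(predictor, dataset$windows[[idx[k]]]$seq, task0,
                          seed = child_seed(cfg$seeds$attribution, paste0("w", k))))
    stage_log(run, stage, length(cmaps), " maps for ", task0)

    stage <- "discover"
    seqlets <- extract_seqlets(cmaps)
    motifs <- discover_motifs(seqlets, min_support = 5L)
    if (length(motifs)) {
      write_meme(motifs, file.path(run, "motifs.meme"))
      write_motif_json(motifs, file.path(run, "motifs.json"))
    }
    stage_log(run, stage, length(motifs), " motifs from ", nrow(seqlets), " seqlets")

    stage <- "scan"
    inst <- empty_instances()
    if (length(motifs)) {
      contig <- dataset$meta$contig[idx]
      offset <- dataset$meta$start[idx]
      inst <- do.call(rbind, lapply(motifs, function(m)
        cwm_scan(cmaps, m, contig = contig, offset = offset)))
      inst <- dedup_instances(inst)
      write_instances_bed(inst, file.path(run, "instances_cwm.bed"))
      pw <- do.call(rbind, lapply(seq_along(idx), function(k)
        pwm_scan(dataset$windows[[idx[k]]]$seq, motifs[[1]],
                 contig = contig[k], offset = offset[k])))
      write_instances_bed(dedup_instances(pw), file.path(run, "instances_pwm.bed"))
    }
    stage_log(run, stage, nrow(inst), " CWM instances")

    stage <- "islands"
    isl <- build_islands(if (nrow(inst)) inst else
      data.frame(contig = genome$truth$contig, start = genome$truth$start,
                 end = genome$truth$end, motif_name = genome$truth$motif))
    writeLines(COORD_HEADER, file.path(run, "islands.bed"))
    if (nrow(isl))
      data.table::fwrite(isl[, c("contig", "start", "end", "n_instances")],
                         file.path(run, "islands.bed"), sep = "\t",
                         append = TRUE, col.names = FALSE)
    stage_log(run, stage, nrow(isl), " islands")

    stage <- "doublescan"
    ds <- scan_double_pattern(genome)
    data.table::fwrite(ds$spacing, file.path(run, "double_spacing.tsv"), sep = "\t")
    stage_log(run, stage, sum(ds$spacing$count), " double occurrences")

    stage <- "insilico"
    mA <- grammar$motifs[[1]]$consensus
    mB <- if (length(grammar$motifs) > 1) grammar$motifs[[2]]$consensus else NULL
    if (!is.null(mB)) {
      sweep <- distance_sweep(predictor, mA, mB, task = task0,
                              distances = cfg$distances,
                              n_backgrounds = cfg$n_backgrounds,
                              seed = cfg$seeds$backgrounds)
      data.table::fwrite(sweep, file.path(run, "enhancement_curve.tsv"), sep = "\t")
    }
    if (length(grammar$strict_rules)) {
      r <- grammar$strict_rules[[1]]
      cc <- double_cooperativity(predictor, r$whole, split = r$half_width + r$gap,
                                 task = r$task, n_backgrounds = cfg$n_backgrounds,
                                 seed = cfg$seeds$backgrounds)
      jsonlite::write_json(
        list(double = r$whole, fold = cc$fold, pred_whole = cc$pred_whole,
             pred_additive = cc$pred_additive),
        file.path(run, "cooperativity.json"), auto_unbox = TRUE, digits = NA)
    }
    stage_log(run, stage, "done")

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("synlab")),
      config = cfg,
      config_hash = sum(utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE))),
      created = format(Sys.time())
    )
    jsonlite::write_json(manifest, file.path(run, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(run)
}
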