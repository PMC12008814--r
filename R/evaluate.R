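# Model evaluation: counts Spearman, Jensen-Shannon distance of profiles and
# binned-profile auPRC.

#' Jensen-Shannon distance between two non-negative profile vectors
#'
#' Vectors are L1-normalized; divergence uses base-2 logs and the square root
#' is returned, a metric in [0, 1] (0 = perfect concordance, 1 = no
#' similarity).
#'
#' @param p,q non-negative numeric vectors of equal length.
#' @export
js_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (sum(p) == 0 || sum(q) == 0) return(NA_real_)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d <- (kl(p, m) + kl(q, m)) / 2
  sqrt(max(0, min(1, d)))
}

#' Average precision (area under the precision-recall curve)
#' @noRd
average_precision <- function(labels, scores) {
  if (!any(labels) || all(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Bin a base-resolution vector by summing `res`-bp bins
#' @noRd
bin_profile <- function(x, res) {
  if (res <= 1L) return(x)
  n <- floor(length(x) / res)
  colSums(matrix(x[seq_len(n * res)], nrow = res))
}

#' Evaluate a predictor on the held-out part of a dataset
#'
#' Computes, per task: Spearman correlation of log1p total counts; binned
#' profile auPRC at 1/2/5/10 bp resolutions (a bin is positive if its observed
#' counts are >= max(1, 1.5 x window mean), bins between 0.5x and 1.5x the
#' mean are ambiguous and excluded); and the distribution of per-region
#' Jensen-Shannon distances between L1-normalized observed and predicted
#' concatenated-strand profiles. Regions with zero observed counts are
#' excluded from JSD and counted.
#'
#' @param predictor a binding predictor.
#' @param dataset a `profile_dataset`.
#' @param split which split to evaluate ("test", "val" or "train").
#' @param resolutions auPRC bin sizes (bp).
#' @return a `model_eval_report` list.
#' @export
evaluate_model <- function(predictor, dataset, split = "test",
                           resolutions = c(1L, 2L, 5L, 10L)) {
  idx <- which(dataset$meta$split == split)
  if (!length(idx)) stop("no windows in split '", split, "'")
  tasks <- intersect(dataset$tasks, predictor_tasks(predictor))
  obs_tot <- matrix(0, length(idx), length(tasks), dimnames = list(NULL, tasks))
  pred_tot <- obs_tot
  jsd <- stats::setNames(vector("list", length(tasks)), tasks)
  zero_regions <- stats::setNames(integer(length(tasks)), tasks)
  binlab <- list(); binscore <- list()
  for (t in tasks) for (r in resolutions) {
    binlab[[paste(t, r)]] <- logical(0); binscore[[paste(t, r)]] <- numeric(0)
  }
  for (k in seq_along(idx)) {
    win <- dataset$windows[[idx[k]]]
    pred <- predict_binding(predictor, win$seq)
    for (t in tasks) {
      obs <- win$Y[[t]]
      obs_tot[k, t] <- sum(obs)
      pred_tot[k, t] <- pred[[t]]$counts
      pv <- c(pred[[t]]$plus, pred[[t]]$minus)
      ov <- c(obs[, 1], obs[, 2])
      if (sum(ov) == 0) zero_regions[t] <- zero_regions[t] + 1L
      else {
        d <- js_distance(ov, pv)   # NA when the prediction is all-zero
        if (is.finite(d)) jsd[[t]] <- c(jsd[[t]], d)
      }
      oflat <- obs[, 1] + obs[, 2]
      pflat <- pred[[t]]$plus + pred[[t]]$minus
      for (r in resolutions) {
        ob <- bin_profile(oflat, r); pb <- bin_profile(pflat, r)
        mu <- mean(ob)
        pos <- ob >= pmax(1, 1.5 * mu)
        amb <- !pos & ob > 0.5 * mu
        key <- paste(t, r)
        binlab[[key]] <- c(binlab[[key]], pos[!amb])
        binscore[[key]] <- c(binscore[[key]], pb[!amb])
      }
    }
  }
  report <- list(tasks = tasks, n_regions = length(idx),
                 zero_regions = zero_regions)
  report$counts_spearman <- vapply(tasks, function(t)
    stats::cor(log1p(obs_tot[, t]), log1p(pred_tot[, t]), method = "spearman"),
    numeric(1))
  report$auprc <- lapply(stats::setNames(tasks, tasks), function(t)
    vapply(stats::setNames(resolutions, paste0("bp", resolutions)), function(r)
      average_precision(binlab[[paste(t, r)]], binscore[[paste(t, r)]]),
      numeric(1)))
  report$jsd <- lapply(jsd, function(v)
    list(median = stats::median(v), q1 = unname(stats::quantile(v, 0.25)),
         q3 = unname(stats::quantile(v, 0.75)), values = v))
  class(report) <- "model_eval_report"
  report
}

#' @export
print.model_eval_report <- function(x, ...) {
  cat("<model_eval_report> ", x$n_regions, " regions\n", sep = "")
  for (t in x$tasks) {
    cat(sprintf("  %-8s spearman=%.3f  median JSD=%.3f  auPRC(1bp)=%.3f\n",
                t, x$counts_spearman[t], x$jsd[[t]]$median, x$auprc[[t]]["bp1"]))
  }
  invisible(x)
}
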