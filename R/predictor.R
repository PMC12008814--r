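# BindingPredictor contract. A predictor exposes, for any input sequence:
#   predict_binding(): per task, expected stranded base-resolution read rates
#                      and total counts;
#   count_score():     a scalar attribution target, log1p(total counts);
#   count_score_grad():the gradient of that scalar w.r.t. the one-hot input.
# Implementations: the analytic grammar oracle (below) and the trained
# sequence-to-profile network (see train_model()).

#' Task names of a predictor
#' @param predictor a binding predictor.
#' @export
predictor_tasks <- function(predictor) UseMethod("predictor_tasks")

#' Nominal input window of a predictor (NA if any length is accepted)
#' @param predictor a binding predictor.
#' @export
predictor_window <- function(predictor) UseMethod("predictor_window")

#' Predict stranded binding profiles and total counts for a sequence
#'
#' @param predictor a binding predictor.
#' @param seq a DNA string over {A,C,G,T}.
#' @return named list per task: `list(plus, minus, counts)` where `plus` and
#'   `minus` are expected reads per base and `counts = sum(plus) + sum(minus)`.
#' @export
predict_binding <- function(predictor, seq) UseMethod("predict_binding")

#' Scalar attribution target: log1p of a task's predicted total counts
#' @param predictor a binding predictor.
#' @param seq a DNA string.
#' @param task task name.
#' @export
count_score <- function(predictor, seq, task) UseMethod("count_score")

#' Gradient of [count_score()] with respect to the one-hot input (L x 4)
#' @param predictor a binding predictor.
#' @param seq a DNA string.
#' @param task task name.
#' @export
count_score_grad <- function(predictor, seq, task) UseMethod("count_score_grad")

#' Express a predicted profile as probabilities over (2 strands x positions)
#'
#' @param pred one task's element of a [predict_binding()] result.
#' @return list(plus, minus) summing to 1 overall.
#' @export
profile_probabilities <- function(pred) {
  tot <- sum(pred$plus) + sum(pred$minus)
  if (tot <= 0) {
    L <- length(pred$plus)
    return(list(plus = rep(1 / (2 * L), L), minus = rep(1 / (2 * L), L)))
  }
  list(plus = pred$plus / tot, minus = pred$minus / tot)
}

# ---------------------------------------------------------------------------
# Analytic oracle predictor

#' Noise-free analytic predictor implementing the grammar directly
#'
#' Scans the sequence for exact and near-consensus grammar-motif matches,
#' applies occupancies, strict double-motif cooperativity and soft boosts, and
#' spreads occupancy by the footprint kernels. It satisfies the
#' BindingPredictor contract, so all interpretation machinery can be exercised
#' independently of model training; its gradients are analytic.
#'
#' @param grammar a `tf_grammar`.
#' @param depth background reads per bp per strand used in predictions.
#' @param window nominal window (the oracle accepts any sequence length).
#' @return an object of class `oracle_predictor`.
#' @export
oracle_predictor <- function(grammar, depth = grammar$depth, window = 1000L) {
  stopifnot(inherits(grammar, "tf_grammar"))
  structure(list(grammar = grammar, depth = depth, window = as.integer(window)),
            class = c("oracle_predictor", "binding_predictor"))
}

#' @export
predictor_tasks.oracle_predictor <- function(predictor) predictor$grammar$tasks

#' @export
predictor_window.oracle_predictor <- function(predictor) predictor$window

#' @export
predict_binding.oracle_predictor <- function(predictor, seq) {
  g <- predictor$grammar
  L <- nchar(seq)
  seq_ints(seq)  # validates alphabet
  inst <- grammar_analyze(g, seq)
  out <- list()
  for (task in g$tasks) {
    ex <- expected_task_profile(g, L, inst, task, depth = predictor$depth)
    out[[task]] <- list(plus = ex$plus, minus = ex$minus,
                        counts = sum(ex$plus) + sum(ex$minus))
  }
  out
}

#' @export
count_score.oracle_predictor <- function(predictor, seq, task) {
  g <- predictor$grammar
  inst <- grammar_analyze(g, seq)
  keep <- inst$motif %in% task_motifs(g, task)
  log1p(2 * nchar(seq) * predictor$depth + sum(inst$occupancy[keep]))
}

#' @export
count_score_grad.oracle_predictor <- function(predictor, seq, task) {
  g <- predictor$grammar
  L <- nchar(seq)
  inst <- grammar_analyze(g, seq)
  terms <- attr(inst, "partner_terms")
  keep <- which(inst$motif %in% task_motifs(g, task))
  G <- matrix(0, L, 4L, dimnames = list(NULL, DNA_BASES))

  add_span <- function(G, start, width, strand, consmat, coef) {
    C <- consmat  # 4 x w consensus indicator
    M <- if (strand == "+") t(C) else t(C[4:1, ncol(C):1, drop = FALSE])
    rows <- (start + 1L):(start + width)
    ok <- rows >= 1L & rows <= L
    G[rows[ok], ] <- G[rows[ok], ] + coef * M[ok, , drop = FALSE]
    G
  }
  # d occ_base_i / dx accumulated with coefficient `coef`
  add_occ_grad <- function(G, i, coef) {
    if (inst$is_double[i]) {
      rule <- g$strict_rules[[inst$motif[i]]]
      half <- g$motifs[[rule$half]]
      G <- add_span(G, inst$h1_start[i], half$width, inst$strand[i], half$match,
                    coef * rule$kappa * g$beta * inst$h1_occ[i])
      G <- add_span(G, inst$h2_start[i], half$width, inst$strand[i], half$match,
                    coef * rule$kappa * g$beta * inst$h2_occ[i])
    } else {
      m <- g$motifs[[inst$motif[i]]]
      G <- add_span(G, inst$start[i], m$width, inst$strand[i], m$match,
                    coef * g$beta * inst$occ_base[i])
    }
    G
  }

  total <- 2 * L * predictor$depth + sum(inst$occupancy[keep])
  for (i in keep) {
    G <- add_occ_grad(G, i, inst$boost[i])
    tt <- terms[[i]]
    if (!is.null(tt)) {
      for (r in seq_len(nrow(tt))) {
        j <- tt[r, "j"]; gij <- tt[r, "g"]
        # d occ_i/d occ_base_j = occ_i * (g_ij/occ_base_j) / (1 + g_ij)
        G <- add_occ_grad(G, j, inst$occupancy[i] * (gij / inst$occ_base[j]) / (1 + gij))
      }
    }
  }
  G / (1 + total)
}
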