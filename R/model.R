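# A small multi-task base-resolution sequence-to-profile network: a dilated
# convolutional body shared across tasks, a per-task profile head (softmax over
# 2 strands x positions, trained with multinomial negative log-likelihood) and
# a per-task counts head (global max pool + linear on log1p scale, trained
# with squared error; attribution uses a softmax-weighted pooling gradient). The shape follows the profile-model idiom; depth and
# filter counts are scaled down to stay CPU-trainable.

#' Hyperparameters for the sequence-to-profile model
#'
#' @param filters number of body filters.
#' @param conv_width width of the first convolution (bp).
#' @param dilations integer vector of dilation factors for the residual
#'   width-3 body layers (may be empty).
#' @param prof_width width of the per-task profile-head convolution.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param patience early-stopping patience (epochs without val improvement).
#' @param lambda counts-loss weight (default 2; NULL requests the
#'   profile-model convention mean(total counts per window)/2, which at this
#'   scale lets the counts gradient swamp profile learning - see vignette).
#' @export
bpnet_hyperparams <- function(filters = 32L, conv_width = 25L, dilations = c(8L),
                              prof_width = 7L, lr = 0.01, epochs = 80L,
                              batch = 4L, patience = 10L, lambda = 2,
                              profile_weight = 1) {
  stopifnot(conv_width %% 2 == 1, prof_width %% 2 == 1)
  list(filters = as.integer(filters), conv_width = as.integer(conv_width),
       dilations = as.integer(dilations), prof_width = as.integer(prof_width),
       lr = lr, epochs = as.integer(epochs), batch = as.integer(batch),
       patience = as.integer(patience), lambda = lambda,
       profile_weight = profile_weight)
}

init_params <- function(hp, tasks, seed_patterns = NULL) {
  K <- hp$filters
  W1 <- matrix(stats::rnorm(4L * hp$conv_width * K, sd = sqrt(2 / (4 * hp$conv_width))),
               4L * hp$conv_width, K)
  # data-driven initialization: plant one-hot sequence patterns harvested
  # under observed profile peaks into a subset of first-layer filters (zero
  # mean per position, so background scores ~0); training refines them
  if (!is.null(seed_patterns)) {
    for (k in seq_len(min(length(seed_patterns), K))) {
      pat <- seed_patterns[[k]]                 # conv_width x 4 one-hot
      W1[, k] <- as.vector(t(pat - 0.25)) * 0.5
    }
  }
  p <- list(W1 = W1, b1 = rep(0, K))
  for (l in seq_along(hp$dilations)) {
    p[[paste0("Wd", l)]] <- matrix(stats::rnorm(3L * K * K, sd = sqrt(2 / (3 * K))),
                                   3L * K, K)
    p[[paste0("bd", l)]] <- rep(0, K)
  }
  for (t in tasks) {
    p[[paste0("Wp_", t)]] <- matrix(stats::rnorm(hp$prof_width * K * 2L,
                                                 sd = sqrt(2 / (hp$prof_width * K))),
                                    hp$prof_width * K, 2L)
    p[[paste0("bp_", t)]] <- rep(0, 2L)
    p[[paste0("wc_", t)]] <- rep(0, K)
    p[[paste0("bc_", t)]] <- 0
  }
  p
}

# forward pass; if `keep` the intermediates needed for backward are returned
model_forward <- function(params, hp, tasks, X, keep = FALSE) {
  K <- hp$filters
  c1 <- conv_fwd(X, params$W1, params$b1, hp$conv_width, 1L)
  H <- relu(c1$Y)
  layers <- list()
  Hin <- H
  for (l in seq_along(hp$dilations)) {
    cl <- conv_fwd(Hin, params[[paste0("Wd", l)]], params[[paste0("bd", l)]],
                   3L, hp$dilations[l])
    Hl <- relu(cl$Y)
    layers[[l]] <- list(A = cl$Y, Xcol = cl$Xcol, Hin = Hin)
    Hin <- Hin + Hl
  }
  # counts head reads per-filter global max activations (high SNR for
  # sparse motif activations; sum pooling buries them in ReLU noise)
  amax <- max.col(t(Hin))
  pooled <- Hin[cbind(amax, seq_len(K))]
  y <- numeric(length(tasks)); names(y) <- tasks
  logits <- list(); pcols <- list()
  for (t in tasks) {
    ct <- conv_fwd(Hin, params[[paste0("Wp_", t)]], params[[paste0("bp_", t)]],
                   hp$prof_width, 1L)
    logits[[t]] <- ct$Y
    if (keep) pcols[[t]] <- ct$Xcol
    y[t] <- sum(pooled * params[[paste0("wc_", t)]]) + params[[paste0("bc_", t)]]
  }
  res <- list(y = y, logits = logits, H = Hin, pooled = pooled, amax = amax)
  if (keep) { res$c1 <- c1; res$A1 <- c1$Y; res$layers <- layers; res$pcols <- pcols }
  res
}

# backward pass from per-task dlogits (L x 2) and dy (named scalar vector);
# returns parameter gradients and optionally the input gradient
model_backward <- function(params, hp, tasks, X, fwd, dlogits, dy,
                           want_dx = FALSE) {
  L <- nrow(X); K <- hp$filters
  g <- lapply(params, function(p) p * 0)
  dH <- matrix(0, L, K)
  for (t in tasks) {
    if (!is.null(dlogits[[t]])) {
      bw <- conv_bwd(dlogits[[t]], fwd$pcols[[t]], params[[paste0("Wp_", t)]],
                     hp$prof_width, 1L, L, K)
      g[[paste0("Wp_", t)]] <- g[[paste0("Wp_", t)]] + bw$dW
      g[[paste0("bp_", t)]] <- g[[paste0("bp_", t)]] + bw$db
      dH <- dH + bw$dX
    }
    if (!is.null(dy) && dy[t] != 0) {
      g[[paste0("wc_", t)]] <- g[[paste0("wc_", t)]] + dy[t] * fwd$pooled
      g[[paste0("bc_", t)]] <- g[[paste0("bc_", t)]] + dy[t]
      if (!is.null(fwd$amax)) {
        idx <- cbind(fwd$amax, seq_len(K))
        dH[idx] <- dH[idx] + dy[t] * params[[paste0("wc_", t)]]
      } else {
        # softened pooling gradient (attribution mode): distribute the
        # counts-head gradient by each filter's softmax activation weights
        dH <- dH + sweep(fwd$pool_w, 2L,
                         dy[t] * params[[paste0("wc_", t)]], "*")
      }
    }
  }
  for (l in rev(seq_along(hp$dilations))) {
    ly <- fwd$layers[[l]]
    dHl <- dH * (ly$A > 0)
    bw <- conv_bwd(dHl, ly$Xcol, params[[paste0("Wd", l)]], 3L, hp$dilations[l], L, K)
    g[[paste0("Wd", l)]] <- g[[paste0("Wd", l)]] + bw$dW
    g[[paste0("bd", l)]] <- g[[paste0("bd", l)]] + bw$db
    dH <- dH + bw$dX     # residual passthrough + branch
  }
  dA1 <- dH * (fwd$A1 > 0)
  bw <- conv_bwd(dA1, fwd$c1$Xcol, params$W1, hp$conv_width, 1L, L, 4L)
  g$W1 <- g$W1 + bw$dW
  g$b1 <- g$b1 + bw$db
  if (want_dx) list(grads = g, dX = bw$dX) else list(grads = g)
}

# Harvest one-hot sequence patterns under observed profile peaks of the
# highest-count training windows, in both orientations, to seed half of the
# first-layer filters.
harvest_patterns <- function(dataset, hp, tr, n = hp$filters %/% 2L) {
  w <- hp$conv_width; half <- (w - 1L) %/% 2L
  tasks <- dataset$tasks
  # per task, windows ranked by that task's counts; harvest round-robin so
  # every task's motif content seeds some filters
  ranked <- lapply(tasks, function(t) {
    tot <- vapply(tr, function(i) sum(dataset$windows[[i]]$Y[[t]]), numeric(1))
    tr[order(tot, decreasing = TRUE)]
  })
  pats <- list()
  ptr <- rep(1L, length(tasks))
  while (length(pats) < n) {
    advanced <- FALSE
    for (j in seq_along(tasks)) {
      if (length(pats) >= n) break
      while (ptr[j] <= length(ranked[[j]])) {
        i <- ranked[[j]][ptr[j]]
        ptr[j] <- ptr[j] + 1L
        win <- dataset$windows[[i]]
        y <- win$Y[[tasks[j]]]
        prof <- y[, 1] + y[, 2]
        pk <- which.max(prof)
        if (pk - half < 1 || pk + half > nrow(win$X)) next
        sub <- win$X[(pk - half):(pk + half), , drop = FALSE]
        pats[[length(pats) + 1L]] <- sub
        if (length(pats) < n)
          pats[[length(pats) + 1L]] <- sub[nrow(sub):1, 4:1]  # reverse complement
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break
  }
  pats
}

# loss + gradients for one window
window_loss_grad <- function(params, hp, tasks, win, lambda, want_grads = TRUE) {
  X <- win$X
  fwd <- model_forward(params, hp, tasks, X, keep = want_grads)
  loss <- 0
  dlogits <- list(); dy <- stats::setNames(numeric(length(tasks)), tasks)
  for (t in tasks) {
    obs <- win$Y[[t]]                     # L x 2 counts
    Tobs <- sum(obs)
    z <- as.vector(fwd$logits[[t]])
    p <- softmax_vec(z)
    pw <- if (is.null(hp$profile_weight)) 1 else hp$profile_weight
    if (Tobs > 0) loss <- loss - pw * sum(obs * log(matrix(p, ncol = 2) + 1e-12))
    target <- log1p(Tobs)
    loss <- loss + lambda * (fwd$y[t] - target)^2
    if (want_grads) {
      dlogits[[t]] <- pw * (matrix(p * Tobs, ncol = 2) - obs)
      dy[t] <- 2 * lambda * (fwd$y[t] - target)
    }
  }
  if (!want_grads) return(list(loss = loss))
  bk <- model_backward(params, hp, tasks, X, fwd, dlogits, dy)
  list(loss = loss, grads = bk$grads)
}

#' Train the multi-task sequence-to-profile model
#'
#' Loss per window is the sum over tasks of the multinomial negative
#' log-likelihood of the observed stranded profile under the softmax profile
#' head plus `lambda` times the squared error of the counts head on
#' log1p(total counts). Adam, minibatches, early stopping on validation loss.
#'
#' @param dataset a `profile_dataset` from [make_training_set()].
#' @param hyperparams from [bpnet_hyperparams()].
#' @param seed RNG seed for weight initialization and batch order.
#' @param verbose print per-epoch losses.
#' @return a `bpnet_model` predictor (also records the training curve in
#'   `$history`).
#' @export
train_model <- function(dataset, hyperparams = bpnet_hyperparams(), seed = 1L,
                        verbose = FALSE) {
  hp <- hyperparams
  tasks <- dataset$tasks
  tr <- which(dataset$meta$split == "train")
  va <- which(dataset$meta$split == "val")
  if (!length(tr)) stop("empty training set")
  if (!length(va)) stop("empty validation set")
  lambda <- hp$lambda
  if (is.null(lambda)) {
    tot <- vapply(tr, function(i)
      mean(vapply(tasks, function(t) sum(dataset$windows[[i]]$Y[[t]]), numeric(1))),
      numeric(1))
    lambda <- mean(tot) / 2
  }
  with_seed(seed, {
    params <- init_params(hp, tasks, seed_patterns = harvest_patterns(dataset, hp, tr))
    # start the counts bias at the per-task mean target (centers the MSE)
    for (t in tasks) {
      mt <- mean(vapply(tr, function(i) log1p(sum(dataset$windows[[i]]$Y[[t]])),
                        numeric(1)))
      params[[paste0("bc_", t)]] <- mt
    }
    st <- adam_init(params)
    best <- list(loss = Inf, params = params)
    history <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
    bad <- 0L
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample(tr)
      tl <- 0
      for (bstart in seq(1, length(ord), by = hp$batch)) {
        bidx <- ord[bstart:min(bstart + hp$batch - 1L, length(ord))]
        acc <- NULL
        for (i in bidx) {
          lg <- window_loss_grad(params, hp, tasks, dataset$windows[[i]], lambda)
          if (!is.finite(lg$loss)) stop("training diverged (NaN/Inf loss)")
          tl <- tl + lg$loss
          acc <- if (is.null(acc)) lg$grads else
            Map(`+`, acc, lg$grads)
        }
        acc <- lapply(acc, function(g) g / length(bidx))
        up <- adam_step(params, acc, st, hp$lr)
        params <- up$params; st <- up$state
      }
      vl <- sum(vapply(va, function(i)
        window_loss_grad(params, hp, tasks, dataset$windows[[i]], lambda,
                         want_grads = FALSE)$loss, numeric(1))) / length(va)
      tl <- tl / length(tr)
      history <- rbind(history, data.frame(epoch = epoch, train = tl, val = vl))
      if (verbose) message(sprintf("epoch %d train %.2f val %.2f", epoch, tl, vl))
      if (vl < best$loss - 1e-9) { best <- list(loss = vl, params = params); bad <- 0L }
      else { bad <- bad + 1L; if (bad >= hp$patience) break }
    }
    structure(list(params = best$params, hyperparams = hp, tasks = tasks,
                   window = dataset$window, lambda = lambda, history = history),
              class = c("bpnet_model", "binding_predictor"))
  })
}

#' @export
predictor_tasks.bpnet_model <- function(predictor) predictor$tasks

#' @export
predictor_window.bpnet_model <- function(predictor) predictor$window

model_input <- function(predictor, seq) {
  X <- if (is.matrix(seq)) seq else onehot(seq)
  if (nrow(X) != predictor$window)
    stop("sequence length ", nrow(X), " != model window ", predictor$window)
  X
}

#' @export
predict_binding.bpnet_model <- function(predictor, seq) {
  X <- model_input(predictor, seq)
  fwd <- model_forward(predictor$params, predictor$hyperparams, predictor$tasks, X)
  out <- list()
  for (t in predictor$tasks) {
    p <- matrix(softmax_vec(as.vector(fwd$logits[[t]])), ncol = 2)
    counts <- max(expm1(fwd$y[t]), 0)
    out[[t]] <- list(plus = p[, 1] * counts, minus = p[, 2] * counts,
                     counts = counts)
  }
  out
}

#' @export
count_score.bpnet_model <- function(predictor, seq, task) {
  X <- model_input(predictor, seq)
  fwd <- model_forward(predictor$params, predictor$hyperparams, predictor$tasks, X)
  unname(fwd$y[task])   # y is log1p(counts) by construction
}

#' @export
count_score_grad.bpnet_model <- function(predictor, seq, task) {
  X <- model_input(predictor, seq)
  hp <- predictor$hyperparams
  fwd <- model_forward(predictor$params, hp, predictor$tasks, X, keep = TRUE)
  dy <- stats::setNames(numeric(length(predictor$tasks)), predictor$tasks)
  dy[task] <- 1
  bk <- model_backward(predictor$params, hp, predictor$tasks, X, fwd,
                       dlogits = list(), dy = dy, want_dx = TRUE)
  colnames(bk$dX) <- DNA_BASES
  bk$dX
}

#' Save / load a trained model (weights + JSON sidecar)
#'
#' Weights go to an RDS file; a JSON sidecar records architecture, tasks and
#' training configuration so any saved predictor can be reloaded behind the
#' BindingPredictor interface.
#'
#' @param model a `bpnet_model`.
#' @param path file stem; writes `<path>.rds` and `<path>.json`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  side <- list(class = "bpnet_model", tasks = model$tasks, window = model$window,
               lambda = model$lambda,
               hyperparams = model$hyperparams[c("filters", "conv_width",
                                                 "dilations", "prof_width", "lr")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param path file stem used in [save_model()].
#' @export
load_model <- function(path) readRDS(paste0(path, ".rds"))
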