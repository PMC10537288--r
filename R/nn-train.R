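#' Training configuration
#'
#' Defaults mirror the pipeline's reference training recipe: 150 epochs of
#' Adam with initial learning rate 0.001, batch size 256, and 10% of the
#' training set held out for validation-loss tracking. No early stopping is
#' used; training always runs the configured number of epochs.
#'
#' @param epochs Number of epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param validation_fraction Fraction held out for validation (the last part
#'   of a seeded shuffle).
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param clip_norm Global gradient-norm clip (stabilizes recurrent nets).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 150L, learning_rate = 0.001,
                         batch_size = 256L, validation_fraction = 0.10,
                         seed = 1L, clip_norm = 5) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), clip_norm = clip_norm),
            class = "train_config")
}

# Shared minibatch Adam loop. loss_fn(out, idx) -> list(loss, dz).
run_training <- function(model, X, loss_fn, tc) {
  n <- nrow(X)
  perm <- sample.int(n)
  n_val <- floor(tc$validation_fraction * n)
  val_idx <- if (n_val > 0) perm[(n - n_val + 1L):n] else integer(0)
  tr_idx <- perm[seq_len(n - n_val)]

  state <- adam_init(model$params)
  step <- 0L
  hist_train <- numeric(tc$epochs)
  hist_val <- numeric(tc$epochs)
  for (ep in seq_len(tc$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    tot <- 0
    for (b0 in seq(1L, length(ord), by = tc$batch_size)) {
      bi <- ord[b0:min(b0 + tc$batch_size - 1L, length(ord))]
      fw <- model_fwd(model, X[bi, , drop = FALSE], training = TRUE)
      model$bn <- fw$bn
      ls <- loss_fn(fw$out, bi)
      grads <- model_bwd(model, fw$cache, ls$dz)
      grads <- clip_grads(grads, tc$clip_norm)
      step <- step + 1L
      upd <- adam_step(model$params, grads, state, tc$learning_rate, step)
      model$params <- upd$params
      state <- upd$state
      tot <- tot + ls$loss * length(bi)
    }
    hist_train[ep] <- tot / length(ord)
    if (length(val_idx) > 0) {
      fv <- model_fwd(model, X[val_idx, , drop = FALSE], training = FALSE)
      hist_val[ep] <- loss_fn(fv$out, val_idx)$loss
    } else hist_val[ep] <- NA_real_
    rm(list = c())
  }
  list(model = model,
       history = data.frame(epoch = seq_len(tc$epochs),
                            train_loss = hist_train, val_loss = hist_val))
}

#' Train a pulse-selection classifier
#'
#' Minimizes binary cross-entropy (on logits, sigmoid applied inside the
#' loss) with Adam over the configured epochs. Deterministic for a fixed
#' `tc$seed`: initialization, the validation split (last 10% of a seeded
#' shuffle), per-epoch shuffling and dropout all derive from it.
#'
#' @param pulses N x 180 matrix of normalized pulses.
#' @param labels Logical (or 0/1) vector: TRUE for a calculable P2/P1 ratio.
#' @param tc A [train_config()].
#' @param cfg A [selector_config()].
#' @return A trained `icpr_model` with a `history` data frame
#'   (epoch, train_loss, val_loss) attached.
#' @export
train_selector <- function(pulses, labels, tc = train_config(),
                           cfg = selector_config("lstm")) {
  labels <- as.numeric(as.logical(labels))
  stopifnot(nrow(pulses) == length(labels), ncol(pulses) == PULSE_LEN)
  if (length(unique(labels)) < 2L)
    icpr_stop("icpr_single_class", "training labels contain a single class")
  with_seed(tc$seed, {
    model <- build_selector(cfg)
    res <- run_training(model, pulses, function(out, idx)
      bce_logits_loss(out, labels[idx], cfg$pos_weight), tc)
    res$model$history <- res$history
    res$model$train_config <- tc
    res$model
  })
}

#' Train a subpeak-designation network
#'
#' Minimizes the mean squared error between the network's 180-point output
#' and the two-Gaussian target vector of each labeled pulse (see
#' [target_vector()]). All labels must be calculable. Deterministic per seed.
#'
#' @param pulses N x 180 matrix of normalized pulses.
#' @param labels Data frame with `p1`, `p2` (1-based indices in the 180
#'   frame) and optionally `calculable`.
#' @param tc A [train_config()].
#' @param cfg A [designator_config()].
#' @return A trained `icpr_model` with `history` attached.
#' @export
train_designator <- function(pulses, labels, tc = train_config(),
                             cfg = designator_config("lstm")) {
  stopifnot(nrow(pulses) == nrow(labels), ncol(pulses) == PULSE_LEN)
  calc <- if ("calculable" %in% names(labels)) labels$calculable
          else labels$p1 > 0 & labels$p2 > 0
  if (!all(calc))
    icpr_stop("icpr_noncalculable_label",
              "designator training requires calculable labels only")
  targets <- t(vapply(seq_len(nrow(labels)), function(i)
    target_vector(labels$p1[i], labels$p2[i], sigma = cfg$target_sigma),
    numeric(PULSE_LEN)))
  with_seed(tc$seed, {
    model <- build_designator(cfg)
    res <- run_training(model, pulses, function(out, idx)
      mse_loss(out, targets[idx, , drop = FALSE]), tc)
    res$model$history <- res$history
    res$model$train_config <- tc
    res$model
  })
}

# Inference in chunks to bound peak memory.
model_predict <- function(model, pulses, chunk = 512L) {
  if (is.null(dim(pulses))) pulses <- matrix(pulses, 1L)
  n <- nrow(pulses)
  outs <- vector("list", ceiling(n / chunk))
  j <- 0L
  for (b0 in seq(1L, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    j <- j + 1L
    outs[[j]] <- model_fwd(model, pulses[bi, , drop = FALSE], training = FALSE)$out
  }
  if (model$task == "selection") unlist(outs) else do.call(rbind, outs)
}

#' Selection probabilities for a pulse matrix
#'
#' @param model A trained selection `icpr_model`.
#' @param pulses N x 180 matrix (or a `pulse_matrix`).
#' @return Numeric vector of per-pulse probabilities in (0, 1) (sigmoid of
#'   the network logits).
#' @export
predict_selection <- function(model, pulses) {
  stopifnot(inherits(model, "icpr_model"), model$task == "selection")
  if (inherits(pulses, "pulse_matrix")) pulses <- pulses$pulses
  stats::plogis(model_predict(model, pulses))
}

#' Designation score densities for a pulse matrix
#'
#' @param model A trained designation `icpr_model`.
#' @param pulses N x 180 matrix (or a `pulse_matrix`).
#' @return N x 180 matrix of per-sample subpeak-proximity scores.
#' @export
predict_density <- function(model, pulses) {
  stopifnot(inherits(model, "icpr_model"), model$task == "designation")
  if (inherits(pulses, "pulse_matrix")) pulses <- pulses$pulses
  model_predict(model, pulses)
}
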