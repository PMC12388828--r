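# Training of the ensemble variants with positively re-weighted binary
# cross-entropy. Contact maps are extremely class-imbalanced (a structure
# of length n has ~n/2 positive cells among n^2), so positive cells are
# up-weighted (default 300). Gradients are analytic and exercised against
# finite differences in the test suite; optimization uses Adam.

.BCE_EPS <- 1e-7

#' Training configuration
#'
#' @param pos_weight Multiplicative weight of positive cells inside the
#'   binary cross-entropy (default 300, reflecting the heavy class
#'   imbalance of contact maps).
#' @param batch_size Examples per gradient step (default 4).
#' @param epochs Training epochs (default 100).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Seed driving initialization and epoch shuffling.
#' @param max_len Sequences longer than this are excluded from training
#'   with a warning (default 500).
#' @param val_every Validate (and checkpoint on median F1) every this many
#'   epochs; the final epoch is always validated.
#' @return A list of class `train_config`.
#' @export
train_config <- function(pos_weight = 300, batch_size = 4L, epochs = 100L,
                         learning_rate = 1e-3, seed = 1L, max_len = 500L,
                         val_every = 1L) {
  stopifnot(pos_weight >= 1, batch_size >= 1, epochs >= 1, learning_rate > 0,
            max_len >= 1, val_every >= 1)
  structure(list(pos_weight = pos_weight, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), max_len = as.integer(max_len),
                 val_every = as.integer(val_every)),
            class = "train_config")
}

#' Bundle one training example
#'
#' @param stack A `learner_stack`.
#' @param truth Ground-truth `contact_map`.
#' @param seq The `rna_sequence` (needed for validation decoding).
#' @return A list of class `training_example`.
#' @export
training_example <- function(stack, truth, seq) {
  stopifnot(inherits(stack, "learner_stack"), inherits(truth, "contact_map"),
            inherits(seq, "rna_sequence"),
            stack$n == truth$n, truth$n == seq$n)
  structure(list(stack = stack, truth = truth, seq = seq),
            class = "training_example")
}

#' Positively re-weighted binary cross-entropy
#'
#' Mean over the masked cells of
#' `-(w * y * log(p) + (1 - y) * log(1 - p))` with `w = pos_weight` on
#' positive cells. Probabilities exactly 0 or 1 are clamped at `1e-7` (with
#' a message). Padding cells (mask 0) contribute nothing.
#'
#' @param Y Predicted probabilities.
#' @param Z Binary labels of the same dimension.
#' @param mask Optional binary matrix marking valid cells (default: all).
#' @param pos_weight Positive-class weight `w >= 1`.
#' @return Scalar loss.
#' @export
weighted_bce <- function(Y, Z, mask = NULL, pos_weight = 1) {
  stopifnot(all(dim(Y) == dim(Z)))
  if (is.null(mask)) mask <- matrix(1, nrow(Y), ncol(Y))
  sel <- mask == 1
  p <- Y[sel]
  z <- Z[sel]
  n_clamp <- sum(p <= 0 | p >= 1)
  if (n_clamp > 0L) {
    message(sprintf("weighted_bce: clamping %d probability value(s) at %.0e",
                    n_clamp, .BCE_EPS))
  }
  p <- pmin(pmax(p, .BCE_EPS), 1 - .BCE_EPS)
  mean(-(pos_weight * z * log(p) + (1 - z) * log(1 - p)))
}

#' Zero-pad examples into shuffled batches
#'
#' Examples are shuffled by `seed`, grouped into batches of `batch_size`,
#' and zero-padded to the longest sequence in each batch; a binary validity
#' mask marks the real top-left block of each example. With
#' `batch_size = 1` no padding ever occurs.
#'
#' @param dataset List of `training_example` objects.
#' @param batch_size Examples per batch.
#' @param seed Shuffling seed.
#' @return List of batches; each batch is a list of padded examples with
#'   fields `maps`, `Z`, `mask`, `n_real`, `stack`, `truth`, `seq`.
#' @export
make_batches <- function(dataset, batch_size, seed = 1L) {
  stopifnot(length(dataset) >= 1L)
  set.seed(seed)
  ord <- sample.int(length(dataset))
  starts <- seq(1L, length(ord), by = batch_size)
  lapply(starts, function(s) {
    idx <- ord[s:min(s + batch_size - 1L, length(ord))]
    ns <- vapply(idx, function(k) dataset[[k]]$truth$n, integer(1L))
    n_pad <- max(ns)
    lapply(idx, function(k) {
      ex <- dataset[[k]]
      n <- ex$truth$n
      pad <- function(m) {
        if (n == n_pad) return(m)
        out <- matrix(0, n_pad, n_pad)
        out[seq_len(n), seq_len(n)] <- m
        out
      }
      mask <- matrix(0, n_pad, n_pad)
      mask[seq_len(n), seq_len(n)] <- 1
      list(maps = lapply(ex$stack$maps, pad), Z = pad(cm_matrix(ex$truth)),
           mask = mask, n_real = n, stack = ex$stack, truth = ex$truth,
           seq = ex$seq)
    })
  })
}

# ---------------------------------------------------------------------------
# Analytic gradients
# ---------------------------------------------------------------------------

.attention_cache <- function(maps, par, n_real) {
  l <- length(maps)
  s_avg <- vapply(maps, sum, numeric(1L)) / (n_real^2)
  s_max <- vapply(maps, max, numeric(1L))
  mlp_a <- .mlp_forward(par, s_avg)
  mlp_m <- .mlp_forward(par, s_max)
  Fp <- .sigmoid(mlp_a$out + mlp_m$out)
  A_prime <- lapply(seq_len(l), function(c) Fp[c] * maps[[c]])
  Pavg <- Reduce(`+`, A_prime) / l
  Pmax <- A_prime[[1L]]
  argm <- matrix(1L, nrow(Pmax), ncol(Pmax))
  if (l > 1L) {
    for (c in 2:l) {
      upd <- A_prime[[c]] > Pmax
      Pmax[upd] <- A_prime[[c]][upd]
      argm[upd] <- c
    }
  }
  S <- .conv7_forward(Pavg, Pmax, par$conv, par$conv_b)
  Fd <- .sigmoid(S)
  A_dprime <- lapply(seq_len(l), function(c) Fd * A_prime[[c]])
  logit <- Reduce(`+`, lapply(seq_len(l), function(c) par$head_w[c] * A_dprime[[c]])) +
    par$head_b
  list(l = l, s_avg = s_avg, s_max = s_max, mlp_a = mlp_a, mlp_m = mlp_m,
       Fp = Fp, A_prime = A_prime, Pavg = Pavg, Pmax = Pmax, argm = argm,
       Fd = Fd, A_dprime = A_dprime, logit = logit, Y = .sigmoid(logit))
}

.zero_like <- function(par, fields) {
  g <- lapply(fields, function(f) {
    x <- par[[f]]
    x[] <- 0
    x
  })
  names(g) <- fields
  g
}

.attention_fields <- c("W1", "b1", "W2", "b2", "conv", "conv_b", "head_w", "head_b")

# loss + gradient of the attention ensemble on one (padded) example
.attention_grad <- function(maps, Z, mask, par, pos_weight, n_real) {
  cc <- .attention_cache(maps, par, n_real)
  l <- cc$l
  sel <- mask == 1
  N <- sum(sel)
  Y <- cc$Y
  p <- pmin(pmax(Y[sel], .BCE_EPS), 1 - .BCE_EPS)
  z <- Z[sel]
  loss <- mean(-(pos_weight * z * log(p) + (1 - z) * log(1 - p)))
  # d loss / d logit, zero on padding
  dlogit <- matrix(0, nrow(Y), ncol(Y))
  dlogit[sel] <- ((1 - z) * p - pos_weight * z * (1 - p)) / N
  g <- .zero_like(par, .attention_fields)
  dA_dp <- vector("list", l)
  for (c in seq_len(l)) {
    g$head_w[c] <- sum(dlogit * cc$A_dprime[[c]])
    dA_dp[[c]] <- par$head_w[c] * dlogit
  }
  g$head_b <- sum(dlogit)
  dFd <- Reduce(`+`, lapply(seq_len(l), function(c) dA_dp[[c]] * cc$A_prime[[c]]))
  dA_p <- lapply(seq_len(l), function(c) cc$Fd * dA_dp[[c]])
  dS <- dFd * cc$Fd * (1 - cc$Fd)
  g$conv_b <- sum(dS)
  dPavg <- matrix(0, nrow(dS), ncol(dS))
  dPmax <- matrix(0, nrow(dS), ncol(dS))
  for (du in -3:3) {
    for (dv in -3:3) {
      g$conv[1L, du + 4L, dv + 4L] <- sum(dS * .shift_mat(cc$Pavg, du, dv))
      g$conv[2L, du + 4L, dv + 4L] <- sum(dS * .shift_mat(cc$Pmax, du, dv))
      k1 <- par$conv[1L, du + 4L, dv + 4L]
      k2 <- par$conv[2L, du + 4L, dv + 4L]
      if (k1 != 0) dPavg <- dPavg + k1 * .shift_mat(dS, -du, -dv)
      if (k2 != 0) dPmax <- dPmax + k2 * .shift_mat(dS, -du, -dv)
    }
  }
  dFp <- numeric(l)
  for (c in seq_len(l)) {
    dA_p[[c]] <- dA_p[[c]] + dPavg / l + dPmax * (cc$argm == c)
    dFp[c] <- sum(dA_p[[c]] * maps[[c]])
  }
  dout <- dFp * cc$Fp * (1 - cc$Fp)
  for (branch in list(list(mlp = cc$mlp_a, s = cc$s_avg),
                      list(mlp = cc$mlp_m, s = cc$s_max))) {
    g$W2 <- g$W2 + dout %o% branch$mlp$hid
    g$b2 <- g$b2 + dout
    dpre <- drop(t(par$W2) %*% dout) * (branch$mlp$pre > 0)
    g$W1 <- g$W1 + dpre %o% branch$s
    g$b1 <- g$b1 + dpre
  }
  list(loss = loss, grads = g, Y = Y)
}

# loss + gradient of the lite ensemble on one (padded) example
.lite_grad <- function(maps, Z, mask, par, pos_weight) {
  pi_w <- lite_softmax(par$raw_weights)
  l <- length(maps)
  Y <- Reduce(`+`, lapply(seq_len(l), function(v) pi_w[v] * maps[[v]]))
  sel <- mask == 1
  N <- sum(sel)
  p <- pmin(pmax(Y[sel], .BCE_EPS), 1 - .BCE_EPS)
  z <- Z[sel]
  loss <- mean(-(pos_weight * z * log(p) + (1 - z) * log(1 - p)))
  dY <- (-pos_weight * z / p + (1 - z) / (1 - p)) / N
  gpi <- vapply(seq_len(l), function(v) sum(dY * maps[[v]][sel]), numeric(1L))
  graw <- pi_w * (gpi - sum(pi_w * gpi))
  list(loss = loss, grads = list(raw_weights = graw), Y = Y)
}

# ---------------------------------------------------------------------------
# Adam
# ---------------------------------------------------------------------------

.adam_init <- function(par, fields) {
  list(m = .zero_like(par, fields), v = .zero_like(par, fields), t = 0L)
}

.adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (f in names(grads)) {
    state$m[[f]] <- beta1 * state$m[[f]] + (1 - beta1) * grads[[f]]
    state$v[[f]] <- beta2 * state$v[[f]] + (1 - beta2) * grads[[f]]^2
    mhat <- state$m[[f]] / (1 - beta1^state$t)
    vhat <- state$v[[f]] / (1 - beta2^state$t)
    par[[f]] <- par[[f]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# ---------------------------------------------------------------------------
# Training loop
# ---------------------------------------------------------------------------

#' Train an ensemble variant with validation-based model selection
#'
#' Runs mini-batch Adam on the positively re-weighted binary cross-entropy.
#' After every `cfg$val_every` epochs the current model is evaluated on the
#' validation set: probability maps are decoded with `decoder` and the
#' median F1 against the validation truths is recorded; the returned
#' parameters are those of the best-validation epoch (falling back to the
#' final epoch when no validation set is given). Fully deterministic given
#' `cfg$seed`.
#'
#' @param dataset List of `training_example` objects.
#' @param val_set Optional list of `training_example` objects.
#' @param cfg A `train_config`.
#' @param variant `"attention"` (channel + spatial attention network) or
#'   `"lite"` (learnable softmax learner weights).
#' @param decoder A `decoder_config` used for validation decoding.
#' @param r Channel-attention reduction ratio (attention variant).
#' @param verbose Print one line per epoch to stderr.
#' @return List with `params` (selected checkpoint), `history` (data frame
#'   of epoch, loss, val_f1), `best_epoch`, and `final_params`.
#' @export
train_ensemble <- function(dataset, val_set = NULL, cfg = train_config(),
                           variant = c("attention", "lite"),
                           decoder = decoder_config(), r = 1,
                           verbose = FALSE) {
  variant <- match.arg(variant)
  if (length(dataset) == 0L) stop("empty training dataset")
  too_long <- vapply(dataset, function(e) e$truth$n > cfg$max_len, logical(1L))
  if (any(too_long)) {
    warning(sprintf("excluding %d example(s) longer than max_len = %d",
                    sum(too_long), cfg$max_len))
    dataset <- dataset[!too_long]
    if (length(dataset) == 0L) stop("no examples remain after length filtering")
  }
  npos <- sum(vapply(dataset, function(e) n_pairs(e$truth), integer(1L)))
  ncell <- sum(vapply(dataset, function(e) e$truth$n^2, numeric(1L)))
  if (npos == 0L || 2 * npos >= ncell) {
    warning("degenerate label distribution (all-negative or all-positive)")
  }
  lnames <- dataset[[1L]]$stack$learner_names
  for (e in dataset) {
    if (!identical(e$stack$learner_names, lnames)) {
      stop("all training stacks must share the same learner set and order")
    }
  }
  l <- length(lnames)
  par <- if (variant == "attention") {
    init_cbam_params(l, r = r, learner_names = lnames, seed = cfg$seed)
  } else {
    init_lite_params(l, learner_names = lnames)
  }
  fields <- if (variant == "attention") .attention_fields else "raw_weights"
  state <- .adam_init(par, fields)
  best_f1 <- -Inf
  best_par <- par
  best_epoch <- NA_integer_
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_f1 = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    batches <- make_batches(dataset, cfg$batch_size, seed = cfg$seed + epoch)
    epoch_loss <- 0
    n_seen <- 0L
    for (batch in batches) {
      acc <- NULL
      bloss <- 0
      for (ex in batch) {
        gr <- if (variant == "attention") {
          .attention_grad(ex$maps, ex$Z, ex$mask, par, cfg$pos_weight, ex$n_real)
        } else {
          .lite_grad(ex$maps, ex$Z, ex$mask, par, cfg$pos_weight)
        }
        bloss <- bloss + gr$loss
        if (is.null(acc)) {
          acc <- gr$grads
        } else {
          for (f in fields) acc[[f]] <- acc[[f]] + gr$grads[[f]]
        }
      }
      nb <- length(batch)
      for (f in fields) acc[[f]] <- acc[[f]] / nb
      upd <- .adam_step(par, acc, state, cfg$learning_rate)
      par <- upd$par
      state <- upd$state
      epoch_loss <- epoch_loss + bloss
      n_seen <- n_seen + nb
    }
    epoch_loss <- epoch_loss / n_seen
    val_f1 <- NA_real_
    if (!is.null(val_set) &&
        (epoch %% cfg$val_every == 0L || epoch == cfg$epochs)) {
      f1s <- vapply(val_set, function(e) {
        Y <- ensemble_predict(e$stack, par)
        pred <- decode(Y, e$seq, decoder)
        pair_metrics(confusion(pred, e$truth))$f1
      }, numeric(1L))
      val_f1 <- median(f1s)
      if (val_f1 > best_f1) {
        best_f1 <- val_f1
        best_par <- par
        best_epoch <- epoch
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                         val_f1 = val_f1))
    if (verbose) {
      message(sprintf("epoch %3d  loss %10.4f  val_f1 %s", epoch, epoch_loss,
                      ifelse(is.na(val_f1), "-", sprintf("%.4f", val_f1))))
    }
  }
  if (is.null(val_set)) {
    best_par <- par
    best_epoch <- cfg$epochs
  }
  list(params = best_par, history = history, best_epoch = best_epoch,
       final_params = par)
}
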