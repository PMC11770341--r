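# ---------------------------------------------------------------------------
# Hybrid imbalance-aware L1 loss and the optimization protocol.
#
# Normalized single-cell expression is ~92% exact zeros. Training therefore
# mixes two L1 variants per batch: with probability p_plain (0.1) the plain
# mean L1 over all nodes (so the model still sees the true zero-heavy
# distribution), otherwise a weighted L1 on a balanced subset in which the
# zero targets are downsampled to match the nonzero count and the zero /
# nonzero groups are reweighted 0.4 / 0.6. Validation always uses the plain
# deterministic mean L1.
# ---------------------------------------------------------------------------

#' Loss configuration
#'
#' @param p_plain probability of taking the plain (no-downsampling) L1 branch
#'   for a batch (default 0.1).
#' @param w_zero,w_nonzero weights of the zero / nonzero target groups in the
#'   weighted branch (defaults 0.4 / 0.6; must sum to 1).
#' @return a `loss_config` list.
#' @export
loss_config <- function(p_plain = 0.1, w_zero = 0.4, w_nonzero = 0.6) {
  stopifnot(p_plain >= 0, p_plain <= 1)
  if (abs(w_zero + w_nonzero - 1) > 1e-12) {
    stop_fmt("w_zero + w_nonzero must equal 1 (got %g + %g)", w_zero, w_nonzero)
  }
  structure(list(p_plain = p_plain, w_zero = w_zero, w_nonzero = w_nonzero),
            class = "loss_config")
}

#' Downsample zero targets to balance a batch
#'
#' Keeps every nonzero-target index and a uniform random sample of the
#' zero-target indices of equal count (drawn from the caller's RNG stream).
#' When zeros are already the minority, all indices are returned unchanged.
#'
#' @param targets numeric target vector.
#' @return sorted integer index subset.
#' @export
downsample_zeros <- function(targets) {
  zero_idx <- which(targets == 0)
  nonzero_idx <- which(targets != 0)
  if (length(nonzero_idx) == 0) {
    warn_fmt("all targets in the batch are zero; weighted loss degenerates to plain L1 on zeros")
    return(seq_along(targets))
  }
  if (length(zero_idx) <= length(nonzero_idx)) {
    return(seq_along(targets))
  }
  sampled <- sample(zero_idx, length(nonzero_idx))
  sort(c(nonzero_idx, sampled))
}

#' Hybrid imbalance-aware L1 loss
#'
#' Draws one uniform number per call (per batch): below `p_plain` the plain
#' mean L1 over all entries is used; otherwise the zero targets are
#' downsampled ([downsample_zeros()]) and the weighted L1
#' `(w_zero * sum|err over zero targets| + w_nonzero * sum|err over nonzero|)
#' / N_subset` is computed on the balanced subset. Also returns the exact
#' subgradient with respect to the predictions, for the optimizer.
#'
#' @param pred,target numeric vectors of equal length.
#' @param cfg a [loss_config()].
#' @param branch `"auto"` (draw the Bernoulli branch from the RNG),
#'   `"plain"`, or `"weighted"` (forced; used in tests and oracles).
#' @return list: `loss` (scalar), `grad` (dLoss/dpred, full length),
#'   `branch`, `subset` (indices the loss was evaluated on).
#' @export
hybrid_loss <- function(pred, target, cfg = loss_config(), branch = "auto") {
  if (length(pred) != length(target)) {
    stop_fmt("pred and target lengths differ (%d vs %d)", length(pred), length(target))
  }
  branch <- match.arg(branch, c("auto", "plain", "weighted"))
  if (branch == "auto") {
    branch <- if (runif(1) < cfg$p_plain) "plain" else "weighted"
  }
  err <- pred - target
  if (branch == "plain") {
    n <- length(pred)
    return(list(loss = mean(abs(err)), grad = sign(err) / n,
                branch = "plain", subset = seq_len(n)))
  }
  idx <- downsample_zeros(target)
  nhat <- length(idx)
  w <- ifelse(target[idx] == 0, cfg$w_zero, cfg$w_nonzero)
  loss <- sum(w * abs(err[idx])) / nhat
  grad <- numeric(length(pred))
  grad[idx] <- w * sign(err[idx]) / nhat
  list(loss = loss, grad = grad, branch = "weighted", subset = idx)
}

#' Training configuration
#'
#' @param learning_rate initial AdamW learning rate (default 1e-4).
#' @param batch_size graphs per batch (default 8).
#' @param weight_decay decoupled weight-decay coefficient (default 0.01).
#' @param max_epochs epoch cap (default 100).
#' @param lr_factor,lr_patience reduce-on-plateau factor (0.5) and patience in
#'   epochs without validation improvement (5).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (5).
#' @param seed master seed for shuffling, the loss-branch stream and the
#'   downsampling stream (each derived independently).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8,
                         weight_decay = 0.01, max_epochs = 100,
                         lr_factor = 0.5, lr_patience = 5,
                         early_stop_patience = 5, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, weight_decay >= 0,
            max_epochs >= 1, lr_factor > 0, lr_factor < 1,
            lr_patience >= 1, early_stop_patience >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 weight_decay = weight_decay, max_epochs = max_epochs,
                 lr_factor = lr_factor, lr_patience = lr_patience,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- AdamW (decoupled weight decay) ----------------------------------------

adamw_init <- function(params) {
  list(t = 0L, m = zero_like(params), v = zero_like(params))
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- lapply(seq_along(p), function(i) rec(p[[i]], g[[i]], m[[i]], v[[i]]))
      names(out) <- names(p)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      upd <- (m2 / bc1) / (sqrt(v2 / bc2) + eps)
      list(p = p - lr * upd - lr * weight_decay * p, m = m2, v = v2)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = structure(r$p, class = class(params)),
       state = list(t = state$t, m = r$m, v = r$v))
}

#' Mean absolute validation error of a parameter set over graphs
#'
#' Plain deterministic L1 on clamped-[0, 1] predictions, averaged over all
#' nodes of all graphs.
#'
#' @param params `model_params`.
#' @param graphs list of `gene_graph`.
#' @param config `model_config`.
#' @return scalar mean absolute error.
#' @export
validation_loss <- function(params, graphs, config) {
  tot <- 0; n <- 0
  for (g in graphs) {
    pred <- model_forward(g, params, config, clamp = TRUE)
    tot <- tot + sum(abs(pred - g$targets))
    n <- n + g$n
  }
  tot / n
}

#' Train the graph transformer
#'
#' Per epoch: the training graphs are reshuffled (seeded), packed into
#' batches of `batch_size`, and one AdamW step is taken per batch on the
#' hybrid loss. After each epoch the deterministic validation L1 drives a
#' reduce-on-plateau learning-rate schedule and early stopping; the
#' parameters achieving the best validation loss are returned. The branch
#' draw and the zero-downsampling use dedicated seeded streams, independent
#' of parameter initialization and shuffling, so the loss history is exactly
#' reproducible.
#'
#' @param train_graphs,val_graphs lists of `gene_graph`.
#' @param model_cfg [model_config()].
#' @param train_cfg [train_config()].
#' @param loss_cfg [loss_config()].
#' @param cell_types optional named cell-type map; when given, train and
#'   validation cell types are asserted disjoint.
#' @param verbose print one line per epoch?
#' @return list: `params` (best checkpoint), `history` (data.table epoch /
#'   train_loss / val_loss / lr), `best_epoch`, `best_val`, `config`.
#' @export
train_model <- function(train_graphs, val_graphs, model_cfg,
                        train_cfg = train_config(), loss_cfg = loss_config(),
                        cell_types = NULL, verbose = FALSE) {
  if (length(train_graphs) == 0 || length(val_graphs) == 0) {
    stop_fmt("empty train or validation split")
  }
  if (!is.null(cell_types)) {
    tt <- unique(cell_types[vapply(train_graphs, function(g) g$cell_id, "")])
    vt <- unique(cell_types[vapply(val_graphs, function(g) g$cell_id, "")])
    if (length(intersect(tt, vt)) > 0) {
      stop_fmt("train and validation cell types overlap: %s",
               paste(intersect(tt, vt), collapse = ", "))
    }
  }
  params <- init_model_params(model_cfg)
  opt <- adamw_init(params)
  lr <- train_cfg$learning_rate
  best_val <- Inf; best_epoch <- 0L; best_params <- params
  stale_sched <- 0L; stale_stop <- 0L
  batch_counter <- 0L
  history <- list()
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- with_seed(derive_seed(train_cfg$seed, paste0("shuffle", epoch)),
                     sample(length(train_graphs)))
    batch_starts <- seq(1, length(ord), by = train_cfg$batch_size)
    epoch_losses <- numeric(length(batch_starts))
    for (b in seq_along(batch_starts)) {
      batch_counter <- batch_counter + 1L
      sel <- ord[batch_starts[b]:min(batch_starts[b] + train_cfg$batch_size - 1, length(ord))]
      batch <- pack_graphs(train_graphs[sel])
      fw <- model_forward(batch, params, model_cfg, clamp = FALSE, cache = TRUE)
      ls <- with_seed(derive_seed(train_cfg$seed, paste0("loss-batch", batch_counter)),
                      hybrid_loss(fw$pred, batch$targets, loss_cfg))
      if (!is.finite(ls$loss)) {
        stop_fmt("non-finite training loss at epoch %d batch %d", epoch, b)
      }
      grads <- model_backward(fw, ls$grad, params, model_cfg)
      st <- adamw_step(params, grads, opt, lr, train_cfg$weight_decay)
      params <- st$params
      opt <- st$state
      epoch_losses[b] <- ls$loss
    }
    val <- validation_loss(params, val_graphs, model_cfg)
    history[[epoch]] <- data.table::data.table(
      epoch = epoch, train_loss = mean(epoch_losses), val_loss = val, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, mean(epoch_losses), val, lr))
    }
    if (val < best_val) {
      best_val <- val; best_epoch <- epoch; best_params <- params
      stale_sched <- 0L; stale_stop <- 0L
    } else {
      stale_sched <- stale_sched + 1L
      stale_stop <- stale_stop + 1L
      if (stale_sched >= train_cfg$lr_patience) {
        lr <- lr * train_cfg$lr_factor
        stale_sched <- 0L
      }
      if (stale_stop >= train_cfg$early_stop_patience) break
    }
  }
  list(params = best_params, history = data.table::rbindlist(history),
       best_epoch = best_epoch, best_val = best_val, config = model_cfg)
}

#' Write a training history as TSV
#' @param history data.table from [train_model()].
#' @param path output path.
#' @export
write_history <- function(history, path) {
  data.table::fwrite(history, path, sep = "\t")
  invisible(path)
}
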